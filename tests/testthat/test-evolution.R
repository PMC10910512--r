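free2 <- c("twostar", "nsp1")

cfg_synth <- function(...) {
  gaConfig(statNames = free2, template = "1-ribbon", nNodes = 8,
           reps = 1, ...)
}

test_that("sphere seeding stays inside the ball and honors fixed edges", {
  cfg <- cfg_synth(masterSeed = 3)
  ctr <- c(twostar = 5, nsp1 = -2)
  pts <- seedSphere(cfg, center = ctr, radius = 7, count = 200, seed = 31)
  d <- vapply(pts, function(p) sqrt(sum((p$phi[free2] - ctr)^2)), numeric(1))
  expect_true(all(d <= 7 + 1e-12))
  expect_gt(max(d), 3.5)   # points actually spread through the ball

  tiny <- seedSphere(cfg, center = ctr, radius = 1e-9, count = 10, seed = 32)
  for (p in tiny) expect_equal(p$phi[free2], ctr, tolerance = 1e-6)

  cfgF <- gaConfig(statNames = c("edges", free2), fixEdge = TRUE,
                   nNodes = 48, masterSeed = 3)
  ptsF <- seedSphere(cfgF, radius = 5, count = 50, seed = 33)
  edgeVals <- vapply(ptsF, function(p) p$phi[["edges"]], numeric(1))
  expect_true(all(edgeVals == fibrilNHM:::.pinned_edge_phi(cfgF)))
  expect_error(seedSphere(gaConfig(statNames = "edges", fixEdge = TRUE)),
               "free dimensions")
})

test_that("line breeding places children per the density rule", {
  cfg <- cfg_synth(masterSeed = 5)
  p1 <- fibrilNHM:::.individual(1L, c(twostar = 0, nsp1 = 0), "seed")
  p2 <- fibrilNHM:::.individual(2L, c(twostar = 0, nsp1 = 3), "seed")
  set.seed(1)
  kids <- breedPair(p1, p2, cfg, noiseVar = 1, mutantsPerChild = 1L)
  # distance 3, minLineDensity 1.2 -> floor(3.6) = 3 linear + 3 mutants
  expect_length(kids, 6)
  lin <- Filter(function(k) k$origin == "linear", kids)
  expect_equal(t(vapply(lin, function(k) unname(k$phi[free2]), numeric(2))),
               cbind(c(0, 0, 0), c(0.75, 1.5, 2.25)))
  # every linear child is exactly collinear with its parents
  for (k in lin) {
    lam <- k$phi[["nsp1"]] / 3
    expect_lt(max(abs(k$phi[free2] -
                      ((1 - lam) * p1$phi[free2] + lam * p2$phi[free2]))),
              1e-9)
  }
  # too-close parents are deemed too related to breed
  p3 <- fibrilNHM:::.individual(3L, c(twostar = 0, nsp1 = 0.5), "seed")
  expect_length(breedPair(p1, p3, cfg), 0)
  # childMax caps the litter
  cfgCap <- cfg_synth(childMax = 2, masterSeed = 5)
  set.seed(2)
  expect_length(breedPair(p1, p2, cfgCap, mutantsPerChild = 3L), 2)
})

test_that("fitness evaluation is deterministic and survives bad regions", {
  cfg <- gaConfig(statNames = c("edges", "twostar"), template = "1-ribbon",
                  nNodes = 16, reps = 3, burninProposals = 3000,
                  masterSeed = 77)
  # a strongly negative theta_e empties the graph: fraction 0
  f0 <- evaluateFitness(c(edges = 20, twostar = 0), cfg, id = 1)
  expect_equal(f0$mean, 0)
  # runaway densification is caught by the guard and scored 0
  cfgG <- gaConfig(statNames = c("edges", "twostar"), template = "1-ribbon",
                   nNodes = 16, reps = 3, burninProposals = 3000,
                   maxEdgesGuard = 30, masterSeed = 77)
  fg <- evaluateFitness(c(edges = -20, twostar = 0), cfgG, id = 2)
  expect_equal(fg$mean, 0)
  # identical phi and id reproduce identical draws
  phi <- c(edges = -104, twostar = 40)
  fa <- evaluateFitness(phi, cfg, id = 5)
  fb <- evaluateFitness(phi, cfg, id = 5)
  expect_identical(fa, fb)
  expect_equal(fa$mean, mean(fa$draws))
})

test_that("selection ranks by mean with deterministic tie-breaks and caps", {
  cfg <- cfg_synth(topFraction = 0.25, maxSurvivors = 20, masterSeed = 1)
  pop <- lapply(1:20, function(i)
    fibrilNHM:::.individual(i, c(twostar = 0, nsp1 = 0), "seed",
                            mean = c(rep(0.9, 3), seq(0.8, 0, length.out = 17))[i]))
  surv <- selectSurvivors(pop, cfg)
  expect_length(surv, 5)
  expect_equal(vapply(surv, `[[`, integer(1), "id")[1:3], 1:3)  # tie by id
  cfgCap <- cfg_synth(topFraction = 1, maxSurvivors = 4, masterSeed = 1)
  set.seed(3)
  expect_length(selectSurvivors(pop, cfgCap), 4)
  expect_error(selectSurvivors(list(), cfg), "empty")
})

test_that("rejected generations trigger smart variance and smart points", {
  cfg <- cfg_synth(maxGenerations = 3, maxRetries = 2, smartVar = TRUE,
                   smartPts = TRUE, topFraction = 0.5, masterSeed = 11)
  # constant fitness: no child can strictly outperform its parents
  run <- runEvolution(cfg, init = rbind(c(0, 0), c(0, 6), c(5, 3)),
                      fitness = function(phi) 0.5)
  expect_true(run@stalled)
  expect_length(run@generations, 1)   # only generation 0 accepted
  rejected <- run@ledger[!run@ledger$accepted, ]
  expect_gt(nrow(rejected), 0)
  expect_equal(sort(unique(rejected$attempt)), 0:2)
  # ledger accounting: every evaluated individual appears exactly once
  expect_false(anyDuplicated(run@ledger$id) > 0)
})

test_that("the GA recovers the optimum of a synthetic Gaussian landscape", {
  target <- c(twostar = 2, nsp1 = -1)
  fitness <- function(phi) exp(-sum((phi[free2] - target)^2))
  # mutant noise matched to the unit-scale landscape; the fibril searches
  # use the coarser default because their coefficients live on a ~40 scale
  cfg <- cfg_synth(noiseVarInit = 0.04, maxGenerations = 15, maxRetries = 6,
                   topFraction = 0.4, maxSurvivors = 6, childMax = 60,
                   masterSeed = 1)
  run <- runEvolution(cfg, center = c(twostar = 0, nsp1 = 0), radius = 6,
                      count = 20, fitness = fitness)
  expect_gt(run@best$mean, 0.99)
  expect_lt(sqrt(sum((run@best$phi[free2] - target)^2)), 0.1)
  # best-of-run trajectory is nondecreasing
  bests <- vapply(run@generations, `[[`, numeric(1), "bestMean")
  expect_true(all(diff(bests) >= 0))
})

test_that("an already-optimal parent persists through generations", {
  target <- c(twostar = 1, nsp1 = 1)
  fitness <- function(phi) exp(-sum((phi[free2] - target)^2))
  cfg <- cfg_synth(maxGenerations = 4, maxRetries = 2, topFraction = 0.5,
                   masterSeed = 13)
  init <- rbind(c(1, 1), c(4, -3), c(-3, 4))   # row 1 is exactly optimal
  run <- runEvolution(cfg, init = init, fitness = fitness)
  expect_equal(run@best$phi[["twostar"]], 1)
  expect_equal(run@best$phi[["nsp1"]], 1)
  # the optimal point survives as a parent copy in every accepted generation
  for (g in run@generations[-1]) {
    led <- run@ledger[run@ledger$generation == g$index & run@ledger$accepted, ]
    expect_true(any(led$origin == "parent-copy" & led$mean == 1))
  }
})

test_that("degenerate starting populations stall immediately", {
  cfg <- cfg_synth(maxGenerations = 5, masterSeed = 2)
  run <- runEvolution(cfg, init = rbind(c(0, 0)),
                      fitness = function(phi) 0.3)
  expect_true(run@stalled)
  expect_length(run@generations, 1)
})

test_that("full runs are reproducible bit for bit under one master seed", {
  fitness <- function(phi) exp(-sum(phi[free2]^2))
  cfg <- cfg_synth(maxGenerations = 4, maxRetries = 2, topFraction = 0.5,
                   masterSeed = 99)
  r1 <- runEvolution(cfg, center = c(twostar = 1, nsp1 = 1), radius = 4,
                     count = 8, fitness = fitness)
  r2 <- runEvolution(cfg, center = c(twostar = 1, nsp1 = 1), radius = 4,
                     count = 8, fitness = fitness)
  expect_identical(r1@ledger, r2@ledger)
  expect_identical(r1@best, r2@best)
})

test_that("fixEdge pins the edge coordinate across an entire run", {
  cfg <- gaConfig(statNames = c("edges", free2), fixEdge = TRUE,
                  nNodes = 48, reps = 1, maxGenerations = 3, maxRetries = 2,
                  topFraction = 0.5, childMax = 10, masterSeed = 55)
  pin <- fibrilNHM:::.pinned_edge_phi(cfg)
  fitness <- function(phi) exp(-sum((phi[free2] - c(1, 1))^2))
  run <- runEvolution(cfg, center = c(twostar = 0, nsp1 = 0), radius = 4,
                      count = 6, fitness = fitness)
  expect_true(all(run@ledger$phi_edges == pin))
  # and the pinned value converts back to exactly the configured theta
  m <- nhmModel(setNames(c(pin, 0, 0), c("edges", free2)))
  expect_equal(phiToTheta(m, cfg@nNodes)[["edges"]], cfg@fixEdgeValue)
})
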