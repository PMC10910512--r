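test_that("log acceptance ratio is the aligned dot product", {
  expect_equal(mhLogRatio(c(edges = 0, twostar = 0), c(edges = 1, twostar = -2)), 0)
  expect_equal(mhLogRatio(c(edges = -2), c(edges = 1)), -2)
  th <- phiToTheta(modelPreset("1-ribbon"), 256)
  d0 <- c(edges = 1, twostar = 0, nsp1 = 0)
  expect_equal(mhLogRatio(th, d0), 107.22 - 1 + log(256))
  expect_error(mhLogRatio(c(edges = 1), c(twostar = 1)), "aligned")
})

test_that("draws are reproducible and ensembles are order-independent", {
  m <- modelPreset("2-ribbon")
  cfg <- samplerConfig(burninProposals = 2e4, seed = 42)
  d1 <- simulateDraw(m, 24, cfg)
  d2 <- simulateDraw(m, 24, cfg)
  expect_identical(igraph::as_edgelist(drawGraph(d1)),
                   igraph::as_edgelist(drawGraph(d2)))
  expect_identical(drawStats(d1), drawStats(d2))

  e1 <- simulateEnsemble(m, 24, 3, masterSeed = 9,
                         config = samplerConfig(burninProposals = 1e4))
  e2 <- simulateEnsemble(m, 24, 3, masterSeed = 9,
                         config = samplerConfig(burninProposals = 1e4))
  expect_identical(lapply(e1, drawStats), lapply(e2, drawStats))
  # a one-draw ensemble equals simulateDraw at the derived seed
  s1 <- fibrilNHM:::.derive_seeds(9, 1)
  one <- simulateEnsemble(m, 24, 1, masterSeed = 9,
                          config = samplerConfig(burninProposals = 1e4))
  direct <- simulateDraw(m, 24, samplerConfig(burninProposals = 1e4, seed = s1))
  expect_identical(drawStats(one[[1]]), drawStats(direct))
})

test_that("edges-only models reproduce the dyad-independent closed form", {
  m <- nhmModel(c(edges = 0))
  # theta_e = -2: each dyad independently present w.p. logistic(-2)
  draws <- simulateEnsemble(m, 20, 40, masterSeed = 11,
                            config = samplerConfig(burninProposals = 2e4),
                            theta = c(edges = -2))
  dens <- vapply(draws, function(d) igraph::ecount(drawGraph(d)) / 190,
                 numeric(1))
  p <- exp(-2) / (1 + exp(-2))
  mc_se <- sqrt(p * (1 - p) / (40 * 190))
  expect_lt(abs(mean(dens) - p), 5 * mc_se)

  # theta = 0: uniform over graphs; edge count ~ Binomial(45, 1/2)
  d0 <- simulateEnsemble(m, 10, 200, masterSeed = 12,
                         config = samplerConfig(burninProposals = 5e3,
                                                maxEdgesGuard = 100),
                         theta = c(edges = 0))
  counts <- vapply(d0, function(d) igraph::ecount(drawGraph(d)), numeric(1))
  expect_lt(abs(mean(counts) - 22.5), 5 * sqrt(45 * 0.25 / 200))
  expect_lt(abs(var(counts) - 11.25), 5 * 11.25 * sqrt(2 / 199))
})

test_that("incrementally maintained statistics equal a full recount", {
  for (nm in c("1-ribbon", "2-ribbon", "1,2 2-ribbon", "3-prism")) {
    m <- modelPreset(nm)
    d <- simulateDraw(m, 48, samplerConfig(burninProposals = 5e4, seed = 7))
    expect_identical(drawStats(d), computeStats(drawGraph(d), statNames(m)))
    expect_lte(d@accepted, d@proposed)
  }
})

test_that("the pure-toggle kernel is also exact for dyad-independent models", {
  m <- nhmModel(c(edges = 0))
  draws <- simulateEnsemble(m, 16, 30, masterSeed = 21,
                            config = samplerConfig(burninProposals = 2e4,
                                                   swapFraction = 0),
                            theta = c(edges = -1))
  dens <- vapply(draws, function(d) igraph::ecount(drawGraph(d)) / 120,
                 numeric(1))
  p <- exp(-1) / (1 + exp(-1))
  expect_lt(abs(mean(dens) - p), 5 * sqrt(p * (1 - p) / (30 * 120)))
})

test_that("runaway densification triggers the degeneracy guard", {
  m <- nhmModel(c(edges = -20))   # theta_e strongly positive
  expect_error(simulateDraw(m, 20, samplerConfig(burninProposals = 1e4,
                                                 maxEdgesGuard = 40)),
               class = "nhmDegeneracyError")
})
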