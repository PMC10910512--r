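test_that("configurations validate, fill defaults, and round-trip", {
  cfg <- asRunConfig(list(preset = "2-ribbon", nNodes = 48))
  expect_equal(cfg$reps, 16L)
  expect_equal(cfg$noiseVarInit, 1.0)
  expect_equal(cfg$topFraction, 0.25)
  expect_equal(cfg$maxSurvivors, 20L)
  expect_equal(cfg$minLineDensity, 1.2)
  expect_equal(cfg$childMax, 100L)

  expect_error(asRunConfig(list(preset = "2-ribbon", topFraction = 1.5)),
               "topFraction")
  expect_error(asRunConfig(list(preset = "2-ribbon", frobnicate = 1)),
               "unknown configuration key")
  expect_error(asRunConfig(list(preset = "9-ribbon")), "unknown fibril")

  p <- withr::local_tempfile(fileext = ".yaml")
  saveConfig(cfg, p)
  expect_equal(unclass(loadConfig(p)), unclass(cfg))

  m <- configModel(asRunConfig(list(model = list(edges = -5, twostar = 2))))
  expect_equal(unname(phiCoefs(m)), c(-5, 2))
  ga <- configGA(asRunConfig(list(preset = "2-ribbon", nNodes = 24,
                                  reps = 4)))
  expect_s4_class(ga, "GAConfig")
  expect_equal(ga@nNodes, 24L)
  expect_equal(ga@reps, 4L)
})

test_that("fixtures are reproducible and match their definitions", {
  g <- makeFixture("four-node-example")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 4)

  perf <- makeFixture("perfect-1ribbon-48-cyclic")
  expect_equal(fibrilFraction(perf, "1-ribbon"), 1.0)

  d1 <- makeFixture("damaged-2ribbon-24u-k3", seed = 9)
  d2 <- makeFixture("damaged-2ribbon-24u-k3", seed = 9)
  expect_identical(igraph::as_edgelist(d1), igraph::as_edgelist(d2))
  expect_equal(igraph::ecount(d1),
               igraph::ecount(makeFixture("perfect-2ribbon-24-cyclic")) - 3)

  cloud <- makeFixture("gen0-cloud", seed = 4)
  expect_length(cloud, 20)
  expect_true(all(vapply(cloud, function(p) p$origin, "") == "seed"))
  expect_error(makeFixture("no-such-fixture"), "unknown fixture")
})

test_that("ensemble outputs are complete and byte-identical across reruns", {
  m <- modelPreset("1-ribbon")
  draws <- simulateEnsemble(m, 16, 4, masterSeed = 31,
                            config = samplerConfig(burninProposals = 5e3))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeOutputs(draws, d1, config = list(preset = "1-ribbon"), masterSeed = 31,
               template = "1-ribbon")
  writeOutputs(draws, d2, config = list(preset = "1-ribbon"), masterSeed = 31,
               template = "1-ribbon")
  expect_length(list.files(d1, pattern = "^draw_"), 4)
  s <- read.csv(file.path(d1, "stats.csv"))
  expect_equal(nrow(s), 4)
  expect_true(all(c("edges", "fibrilFraction") %in% names(s)))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # draws can be reloaded from their edge lists
  g <- readEdgeList(file.path(d1, "draw_001.txt"))
  expect_equal(unname(computeStats(g, statNames(m))),
               unname(drawStats(draws[[1]])))
})

test_that("evolution outputs carry the full per-individual ledger", {
  cfg <- gaConfig(statNames = c("twostar", "nsp1"), template = "1-ribbon",
                  nNodes = 8, reps = 1, maxGenerations = 3, maxRetries = 2,
                  topFraction = 0.5, childMax = 10, masterSeed = 21)
  run <- runEvolution(cfg, center = c(twostar = 0, nsp1 = 0), radius = 5,
                      count = 6,
                      fitness = function(phi) exp(-sum((phi - 1)^2)))
  d <- withr::local_tempdir()
  writeOutputs(run, d, config = list(), masterSeed = 21)
  led <- read.csv(file.path(d, "ledger.csv"))
  expect_equal(nrow(led), nrow(run@ledger))
  # accepted rows per generation match the recorded population sizes
  for (g in run@generations[-1])
    expect_equal(sum(led$accepted & led$generation == g$index),
                 length(g$populationIds))
  gens <- read.csv(file.path(d, "generations.csv"))
  expect_equal(nrow(gens), length(run@generations))
  expect_true(file.exists(file.path(d, "best_model.yaml")))
  log <- yaml::read_yaml(file.path(d, "run_log.yaml"))
  expect_equal(log$masterSeed, 21)
})
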