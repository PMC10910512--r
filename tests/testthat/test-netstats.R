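test_that("worked four-node example reproduces the hand-checked statistics", {
  g <- makeFixture("four-node-example")
  expect_equal(computeStatistic(g, "nsp1"), 2)
  expect_equal(computeStatistic(g, "esp0"), 1)
  expect_equal(computeStatistic(g, "cycle3"), 1)
  expect_equal(computeStatistic(g, "cycle5"), 0)
  expect_equal(computeStatistic(g, "cycle6"), 0)
  expect_equal(computeStatistic(g, "cycle7"), 0)
  # remaining statistics against the brute-force oracle
  expect_equal(unname(computeStats(g, all_stats)), unname(oracle_stats(g, all_stats)))
  expect_equal(unname(computeStats(g, c("edges", "twostar", "nsp1", "nsp2",
                                        "esp0", "esp1", "cycle3"))),
               c(4, 5, 2, 0, 1, 3, 1))
})

test_that("degenerate and closed-form graphs count correctly", {
  empty <- graphFromEdges(6, NULL)
  for (nm in all_stats) expect_equal(computeStatistic(empty, nm), 0)

  path5 <- buildFibril("1-ribbon", 5)
  expect_equal(unname(computeStats(path5, c("edges", "twostar"))), c(4, 3))

  # complete graphs: cycle_k = C(n,k) (k-1)! / 2
  for (n in 4:8) {
    kn <- igraph::make_full_graph(n)
    for (k in c(3, 5, 6, 7)) {
      if (k > n) next
      expect_equal(computeStatistic(kn, paste0("cycle", k)),
                   choose(n, k) * factorial(k - 1) / 2)
    }
  }
})

test_that("all statistics match the brute-force oracle on random graphs", {
  set.seed(101)
  for (i in 1:40) {
    g <- random_graph(sample(5:8, 1), runif(1, 0.2, 0.7))
    expect_equal(unname(computeStats(g, all_stats)),
                 unname(oracle_stats(g, all_stats)))
  }
})

test_that("statistics are invariant under node relabeling", {
  set.seed(102)
  for (i in 1:10) {
    g <- random_graph(8, 0.4)
    perm <- sample(8)
    gp <- igraph::permute(g, perm)
    expect_equal(computeStats(gp, all_stats), computeStats(g, all_stats))
  }
})

test_that("change statistics equal full-recount differences", {
  # empty graph: the first edge adds one edge and one zero-shared-partner
  # edge (esp0); no stars, null partners, or cycles
  e10 <- graphFromEdges(10, NULL)
  d <- changeStats(e10, c(3, 7), all_stats)
  expect_equal(d[["edges"]], 1)
  expect_equal(d[["esp0"]], 1)
  expect_equal(sum(abs(d[setdiff(all_stats, c("edges", "esp0"))])), 0)

  # randomized equivalence, >= 1000 toggles on 8-node graphs
  set.seed(103)
  for (i in 1:250) {
    g <- random_graph(8, runif(1, 0.15, 0.8))
    for (r in 1:4) {
      dy <- sample(8, 2)
      delta <- changeStats(g, dy, all_stats)
      recount <- computeStats(toggle_dyad(g, dy), all_stats) -
        computeStats(g, all_stats)
      expect_equal(delta, recount)
    }
  }
})

test_that("invalid inputs are rejected with named errors", {
  g <- makeFixture("four-node-example")
  expect_error(computeStatistic(g, "fourstar"), "unknown statistic")
  expect_error(computeStats(g, c("edges", "edges")), "unique")
  expect_error(changeStats(g, c(2, 2), "edges"), "self-loop")
  expect_error(changeStats(g, c(1, 9), "edges"), "range")
  expect_error(graphFromEdges(3, rbind(c(0, 0))), "self-loops")
  expect_error(graphFromEdges(3, rbind(c(0, 1), c(1, 0))), "duplicate")
})

test_that("edge-list and GraphML I/O round-trip, keeping isolated nodes", {
  g <- igraph::add_vertices(buildFibril("2-ribbon", 4), 3)
  p1 <- withr::local_tempfile(fileext = ".txt")
  writeEdgeList(g, p1)
  g1 <- readEdgeList(p1)
  expect_equal(igraph::vcount(g1), igraph::vcount(g))
  expect_equal(computeStats(g1, all_stats), computeStats(g, all_stats))

  p2 <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(g, p2)
  g2 <- readGraphML(p2)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(computeStats(g2, all_stats), computeStats(g, all_stats))
})
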