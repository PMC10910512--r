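# Independent oracles: brute-force statistic counting on small graphs,
# kept deliberately separate from the package's C++ implementation.

# shared-partner and star statistics via the adjacency matrix
oracle_pair_stats <- function(g) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  CN <- A %*% A
  out <- c(edges = sum(A) / 2,
           twostar = sum(choose(rowSums(A), 2)),
           nsp1 = 0, nsp2 = 0, esp0 = 0, esp1 = 0)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      k <- CN[i, j]
      if (A[i, j] == 1) {
        if (k == 0) out[["esp0"]] <- out[["esp0"]] + 1
        if (k == 1) out[["esp1"]] <- out[["esp1"]] + 1
      } else {
        if (k == 1) out[["nsp1"]] <- out[["nsp1"]] + 1
        if (k == 2) out[["nsp2"]] <- out[["nsp2"]] + 1
      }
    }
  }
  out
}

# simple cycles of length k, each counted once, via igraph ring
# subisomorphism counting (2k automorphisms per cycle)
oracle_cycles <- function(g, k) {
  if (igraph::vcount(g) < k) return(0)
  igraph::count_subgraph_isomorphisms(igraph::make_ring(k), g) / (2 * k)
}

oracle_stats <- function(g, spec) {
  ps <- oracle_pair_stats(g)
  vapply(spec, function(nm) {
    if (nm %in% names(ps)) return(unname(ps[[nm]]))
    k <- as.integer(sub("cycle", "", nm))
    oracle_cycles(g, k)
  }, numeric(1))
}

random_graph <- function(n, p) igraph::sample_gnp(n, p)

toggle_dyad <- function(g, d) {
  if (igraph::are_adjacent(g, d[1], d[2]))
    igraph::delete_edges(g, igraph::get_edge_ids(g, d))
  else igraph::add_edges(g, d)
}

all_stats <- supportedStatistics()
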