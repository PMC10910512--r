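#' @useDynLib fibrilNHM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# internal statistic codes, kept in sync with src/nhm_core.cpp
.stat_codes <- c(edges = 0L, twostar = 1L, nsp1 = 2L, nsp2 = 3L,
                 esp0 = 4L, esp1 = 5L, cycle3 = 6L, cycle5 = 7L,
                 cycle6 = 8L, cycle7 = 9L)

#' Supported sufficient statistics
#'
#' The topological sufficient statistics available for network Hamiltonian
#' models: \code{edges} (edge count), \code{twostar} (nodes bonded to an
#' unordered pair of partners, \eqn{\sum_v {deg(v) \choose 2}}), \code{nsp1}
#' and \code{nsp2} (non-adjacent node pairs with exactly 1 or 2 shared
#' partners), \code{esp0} and \code{esp1} (edges whose endpoints have exactly
#' 0 or 1 shared partners), and \code{cycle3}, \code{cycle5}, \code{cycle6},
#' \code{cycle7} (simple cycles of that exact length, each counted once).
#'
#' @return character vector of statistic names, in canonical order.
#' @export
#' @examples
#' supportedStatistics()
supportedStatistics <- function() names(.stat_codes)

.check_spec <- function(spec) {
  if (!is.character(spec) || length(spec) == 0L)
    stop("statistic specification must be a nonempty character vector")
  bad <- setdiff(spec, supportedStatistics())
  if (length(bad))
    stop("unknown statistic name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(spec))
    stop("statistic names must be unique")
  invisible(spec)
}

# igraph -> (n, 0-based edge matrix); validates simplicity
.graph_data <- function(g) {
  if (!igraph::is_igraph(g))
    stop("expected an igraph graph")
  if (igraph::is_directed(g))
    stop("graphs must be undirected")
  if (!igraph::is_simple(g))
    stop("graphs must be simple (no loops or multi-edges)")
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  list(n = igraph::vcount(g), edges = el - 1L)
}

#' Build a graph from a 0-based edge list
#'
#' Thin constructor used throughout the package: nodes are \code{0:(n-1)} in
#' files and at the C++ layer, and vertices \code{1:n} in the returned
#' \code{igraph} object (igraph's convention).
#'
#' @param n number of nodes.
#' @param edges two-column matrix of 0-based node indices (or a zero-row
#'   matrix for the empty graph).
#' @return an undirected simple \code{igraph} graph on \code{n} vertices.
#' @export
#' @examples
#' g <- graphFromEdges(4, rbind(c(0, 1), c(0, 2), c(0, 3), c(2, 3)))
graphFromEdges <- function(n, edges) {
  if (is.null(edges) || length(edges) == 0L)
    edges <- matrix(integer(0), ncol = 2)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns")
  if (nrow(edges)) {
    if (any(edges < 0) || any(edges >= n))
      stop("edge endpoints must lie in [0, n)")
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, as.vector(t(edges + 1L)))
  g
}

#' Compute one sufficient statistic
#'
#' Exact count of subgraphs of the named type in \code{g}; see
#' \code{\link{supportedStatistics}} for definitions.
#'
#' @param g an undirected simple \code{igraph} graph.
#' @param name a single statistic name.
#' @return the count (numeric scalar).
#' @export
#' @examples
#' g <- makeFixture("four-node-example")
#' computeStatistic(g, "nsp1")  # 2
computeStatistic <- function(g, name) {
  if (length(name) != 1L) stop("name must be a single statistic name")
  .check_spec(name)
  gd <- .graph_data(g)
  as.numeric(cpp_compute_stats(gd$n, gd$edges, .stat_codes[[name]]))
}

#' Compute a statistic vector
#'
#' @param g an undirected simple \code{igraph} graph.
#' @param spec ordered character vector of statistic names.
#' @return named numeric vector of counts, aligned with \code{spec}.
#' @export
#' @examples
#' g <- makeFixture("four-node-example")
#' computeStats(g, c("edges", "twostar", "nsp1", "esp0", "cycle3"))
computeStats <- function(g, spec) {
  .check_spec(spec)
  gd <- .graph_data(g)
  setNames(as.numeric(cpp_compute_stats(gd$n, gd$edges,
                                        unname(.stat_codes[spec]))), spec)
}

#' Change statistics for an edge toggle
#'
#' Difference \eqn{t(g') - t(g)} where \eqn{g'} is \code{g} with the dyad
#' toggled (edge added if absent, removed if present), computed from the
#' local neighborhood only — this is the quantity the Metropolis-Hastings
#' sampler evaluates per proposal.
#'
#' @param g an undirected simple \code{igraph} graph.
#' @param dyad integer vector of two distinct vertex ids (1-based, igraph
#'   convention).
#' @param spec ordered character vector of statistic names.
#' @return named numeric vector of signed changes, aligned with \code{spec}.
#' @export
#' @examples
#' g <- makeFixture("four-node-example")
#' changeStats(g, c(1, 2), c("edges", "twostar", "nsp1"))
changeStats <- function(g, dyad, spec) {
  .check_spec(spec)
  dyad <- as.integer(dyad)
  if (length(dyad) != 2L || anyNA(dyad)) stop("dyad must be two vertex ids")
  if (dyad[1] == dyad[2]) stop("self-loop dyad is not allowed")
  gd <- .graph_data(g)
  if (any(dyad < 1L) || any(dyad > gd$n)) stop("dyad out of range")
  setNames(as.numeric(cpp_change_stats(gd$n, gd$edges, dyad[1] - 1L,
                                       dyad[2] - 1L,
                                       unname(.stat_codes[spec]))), spec)
}

#' Read and write graphs
#'
#' Edge-list files are whitespace-delimited with one \code{"u v"} pair per
#' line and 0-based node indices; isolated trailing nodes are recovered from
#' \code{n} (stored as a \code{# n <N>} header line by
#' \code{writeEdgeList}). GraphML I/O is delegated to igraph.
#'
#' @param path file path.
#' @param n number of nodes; if \code{NULL}, taken from the file header or
#'   inferred as max index + 1.
#' @param g an undirected simple \code{igraph} graph.
#' @return \code{readEdgeList} and \code{readGraphML} return an
#'   \code{igraph} graph; the writers return \code{path} invisibly.
#' @name graph_io
#' @examples
#' g <- buildFibril(fibrilTemplate("1-ribbon"), 6)
#' p <- tempfile(fileext = ".txt")
#' writeEdgeList(g, p)
#' identical(computeStats(readEdgeList(p), "edges"), computeStats(g, "edges"))
NULL

#' @rdname graph_io
#' @export
readEdgeList <- function(path, n = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(n) && length(hdr)) {
    m <- regmatches(hdr, regexec("^#\\s*n\\s+(\\d+)", hdr))
    hit <- vapply(m, length, 1L) == 2L
    if (any(hit)) n <- as.integer(m[hit][[1]][2])
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines)) {
    el <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(x) {
      if (length(x) != 2L) stop("malformed edge-list line: ", paste(x, collapse = " "))
      as.integer(x)
    }))
  } else el <- matrix(integer(0), ncol = 2)
  if (is.null(n)) n <- if (nrow(el)) max(el) + 1L else 0L
  graphFromEdges(n, el)
}

#' @rdname graph_io
#' @export
writeEdgeList <- function(g, path) {
  gd <- .graph_data(g)
  lines <- c(sprintf("# n %d", gd$n),
             if (nrow(gd$edges)) paste(gd$edges[, 1], gd$edges[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname graph_io
#' @export
readGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  g
}

#' @rdname graph_io
#' @export
writeGraphML <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
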