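# The five periodic fibril topologies as graph templates, perfect-fibril
# construction, and the fibril-fraction assay.

# default edge rules; strand indices 0-based, di = axial offset
.template_defs <- list(
  "1-ribbon" = list(strands = 1L, offsets = data.frame(
    a = 0L, b = 0L, di = 1L)),
  "2-ribbon" = list(strands = 2L, offsets = data.frame(
    a  = c(0L, 1L, 0L),
    b  = c(0L, 1L, 1L),
    di = c(1L, 1L, 0L))),
  "1,2 2-ribbon" = list(strands = 2L, offsets = data.frame(
    a  = c(0L, 1L, 0L, 0L),
    b  = c(0L, 1L, 1L, 1L),
    di = c(1L, 1L, 0L, 1L))),
  "double 1,2 2-ribbon" = list(strands = 4L, offsets = data.frame(
    a  = c(0L, 1L, 2L, 3L, 0L, 2L, 1L, 0L, 2L),
    b  = c(0L, 1L, 2L, 3L, 1L, 3L, 2L, 1L, 3L),
    di = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L))),
  "3-prism" = list(strands = 3L, offsets = data.frame(
    a  = c(0L, 1L, 2L, 0L, 1L, 0L),
    b  = c(0L, 1L, 2L, 1L, 2L, 2L),
    di = c(1L, 1L, 1L, 0L, 0L, 0L))))

#' Fibril topology templates
#'
#' Returns one of the five built-in periodic fibril templates — 1-ribbon
#' (a single bonded strand), 2-ribbon (a ladder of two strands), 1,2
#' 2-ribbon (the steric-zipper-like ladder with one diagonal bond family),
#' double 1,2 2-ribbon (two 1,2 2-ribbons joined by rungs), and 3-prism
#' (three strands closed into triangles) — or builds a custom template from
#' explicit edge rules. Templates are data: the built-in rule sets can be
#' overridden via the \code{strands}/\code{offsets} arguments.
#'
#' @param name template name (or slug such as \code{"12ribbon"}); ignored as
#'   a lookup key when \code{offsets} is supplied.
#' @param strands,offsets custom template definition: number of strands and
#'   a data.frame with columns \code{a}, \code{b} (0-based strand indices)
#'   and \code{di} (axial offset, 0 or 1); rule \code{(a, b, di)} bonds node
#'   \code{(a, i)} to node \code{(b, i + di)}.
#' @param minUnits minimum repeat units a matched region must span to count
#'   as fibril; default 3.
#' @return a \code{\linkS4class{FibrilTemplate}}.
#' @export
#' @examples
#' fibrilTemplate("3-prism")
fibrilTemplate <- function(name, strands = NULL, offsets = NULL,
                           minUnits = 3L) {
  if (is(name, "FibrilTemplate")) return(name)
  if (is.null(offsets)) {
    cname <- .canonical_topology(name)
    def <- .template_defs[[cname]]
    return(new("FibrilTemplate", name = cname, strands = def$strands,
               offsets = def$offsets, minUnits = as.integer(minUnits)))
  }
  offsets <- as.data.frame(offsets)
  offsets[] <- lapply(offsets, as.integer)
  new("FibrilTemplate", name = as.character(name),
      strands = as.integer(strands), offsets = offsets,
      minUnits = as.integer(minUnits))
}

# interior degree by strand: how many template edges touch a node of strand
# s once the fibril extends in both axial directions
templateInteriorDegrees <- function(template) {
  off <- template@offsets
  vapply(seq_len(template@strands) - 1L, function(s)
    sum(off$a == s) + sum(off$b == s), 1L)
}

#' Build a perfect fibril graph
#'
#' Realizes \code{units} repeat units of a template as an \code{igraph}
#' graph on \code{strands(template) * units} nodes, with exactly the
#' template edges and no others. With \code{cyclic = TRUE} the axial
#' direction wraps around (the closed-ring fibrils that equilibrium
#' simulations commonly produce); wrapping needs at least 3 units.
#'
#' Node \code{(strand s, unit i)} is vertex \code{(i - 1) * strands + s + 1}
#' (unit-major order).
#'
#' @param template a \code{\linkS4class{FibrilTemplate}} or template name.
#' @param units number of repeat units (>= 1).
#' @param cyclic wrap the fibril into a closed ring?
#' @return an \code{igraph} graph.
#' @export
#' @examples
#' buildFibril("2-ribbon", 5)            # ladder: 13 edges
#' buildFibril("3-prism", 4, cyclic = TRUE)
buildFibril <- function(template, units, cyclic = FALSE) {
  template <- fibrilTemplate(template)
  units <- as.integer(units)
  if (is.na(units) || units < 1L) stop("units must be >= 1")
  if (cyclic && units < 3L)
    stop("cyclic fibrils need at least 3 units to wrap")
  S <- template@strands
  off <- template@offsets
  idx <- function(s, i) (i - 1L) * S + s  # 0-based node index
  edges <- NULL
  for (i in seq_len(units)) {
    j <- i + off$di
    wrap <- j > units
    j[wrap] <- j[wrap] - units
    keep <- !wrap | cyclic
    if (any(keep))
      edges <- rbind(edges, cbind(idx(off$a[keep], i),
                                  idx(off$b[keep], j[keep])))
  }
  graphFromEdges(S * units, edges)
}

#' Fibril-fraction assay
#'
#' \code{fibrilNodes} returns every node that belongs to a region of
#' perfect fibril under the template: the node must sit at an interior
#' (non-terminal) position of an embedded segment of at least
#' \code{minUnits(template)} repeat units in which all template edges are
#' present, and must carry no edges beyond its complete interior template
#' neighborhood (strict matching — its degree equals the template's interior
#' degree for its strand). Interior-node counting deliberately undercounts
#' fibril ends. \code{fibrilFraction} is the count of such nodes divided by
#' the total number of nodes; \code{fibrilAssay} returns both.
#'
#' @param g an undirected simple \code{igraph} graph.
#' @param template a \code{\linkS4class{FibrilTemplate}} or template name.
#' @return \code{fibrilNodes}: integer vector of fibrillar vertex ids
#'   (1-based); \code{fibrilFraction}: numeric in \code{[0, 1]};
#'   \code{fibrilAssay}: list with elements \code{nodes} and
#'   \code{fraction}.
#' @export
#' @examples
#' g <- buildFibril("1-ribbon", 10)        # linear 10-node chain
#' fibrilFraction(g, "1-ribbon")           # 0.8: the 8 non-terminal nodes
fibrilNodes <- function(g, template) {
  template <- fibrilTemplate(template)
  gd <- .graph_data(g)
  if (gd$n == 0L) return(integer(0))
  off <- template@offsets
  intra <- as.matrix(off[off$di == 0L, c("a", "b"), drop = FALSE])
  inter <- as.matrix(off[off$di == 1L, c("a", "b"), drop = FALSE])
  storage.mode(intra) <- "integer"
  storage.mode(inter) <- "integer"
  cpp_fibril_nodes(gd$n, gd$edges, template@strands, intra, inter,
                   templateInteriorDegrees(template),
                   template@minUnits) + 1L
}

#' @rdname fibrilNodes
#' @export
fibrilFraction <- function(g, template) {
  n <- igraph::vcount(g)
  if (n == 0L) return(0)
  length(fibrilNodes(g, template)) / n
}

#' @rdname fibrilNodes
#' @export
fibrilAssay <- function(g, template) {
  nodes <- fibrilNodes(g, template)
  n <- igraph::vcount(g)
  list(nodes = nodes, fraction = if (n) length(nodes) / n else 0)
}
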