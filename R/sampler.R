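# Metropolis-Hastings edge-toggle sampler for the network Hamiltonian
# distribution P(g) proportional to exp(theta' t(g)).

#' Sampler configuration
#'
#' @param burninProposals number of uniform-random dyad-toggle proposals per
#'   draw; default \code{50 * choose(n, 2)}, i.e. on the order of fifty
#'   expected toggles per dyad.
#' @param seed integer RNG seed for the draw.
#' @param init initial graph: \code{"empty"} (a fully disaggregated monomer
#'   system, the default) or an \code{igraph} graph on the right number of
#'   nodes.
#' @param maxEdgesGuard degeneracy guard: the draw aborts with an error of
#'   class \code{nhmDegeneracyError} if the edge count ever exceeds this;
#'   default \code{8 * n}. Runaway densification is the classic failure mode
#'   of 2-star-driven exponential random graph models, and parameter
#'   searches must survive visits to such regions.
#' @param swapFraction fraction of proposals that are degree-preserving
#'   double-edge swaps rather than single-dyad toggles (default 0.5; 0 gives
#'   the pure toggle kernel). Both proposal types are symmetric and target
#'   the same distribution; swaps cancel the degree-dependent terms of the
#'   Hamiltonian and let locally ordered (fibrillar) states anneal in at
#'   fixed edge count, where single toggles alone must cross heavily
#'   penalized degree-defect states.
#' @return a list of class \code{samplerConfig}.
#' @export
samplerConfig <- function(burninProposals = NULL, seed = 1L, init = "empty",
                          maxEdgesGuard = NULL, swapFraction = 0.5) {
  if (!is.null(burninProposals) &&
      (!is.finite(burninProposals) || burninProposals < 1))
    stop("burninProposals must be >= 1")
  if (!is.finite(swapFraction) || swapFraction < 0 || swapFraction > 1)
    stop("swapFraction must lie in [0, 1]")
  structure(list(burninProposals = burninProposals, seed = as.integer(seed),
                 init = init, maxEdgesGuard = maxEdgesGuard,
                 swapFraction = swapFraction),
            class = "samplerConfig")
}

#' Metropolis-Hastings log acceptance ratio
#'
#' For a symmetric proposal toggling one dyad, the log acceptance ratio is
#' \eqn{\theta^T \Delta t}; the proposal is accepted with probability
#' \eqn{\min(1, e^{\theta^T \Delta t})}.
#'
#' @param theta named theta vector.
#' @param delta named change-statistic vector (as from
#'   \code{\link{changeStats}}); names must match \code{theta}.
#' @return numeric scalar log ratio.
#' @export
#' @examples
#' mhLogRatio(c(edges = -2), c(edges = 1))
mhLogRatio <- function(theta, delta) {
  if (length(theta) != length(delta) ||
      !identical(names(theta), names(delta)))
    stop("theta and delta must be aligned (same names, same order)")
  sum(theta * delta)
}

.degeneracy_error <- function(nNodes, guard) {
  structure(class = c("nhmDegeneracyError", "error", "condition"),
            list(message = sprintf(
              paste0("degenerate densification: edge count exceeded the ",
                     "guard of %g on %d nodes"), guard, nNodes),
              call = NULL))
}

#' Draw one equilibrium graph
#'
#' Runs \code{burninProposals} Metropolis-Hastings proposals, each toggling
#' a uniformly chosen dyad and accepted with probability
#' \eqn{\min(1, e^{\theta^T \Delta t})}, starting from the configured
#' initial graph. Statistics are maintained incrementally via change
#' statistics; the returned vector equals a full recount of the final graph.
#'
#' @param model an \code{\linkS4class{NHModel}}; coefficients are converted
#'   with \code{\link{phiToTheta}} at \code{nNodes} unless \code{theta} is
#'   given.
#' @param nNodes system size (nodes).
#' @param config a \code{\link{samplerConfig}}.
#' @param theta optional explicit named theta vector overriding the model
#'   conversion (used, e.g., to pin the edge coordinate).
#' @return an \code{\linkS4class{NHDraw}}.
#' @export
#' @examples
#' d <- simulateDraw(modelPreset("1-ribbon"), 32,
#'                   samplerConfig(burninProposals = 2e4, seed = 7))
simulateDraw <- function(model, nNodes, config = samplerConfig(),
                         theta = NULL) {
  stopifnot(is(model, "NHModel"))
  nNodes <- as.integer(nNodes)
  if (is.na(nNodes) || nNodes < 2L) stop("nNodes must be >= 2")
  spec <- model@statNames
  if (is.null(theta)) theta <- phiToTheta(model, nNodes)
  if (!identical(names(theta), spec))
    stop("theta must be aligned with the model's statistics")
  burnin <- config$burninProposals
  if (is.null(burnin)) burnin <- 50 * choose(nNodes, 2)
  guard <- config$maxEdgesGuard
  if (is.null(guard)) guard <- 8 * nNodes
  init <- config$init
  if (identical(init, "empty")) {
    initEdges <- matrix(integer(0), ncol = 2)
  } else {
    gd <- .graph_data(init)
    if (gd$n != nNodes) stop("init graph must have nNodes nodes")
    initEdges <- gd$edges
  }
  swapFraction <- config$swapFraction
  if (is.null(swapFraction)) swapFraction <- 0.5
  res <- cpp_simulate(nNodes, initEdges, unname(.stat_codes[spec]),
                      unname(theta), burnin, as.integer(config$seed), guard,
                      swapFraction)
  if (isTRUE(res$degenerate)) stop(.degeneracy_error(nNodes, guard))
  new("NHDraw", graph = graphFromEdges(nNodes, res$edges),
      stats = setNames(as.numeric(res$stats), spec),
      accepted = res$accepted, proposed = res$proposed,
      seed = as.integer(config$seed))
}

# deterministic per-replicate seed stream; all arithmetic stays < 2^53 so
# the doubles are exact, and results stay inside 32-bit integer range
.derive_seeds <- function(masterSeed, k, salt = 0) {
  m <- 2147483647
  base <- (abs(as.numeric(masterSeed)) + salt * 2654435761) %% m
  as.integer((base + seq_len(k) * 1103515245) %% m) + 1L
}

#' Draw an ensemble of independent equilibrium graphs
#'
#' \code{reps} independent draws whose per-replicate seeds are derived
#' deterministically from \code{masterSeed}; results do not depend on
#' evaluation order and are bitwise reproducible.
#'
#' @inheritParams simulateDraw
#' @param reps number of draws.
#' @param masterSeed integer master seed.
#' @param ... further arguments passed to \code{\link{simulateDraw}}
#'   (e.g. \code{theta}).
#' @param config a \code{\link{samplerConfig}} whose \code{seed} field is
#'   ignored in favor of the derived per-replicate seeds.
#' @param onDegeneracy \code{"error"} to propagate degeneracy errors, or
#'   \code{"null"} to return \code{NULL} for degenerate replicates.
#' @return list of \code{\linkS4class{NHDraw}} (with \code{NULL} entries for
#'   degenerate replicates when \code{onDegeneracy = "null"}).
#' @export
simulateEnsemble <- function(model, nNodes, reps, masterSeed = 1L,
                             config = samplerConfig(),
                             onDegeneracy = c("error", "null"), ...) {
  onDegeneracy <- match.arg(onDegeneracy)
  if (reps < 1) stop("reps must be >= 1")
  seeds <- .derive_seeds(masterSeed, reps)
  lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    if (onDegeneracy == "error") simulateDraw(model, nNodes, cfg, ...)
    else tryCatch(simulateDraw(model, nNodes, cfg, ...),
                  nhmDegeneracyError = function(e) NULL)
  })
}
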