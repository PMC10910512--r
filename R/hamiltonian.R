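# Parameter vectors, the network Hamiltonian energy, phi <-> theta
# conversion, and system-size edge offsets.

#' Construct a network Hamiltonian model
#'
#' @param phi named numeric vector of coefficients in physical form (units
#'   of \eqn{k_B T}); names must be supported statistic names and define the
#'   statistic order of the model.
#' @param statNames optional explicit statistic order; defaults to
#'   \code{names(phi)}.
#' @param kBT thermal scale, default 1.
#' @return an \code{\linkS4class{NHModel}}.
#' @export
#' @examples
#' m <- nhmModel(c(edges = -107.22, twostar = 37.33, nsp1 = 1.35))
nhmModel <- function(phi, statNames = names(phi), kBT = 1) {
  if (is.null(statNames))
    stop("phi must be named (or statNames supplied)")
  .check_spec(statNames)
  phi <- phi[statNames]
  if (anyNA(phi)) stop("phi must supply a coefficient for every statistic")
  new("NHModel", statNames = statNames,
      phi = setNames(as.numeric(phi), statNames), kBT = as.numeric(kBT))
}

#' Network Hamiltonian energy of a graph
#'
#' \eqn{H(g) = \sum_X \phi_X t_X(g)}, the energy that the model's Boltzmann
#' distribution \eqn{P(g) \propto \exp(-H(g)/k_B T)} penalizes.
#'
#' @param g an undirected simple \code{igraph} graph.
#' @param model an \code{\linkS4class{NHModel}}.
#' @return numeric scalar energy, in units of \eqn{k_B T}.
#' @export
#' @examples
#' energy(makeFixture("four-node-example"), modelPreset("1-ribbon"))
energy <- function(g, model) {
  stopifnot(is(model, "NHModel"))
  sum(model@phi * computeStats(g, model@statNames))
}

#' Convert physical coefficients to simulation (theta) form
#'
#' The sampler works with the statistical parameterization
#' \eqn{P(g) \propto \exp(\theta^T t(g))}. For \eqn{k_B T = 1} the
#' conversion is \eqn{\theta_X = -\phi_X} for every statistic except edges;
#' the edge coordinate additionally absorbs a system-size offset,
#' \eqn{\theta_e = -(\phi_e + c - \ln N)} with offset constant \eqn{c = 1}
#' by default (set \code{edgeOffset = FALSE} for the plain
#' \eqn{\theta = -\phi} conversion).
#'
#' @param model an \code{\linkS4class{NHModel}}.
#' @param nNodes system size \eqn{N} (nodes), at least 2.
#' @param edgeOffset apply the size offset to the edge coordinate?
#' @param offsetConst the additive constant in the edge offset (default 1).
#' @return named numeric theta vector aligned with \code{statNames(model)}.
#' @export
#' @examples
#' phiToTheta(modelPreset("1-ribbon"), 256)
phiToTheta <- function(model, nNodes, edgeOffset = TRUE, offsetConst = 1) {
  stopifnot(is(model, "NHModel"))
  nNodes <- as.integer(nNodes)
  if (is.na(nNodes) || nNodes < 2L) stop("nNodes must be >= 2")
  theta <- -model@phi
  if (edgeOffset && "edges" %in% model@statNames)
    theta[["edges"]] <- -(model@phi[["edges"]] + offsetConst - log(nNodes))
  theta
}

#' Rescale an edge coefficient between system sizes
#'
#' Log-of-size (Krivitsky-type) offset that transfers a model fitted on an
#' \code{nFrom}-node system to an \code{nTo}-node system:
#' \eqn{\phi_e' = \phi_e + \ln(nFrom) - \ln(nTo)}. All other coefficients
#' transfer unchanged.
#'
#' @param phiE edge coefficient in physical form.
#' @param nFrom,nTo system sizes (nodes), both at least 2.
#' @return the rescaled edge coefficient.
#' @export
#' @examples
#' rescaleEdgePhi(-107.22, 48, 256)
rescaleEdgePhi <- function(phiE, nFrom, nTo) {
  if (nFrom < 2 || nTo < 2) stop("system sizes must be >= 2")
  phiE + log(nFrom) - log(nTo)
}

# Coefficients (phi form) with the highest mean fibril fractions found by
# the genetic algorithm, per topology; zero-coefficient statistics trimmed.
.model_presets <- list(
  "1-ribbon" = c(edges = -107.22, twostar = 37.33, nsp1 = 1.35),
  "2-ribbon" = c(edges = -102.28, twostar = 25.2, nsp1 = -0.44,
                 nsp2 = -5.56),
  "1,2 2-ribbon" = c(edges = -158.21, twostar = 27.28, nsp1 = 1.87,
                     nsp2 = -7.12, esp0 = 6.59),
  "double 1,2 2-ribbon" = c(edges = -471.95, twostar = 65.31, nsp1 = -0.25,
                            nsp2 = -23.99, esp0 = 75.18, esp1 = 62.03),
  "3-prism" = c(edges = -193.35, twostar = 38.13, nsp1 = -5.77,
                nsp2 = -14.7, esp0 = -2.51, esp1 = -11.14,
                cycle5 = 0.12, cycle6 = 0.69, cycle7 = -0.02))

# short slugs accepted wherever a topology name is expected
.topology_slugs <- c("1ribbon" = "1-ribbon", "2ribbon" = "2-ribbon",
                     "12ribbon" = "1,2 2-ribbon",
                     "double12ribbon" = "double 1,2 2-ribbon",
                     "3prism" = "3-prism")

.canonical_topology <- function(name) {
  if (name %in% names(.topology_slugs)) return(.topology_slugs[[name]])
  if (name %in% unname(.topology_slugs)) return(name)
  stop("unknown fibril topology '", name, "'; expected one of: ",
       paste(unname(.topology_slugs), collapse = ", "))
}

#' Shipped model presets
#'
#' \code{modelPreset} returns the optimized coefficient set for one of the
#' five fibril topologies as an \code{\linkS4class{NHModel}} (statistics
#' with zero coefficients trimmed); \code{presetNames} lists the available
#' topologies. Short slugs ("1ribbon", "12ribbon", ...) are accepted.
#'
#' @param name topology name, one of \code{presetNames()}.
#' @return an \code{NHModel} (\code{modelPreset}) or character vector
#'   (\code{presetNames}).
#' @export
#' @examples
#' modelPreset("3-prism")
modelPreset <- function(name) {
  nhmModel(.model_presets[[.canonical_topology(name)]])
}

#' @rdname modelPreset
#' @export
presetNames <- function() names(.model_presets)
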