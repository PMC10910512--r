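#' @import methods
#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils write.csv read.csv
NULL

#' Network Hamiltonian model
#'
#' An \code{NHModel} bundles an ordered set of sufficient-statistic names, a
#' coefficient vector \eqn{\phi} in physical (energy) form, and the thermal
#' scale \eqn{k_B T}. The model assigns a graph \eqn{g} the energy
#' \eqn{H(g) = \sum_X \phi_X t_X(g)} and hence the Boltzmann-type probability
#' \eqn{P(g) \propto \exp(-H(g)/k_B T)} over simple undirected graphs on a
#' fixed node set (uniform reference measure).
#'
#' @slot statNames ordered character vector of statistic names (see
#'   \code{\link{supportedStatistics}}).
#' @slot phi named numeric vector of coefficients, units of \eqn{k_B T},
#'   aligned with \code{statNames}.
#' @slot kBT positive numeric; thermal energy scale (default 1).
#' @seealso \code{\link{nhmModel}}, \code{\link{modelPreset}},
#'   \code{\link{energy}}, \code{\link{phiToTheta}}
#' @export
setClass("NHModel",
  representation(statNames = "character", phi = "numeric", kBT = "numeric"),
  validity = function(object) {
    msg <- character()
    bad <- setdiff(object@statNames, supportedStatistics())
    if (length(bad))
      msg <- c(msg, paste0("unknown statistic name(s): ",
                           paste(bad, collapse = ", ")))
    if (anyDuplicated(object@statNames))
      msg <- c(msg, "statistic names must be unique")
    if (length(object@statNames) == 0L)
      msg <- c(msg, "at least one statistic is required")
    if (length(object@phi) != length(object@statNames))
      msg <- c(msg, "phi length must match statNames")
    if (!all(is.finite(object@phi)))
      msg <- c(msg, "phi coefficients must be finite")
    if (length(object@kBT) != 1L || !is.finite(object@kBT) || object@kBT <= 0)
      msg <- c(msg, "kBT must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Periodic fibril topology template
#'
#' A \code{FibrilTemplate} describes one of the periodic amyloid fibril
#' topologies as an infinite graph generated by a repeat unit of
#' \code{strands} nodes and a set of edge rules. Rule \code{(a, b, di)}
#' places an edge between node \code{(a, i)} (strand \code{a}, repeat unit
#' \code{i}) and node \code{(b, i + di)} for every unit \code{i}. Axial
#' offsets are restricted to \code{di} of 0 (within a unit) and 1 (between
#' consecutive units), which covers the five experimentally observed
#' topologies.
#'
#' @slot name template name.
#' @slot strands number of strands (nodes per repeat unit).
#' @slot offsets data.frame with integer columns \code{a}, \code{b},
#'   \code{di}; strand indices are 0-based.
#' @slot minUnits minimum number of repeat units a matched region must span
#'   to count as fibril (default 3).
#' @seealso \code{\link{fibrilTemplate}}, \code{\link{buildFibril}},
#'   \code{\link{fibrilFraction}}
#' @export
setClass("FibrilTemplate",
  representation(name = "character", strands = "integer",
                 offsets = "data.frame", minUnits = "integer"),
  validity = function(object) {
    msg <- character()
    off <- object@offsets
    if (!all(c("a", "b", "di") %in% names(off)))
      msg <- c(msg, "offsets needs columns a, b, di")
    else {
      if (nrow(off) == 0L) msg <- c(msg, "at least one edge rule is required")
      if (any(off$a < 0 | off$a >= object@strands |
              off$b < 0 | off$b >= object@strands))
        msg <- c(msg, "strand indices must lie in [0, strands)")
      if (!all(off$di %in% c(0L, 1L)))
        msg <- c(msg, "axial offsets must be 0 or 1")
      if (any(off$di == 0L & off$a == off$b))
        msg <- c(msg, "offset-0 rules may not be self-rules")
      key <- paste(pmin(off$a, off$b), pmax(off$a, off$b), off$di)
      if (anyDuplicated(key[off$di == 0L]))
        msg <- c(msg, "duplicate offset-0 rule")
    }
    if (object@strands < 1L) msg <- c(msg, "strands must be >= 1")
    if (object@minUnits < 1L) msg <- c(msg, "minUnits must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' One equilibrium draw from the sampler
#'
#' @slot graph the sampled \code{igraph} graph.
#' @slot stats named numeric vector: sufficient statistics of \code{graph},
#'   maintained incrementally during sampling.
#' @slot accepted number of accepted proposals.
#' @slot proposed number of proposals made.
#' @slot seed the integer seed that produced this draw.
#' @seealso \code{\link{simulateDraw}}, \code{\link{simulateEnsemble}}
#' @export
setClass("NHDraw",
  representation(graph = "ANY", stats = "numeric", accepted = "numeric",
                 proposed = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@accepted < 0 || object@accepted > object@proposed)
      "accepted must lie in [0, proposed]" else TRUE
  })

#' Genetic-algorithm configuration
#'
#' Hyperparameters of the evolutionary search. Field names follow the
#' algorithm's standard vocabulary: \code{reps} (simulations per fitness
#' evaluation), \code{noiseVarInit} (initial mutant noise variance),
#' \code{topFraction} (fraction surviving selection), \code{maxSurvivors},
#' \code{fixEdge}/\code{fixEdgeValue} (pin the edge parameter, value given in
#' theta form), \code{smartVar} (double the noise variance after a failed
#' generation), \code{smartPts} (one extra mutant per linear child after a
#' failed generation), \code{useLineDensity}/\code{minLineDensity} (children
#' per unit parent distance), and \code{childMax} (hard cap per breeding
#' pair).
#'
#' @seealso \code{\link{gaConfig}}, \code{\link{runEvolution}}
#' @export
setClass("GAConfig",
  representation(
    reps = "integer", noiseVarInit = "numeric", topFraction = "numeric",
    maxSurvivors = "integer", fixEdge = "logical", fixEdgeValue = "numeric",
    smartVar = "logical", smartPts = "logical", useLineDensity = "logical",
    minLineDensity = "numeric", linearChildren = "integer",
    childMax = "integer", maxGenerations = "integer", maxRetries = "integer",
    nNodes = "integer", statNames = "character", template = "FibrilTemplate",
    burninProposals = "numeric", maxEdgesGuard = "numeric",
    masterSeed = "integer"),
  validity = function(object) {
    msg <- character()
    pos <- c(reps = object@reps, noiseVarInit = object@noiseVarInit,
             maxSurvivors = object@maxSurvivors,
             minLineDensity = object@minLineDensity,
             linearChildren = object@linearChildren,
             childMax = object@childMax,
             maxGenerations = object@maxGenerations, nNodes = object@nNodes)
    for (nm in names(pos))
      if (!is.finite(pos[[nm]]) || pos[[nm]] <= 0)
        msg <- c(msg, paste0(nm, " must be positive"))
    if (!is.finite(object@topFraction) ||
        object@topFraction <= 0 || object@topFraction > 1)
      msg <- c(msg, "topFraction must lie in (0, 1]")
    if (object@maxRetries < 0) msg <- c(msg, "maxRetries must be >= 0")
    if (object@nNodes < 2) msg <- c(msg, "nNodes must be >= 2")
    bad <- setdiff(object@statNames, supportedStatistics())
    if (length(bad))
      msg <- c(msg, paste0("unknown statistic name(s): ",
                           paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Result of a genetic-algorithm run
#'
#' @slot generations list of per-generation state records (index, population,
#'   survivors, noise variance, mutants per linear child, best mean).
#' @slot ledger data.frame with one row per evaluated individual, including
#'   individuals from rejected generation attempts.
#' @slot best the best individual seen over the whole run.
#' @slot stalled logical; \code{TRUE} if the retry budget was exhausted
#'   before \code{maxGenerations}.
#' @slot config the \code{GAConfig} used.
#' @seealso \code{\link{runEvolution}}
#' @export
setClass("EvolutionRun",
  representation(generations = "list", ledger = "data.frame", best = "list",
                 stalled = "logical", config = "GAConfig"))
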