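#' Accessors for model and template objects
#'
#' \code{statNames} returns the ordered statistic names of a model or
#' configuration; \code{phiCoefs} the physical-form coefficient vector;
#' \code{kBT} the thermal scale; \code{templateName}, \code{strands},
#' \code{edgeOffsets} and \code{minUnits} the corresponding
#' \code{FibrilTemplate} fields; \code{drawGraph} and \code{drawStats} the
#' graph and statistic vector held by an \code{NHDraw}.
#'
#' @param object an \code{NHModel}, \code{GAConfig}, \code{FibrilTemplate}
#'   or \code{NHDraw}.
#' @return the requested component.
#' @name accessors
#' @examples
#' m <- modelPreset("1-ribbon")
#' statNames(m)
#' phiCoefs(m)
NULL

#' @rdname accessors
#' @export
setGeneric("statNames", function(object) standardGeneric("statNames"))

#' @rdname accessors
#' @export
setGeneric("phiCoefs", function(object) standardGeneric("phiCoefs"))

#' @rdname accessors
#' @export
setGeneric("kBT", function(object) standardGeneric("kBT"))

#' @rdname accessors
#' @export
setGeneric("templateName", function(object) standardGeneric("templateName"))

#' @rdname accessors
#' @export
setGeneric("strands", function(object) standardGeneric("strands"))

#' @rdname accessors
#' @export
setGeneric("edgeOffsets", function(object) standardGeneric("edgeOffsets"))

#' @rdname accessors
#' @export
setGeneric("minUnits", function(object) standardGeneric("minUnits"))

#' @rdname accessors
#' @export
setGeneric("drawGraph", function(object) standardGeneric("drawGraph"))

#' @rdname accessors
#' @export
setGeneric("drawStats", function(object) standardGeneric("drawStats"))

#' @rdname accessors
#' @export
setMethod("statNames", "NHModel", function(object) object@statNames)

#' @rdname accessors
#' @export
setMethod("statNames", "GAConfig", function(object) object@statNames)

#' @rdname accessors
#' @export
setMethod("phiCoefs", "NHModel", function(object) object@phi)

#' @rdname accessors
#' @export
setMethod("kBT", "NHModel", function(object) object@kBT)

#' @rdname accessors
#' @export
setMethod("templateName", "FibrilTemplate", function(object) object@name)

#' @rdname accessors
#' @export
setMethod("strands", "FibrilTemplate", function(object) object@strands)

#' @rdname accessors
#' @export
setMethod("edgeOffsets", "FibrilTemplate", function(object) object@offsets)

#' @rdname accessors
#' @export
setMethod("minUnits", "FibrilTemplate", function(object) object@minUnits)

#' @rdname accessors
#' @export
setMethod("drawGraph", "NHDraw", function(object) object@graph)

#' @rdname accessors
#' @export
setMethod("drawStats", "NHDraw", function(object) object@stats)

setMethod("show", "NHModel", function(object) {
  cat("NHModel with", length(object@statNames), "sufficient statistics",
      sprintf("(kBT = %g)\n", object@kBT))
  print(object@phi)
})

setMethod("show", "FibrilTemplate", function(object) {
  cat(sprintf("FibrilTemplate '%s': %d strand(s), %d edge rule(s), minUnits = %d\n",
              object@name, object@strands, nrow(object@offsets),
              object@minUnits))
  cat("interior degree by strand:",
      paste(templateInteriorDegrees(object), collapse = " "), "\n")
})

setMethod("show", "NHDraw", function(object) {
  cat(sprintf("NHDraw: %d nodes, %d edges; %d/%d proposals accepted (seed %d)\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              as.integer(object@accepted), as.integer(object@proposed),
              object@seed))
  print(object@stats)
})

setMethod("show", "GAConfig", function(object) {
  cat(sprintf(paste0(
    "GAConfig: %d nodes, reps = %d, topFraction = %g, maxSurvivors = %d\n",
    "  noiseVarInit = %g, smartVar = %s, smartPts = %s, childMax = %d\n",
    "  fixEdge = %s (theta value %g), template '%s', statistics: %s\n"),
    object@nNodes, object@reps, object@topFraction, object@maxSurvivors,
    object@noiseVarInit, object@smartVar, object@smartPts, object@childMax,
    object@fixEdge, object@fixEdgeValue, object@template@name,
    paste(object@statNames, collapse = ", ")))
})

setMethod("show", "EvolutionRun", function(object) {
  ng <- length(object@generations)
  cat(sprintf("EvolutionRun: %d generation(s), best mean fibril fraction %.4f%s\n",
              ng, object@best$mean, if (object@stalled) " (stalled)" else ""))
})
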