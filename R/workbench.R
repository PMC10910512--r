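# Configuration files, fixtures, and run outputs.

.table1_defaults <- list(reps = 16L, noiseVarInit = 1.0, topFraction = 0.25,
                         maxSurvivors = 20L, fixEdge = FALSE,
                         fixEdgeValue = 100, smartVar = TRUE, smartPts = TRUE,
                         useLineDensity = TRUE, minLineDensity = 1.2,
                         childMax = 100L)

.runconfig_keys <- c("model", "preset", "nNodes", "template", "masterSeed",
                     "outputDir", "burninProposals", "maxEdgesGuard",
                     "maxGenerations", "maxRetries", names(.table1_defaults))

#' Load, validate and save run configurations
#'
#' Run configurations are YAML mappings. Recognized keys: \code{preset} or
#' \code{model} (a mapping statistic name -> phi coefficient),
#' \code{nNodes}, \code{template}, \code{masterSeed}, \code{outputDir},
#' sampler settings (\code{burninProposals}, \code{maxEdgesGuard}), and the
#' genetic-algorithm hyperparameters under their standard names
#' (\code{reps}, \code{noiseVarInit}, \code{topFraction},
#' \code{maxSurvivors}, \code{fixEdge}, \code{fixEdgeValue},
#' \code{smartVar}, \code{smartPts}, \code{useLineDensity},
#' \code{minLineDensity}, \code{childMax}, \code{maxGenerations},
#' \code{maxRetries}). Missing hyperparameters take their typical values;
#' unknown keys and out-of-range values are rejected. Configurations
#' round-trip losslessly through \code{saveConfig}/\code{loadConfig}.
#'
#' @param path file path.
#' @param config a run-configuration list.
#' @return \code{loadConfig} and \code{asRunConfig} return a validated
#'   config list of class \code{nhmRunConfig}; \code{saveConfig} returns
#'   \code{path} invisibly.
#' @export
loadConfig <- function(path) {
  asRunConfig(yaml::read_yaml(path))
}

#' @rdname loadConfig
#' @param x a raw list to validate.
#' @export
asRunConfig <- function(x) {
  bad <- setdiff(names(x), .runconfig_keys)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (k in names(.table1_defaults))
    if (is.null(x[[k]])) x[[k]] <- .table1_defaults[[k]]
  if (is.null(x$nNodes)) x$nNodes <- 48L
  if (is.null(x$masterSeed)) x$masterSeed <- 1L
  if (is.null(x$maxGenerations)) x$maxGenerations <- 10L
  if (is.null(x$maxRetries)) x$maxRetries <- 5L
  if (!is.null(x$preset)) .canonical_topology(x$preset)
  if (!is.null(x$model)) .check_spec(names(x$model))
  if (!is.null(x$template) && is.character(x$template))
    .canonical_topology(x$template)
  if (x$topFraction <= 0 || x$topFraction > 1)
    stop("topFraction must lie in (0, 1]")
  for (k in c("reps", "maxSurvivors", "childMax", "nNodes",
              "maxGenerations", "noiseVarInit", "minLineDensity"))
    if (!is.numeric(x[[k]]) || x[[k]] <= 0)
      stop(k, " must be positive")
  structure(x, class = "nhmRunConfig")
}

#' @rdname loadConfig
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Model and GA objects from a run configuration
#'
#' \code{configModel} builds the \code{\linkS4class{NHModel}} a
#' configuration describes (preset or explicit coefficients);
#' \code{configGA} builds the corresponding
#' \code{\linkS4class{GAConfig}}.
#'
#' @param config an \code{nhmRunConfig}.
#' @return an \code{NHModel} / \code{GAConfig}.
#' @export
configModel <- function(config) {
  if (!is.null(config$preset)) return(modelPreset(config$preset))
  if (is.null(config$model)) stop("configuration has no model or preset")
  nhmModel(unlist(config$model))
}

#' @rdname configModel
#' @export
configGA <- function(config) {
  tpl <- config$template
  if (is.null(tpl)) tpl <- if (!is.null(config$preset)) config$preset
                           else "2-ribbon"
  statNames <- if (!is.null(config$model)) names(config$model)
               else statNames(configModel(config))
  gaConfig(reps = config$reps, noiseVarInit = config$noiseVarInit,
           topFraction = config$topFraction,
           maxSurvivors = config$maxSurvivors, fixEdge = config$fixEdge,
           fixEdgeValue = config$fixEdgeValue, smartVar = config$smartVar,
           smartPts = config$smartPts,
           useLineDensity = config$useLineDensity,
           minLineDensity = config$minLineDensity,
           childMax = config$childMax,
           maxGenerations = config$maxGenerations,
           maxRetries = config$maxRetries, nNodes = config$nNodes,
           statNames = statNames, template = tpl,
           burninProposals = if (is.null(config$burninProposals)) NA_real_
                             else config$burninProposals,
           maxEdgesGuard = if (is.null(config$maxEdgesGuard)) NA_real_
                           else config$maxEdgesGuard,
           masterSeed = config$masterSeed)
}

#' Built-in test fixtures
#'
#' Named, seeded inputs used by the test-suite and examples:
#' \itemize{
#'   \item \code{"four-node-example"} — the worked four-node example graph
#'     (a triangle with one pendant edge) on which every supported statistic
#'     can be checked by hand.
#'   \item \code{"perfect-<slug>-<units>"} and
#'     \code{"perfect-<slug>-<units>-cyclic"} — perfect fibrils, e.g.
#'     \code{"perfect-1ribbon-48-cyclic"}; slugs are \code{1ribbon},
#'     \code{2ribbon}, \code{12ribbon}, \code{double12ribbon},
#'     \code{3prism}.
#'   \item \code{"damaged-<slug>-<units>u-k<k>"} — a perfect cyclic fibril
#'     with \code{k} edges removed uniformly at random (reproducible given
#'     \code{seed}).
#'   \item \code{"gen0-cloud"} — a sphere-sampled generation-0 parameter
#'     cloud for the 2-ribbon search (edge parameter pinned).
#' }
#'
#' @param name fixture name.
#' @param seed seed for the randomized fixtures.
#' @return an \code{igraph} graph, or a list of individuals for
#'   \code{"gen0-cloud"}.
#' @export
#' @examples
#' fibrilFraction(makeFixture("perfect-1ribbon-48-cyclic"), "1-ribbon")
makeFixture <- function(name, seed = 1L) {
  if (name == "four-node-example") {
    # nodes A,B,C,D = 0,1,2,3; triangle A-C-D plus pendant edge A-B
    return(graphFromEdges(4, rbind(c(0L, 1L), c(0L, 2L), c(0L, 3L),
                                   c(2L, 3L))))
  }
  m <- regmatches(name, regexec("^perfect-([a-z0-9]+)-(\\d+)(-cyclic)?$", name))[[1]]
  if (length(m)) {
    return(buildFibril(.canonical_topology(m[2]), as.integer(m[3]),
                       cyclic = nzchar(m[4])))
  }
  m <- regmatches(name, regexec("^damaged-([a-z0-9]+)-(\\d+)u-k(\\d+)$", name))[[1]]
  if (length(m)) {
    g <- buildFibril(.canonical_topology(m[2]), as.integer(m[3]),
                     cyclic = TRUE)
    k <- as.integer(m[4])
    if (k > igraph::ecount(g)) stop("cannot remove more edges than exist")
    set.seed(seed)
    drop <- sample.int(igraph::ecount(g), k)
    return(igraph::delete_edges(g, drop))
  }
  if (name == "gen0-cloud") {
    cfg <- gaConfig(fixEdge = TRUE)
    return(seedSphere(cfg, radius = 40, count = 20, seed = seed))
  }
  stop("unknown fixture '", name, "'")
}

# small FNV-1a hash so outputs can record a config fingerprint without
# extra dependencies
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write simulation or evolution outputs
#'
#' For a list of draws (\code{\link{simulateEnsemble}}): one 0-based edge
#' list per draw plus a per-draw statistics table (\code{stats.csv}, with
#' fibril fractions when a template is given). For an
#' \code{\linkS4class{EvolutionRun}}: the full per-individual ledger
#' (\code{ledger.csv}), a per-generation summary
#' (\code{generations.csv}), and the best coefficient vector
#' (\code{best_model.yaml}). Every output directory also receives a
#' \code{run_log.yaml} recording the master seed and a config fingerprint,
#' so a run is replayable from its outputs alone. Numeric formatting is
#' locale-independent.
#'
#' @param results a list of \code{\linkS4class{NHDraw}} or an
#'   \code{\linkS4class{EvolutionRun}}.
#' @param dir output directory (created if needed).
#' @param config the run configuration (any list) to fingerprint.
#' @param masterSeed the master seed used.
#' @param template optional template for per-draw fibril fractions.
#' @return invisibly, the paths written.
#' @export
writeOutputs <- function(results, dir, config = list(), masterSeed = NA,
                         template = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  withr_locale <- Sys.getlocale("LC_NUMERIC")  # sanity: must be "C"/"POSIX"
  if (!withr_locale %in% c("C", "POSIX"))
    on.exit(Sys.setlocale("LC_NUMERIC", withr_locale), add = TRUE)

  if (is(results, "EvolutionRun")) {
    p <- file.path(dir, "ledger.csv")
    write.csv(results@ledger, p, row.names = FALSE)
    paths <- c(paths, p)
    gsum <- do.call(rbind, lapply(results@generations, function(g)
      data.frame(generation = g$index, populationSize = length(g$populationIds),
                 survivors = length(g$survivorIds), noiseVar = g$noiseVar,
                 mutantsPerChild = g$mutantsPerChild, bestMean = g$bestMean)))
    p <- file.path(dir, "generations.csv")
    write.csv(gsum, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, "best_model.yaml")
    yaml::write_yaml(list(phi = as.list(results@best$phi),
                          mean = results@best$mean,
                          id = results@best$id), p)
    paths <- c(paths, p)
  } else if (is.list(results) && length(results) &&
             all(vapply(results, function(x) is.null(x) || is(x, "NHDraw"),
                        TRUE))) {
    rows <- NULL
    for (i in seq_along(results)) {
      d <- results[[i]]
      if (is.null(d)) next
      p <- file.path(dir, sprintf("draw_%03d.txt", i))
      writeEdgeList(drawGraph(d), p)
      paths <- c(paths, p)
      row <- data.frame(rep = i, seed = d@seed, t(drawStats(d)),
                        accepted = d@accepted, proposed = d@proposed)
      if (!is.null(template))
        row$fibrilFraction <- fibrilFraction(drawGraph(d), template)
      rows <- rbind(rows, row)
    }
    p <- file.path(dir, "stats.csv")
    write.csv(rows, p, row.names = FALSE)
    paths <- c(paths, p)
  } else stop("unsupported results object")

  p <- file.path(dir, "run_log.yaml")
  yaml::write_yaml(list(masterSeed = masterSeed,
                        configHash = .config_hash(config),
                        package = as.character(utils::packageVersion("fibrilNHM")),
                        timestamp = "deterministic-output"), p)
  paths <- c(paths, p)
  invisible(paths)
}
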