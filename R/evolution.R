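# Genetic algorithm for network Hamiltonian parameterization: sphere-sampled
# generation 0, all-pairs line breeding with linear and mutant children,
# fitness by mean fibril fraction, top-fraction selection, generation
# rejection with smart variance/points, and parent immortality.

#' Construct a genetic-algorithm configuration
#'
#' Defaults are the algorithm's typical values: \code{reps = 16},
#' \code{noiseVarInit = 1}, \code{topFraction = 0.25},
#' \code{maxSurvivors = 20}, \code{fixEdgeValue = 100} (theta form),
#' \code{smartVar}, \code{smartPts} and \code{useLineDensity} on,
#' \code{minLineDensity = 1.2}, \code{childMax = 100}.
#'
#' @param reps simulations per fitness evaluation (mean fibril fraction).
#' @param noiseVarInit initial variance of the mutant noise, per free
#'   dimension.
#' @param topFraction fraction of a generation that survives selection.
#' @param maxSurvivors hard cap on survivors; beyond it a random subset of
#'   the top fraction is kept.
#' @param fixEdge,fixEdgeValue pin the edge parameter during evolution;
#'   \code{fixEdgeValue} is in theta form (the pinned phi coordinate is
#'   \code{-fixEdgeValue - 1 + log(nNodes)}, which converts back to exactly
#'   \code{fixEdgeValue}).
#' @param smartVar double the mutant noise variance after a rejected
#'   generation?
#' @param smartPts add one mutant per linear child after a rejected
#'   generation?
#' @param useLineDensity,minLineDensity when on, a breeding pair at
#'   parameter-space distance \code{d} produces
#'   \code{floor(minLineDensity * d)} linear children; pairs implying fewer
#'   than one child are deemed too closely related to breed.
#' @param linearChildren fixed linear-children count used when
#'   \code{useLineDensity} is off.
#' @param childMax cap on children per breeding pair; beyond it a uniform
#'   random subset is kept.
#' @param maxGenerations generations to run.
#' @param maxRetries rebreeding attempts per generation before the run is
#'   reported as stalled.
#' @param nNodes system size for fitness simulations.
#' @param statNames statistics of the model being evolved.
#' @param template fibril topology the fitness assay scores against
#'   (name or \code{\linkS4class{FibrilTemplate}}).
#' @param burninProposals,maxEdgesGuard sampler settings (\code{NA} = the
#'   \code{\link{samplerConfig}} defaults).
#' @param masterSeed master seed; all randomness (breeding, selection,
#'   per-individual simulation seeds) derives from it.
#' @return a \code{\linkS4class{GAConfig}}.
#' @export
gaConfig <- function(reps = 16, noiseVarInit = 1.0, topFraction = 0.25,
                     maxSurvivors = 20, fixEdge = FALSE, fixEdgeValue = 100,
                     smartVar = TRUE, smartPts = TRUE, useLineDensity = TRUE,
                     minLineDensity = 1.2, linearChildren = 5L,
                     childMax = 100, maxGenerations = 10L, maxRetries = 5L,
                     nNodes = 48L,
                     statNames = c("edges", "twostar", "nsp1", "nsp2"),
                     template = "2-ribbon", burninProposals = NA_real_,
                     maxEdgesGuard = NA_real_, masterSeed = 1L) {
  new("GAConfig", reps = as.integer(reps), noiseVarInit = noiseVarInit,
      topFraction = topFraction, maxSurvivors = as.integer(maxSurvivors),
      fixEdge = fixEdge, fixEdgeValue = fixEdgeValue, smartVar = smartVar,
      smartPts = smartPts, useLineDensity = useLineDensity,
      minLineDensity = minLineDensity,
      linearChildren = as.integer(linearChildren),
      childMax = as.integer(childMax),
      maxGenerations = as.integer(maxGenerations),
      maxRetries = as.integer(maxRetries), nNodes = as.integer(nNodes),
      statNames = statNames, template = fibrilTemplate(template),
      burninProposals = as.numeric(burninProposals),
      maxEdgesGuard = as.numeric(maxEdgesGuard),
      masterSeed = as.integer(masterSeed))
}

.free_dims <- function(cfg) {
  if (cfg@fixEdge) setdiff(cfg@statNames, "edges") else cfg@statNames
}

.pinned_edge_phi <- function(cfg) {
  -cfg@fixEdgeValue - 1 + log(cfg@nNodes)
}

.individual <- function(id, phi, origin, parents = c(NA_integer_, NA_integer_),
                        draws = numeric(0), mean = NA_real_) {
  list(id = as.integer(id), phi = phi, origin = origin,
       parents = as.integer(parents), draws = draws, mean = mean)
}

#' Seed a generation-0 parameter cloud
#'
#' Samples \code{count} coefficient vectors uniformly from the ball of the
#' given radius around \code{center} over the free dimensions. With
#' \code{fixEdge} on, the edge coordinate is excluded from sampling and set
#' to the pinned value on every point.
#'
#' @param cfg a \code{\linkS4class{GAConfig}}.
#' @param center named numeric: ball center over the free dimensions
#'   (missing dimensions default to 0).
#' @param radius ball radius (> 0).
#' @param count number of points.
#' @param seed optional seed for this sampling step.
#' @return list of individuals (origin \code{"seed"}, unevaluated).
#' @export
seedSphere <- function(cfg, center = NULL, radius = 40, count = 100,
                       seed = NULL) {
  if (radius <= 0) stop("radius must be > 0")
  if (count < 1) stop("count must be >= 1")
  free <- .free_dims(cfg)
  if (length(free) == 0L) stop("no free dimensions to sample")
  ctr <- setNames(numeric(length(free)), free)
  if (!is.null(center)) {
    keep <- intersect(names(center), free)
    ctr[keep] <- center[keep]
  }
  if (!is.null(seed)) set.seed(seed)
  d <- length(free)
  pts <- lapply(seq_len(count), function(i) {
    z <- rnorm(d)
    u <- runif(1)
    ctr + z / sqrt(sum(z^2)) * radius * u^(1 / d)
  })
  lapply(seq_along(pts), function(i) {
    phi <- setNames(numeric(length(cfg@statNames)), cfg@statNames)
    phi[free] <- pts[[i]]
    if (cfg@fixEdge && "edges" %in% cfg@statNames)
      phi[["edges"]] <- .pinned_edge_phi(cfg)
    .individual(i, phi, "seed")
  })
}

#' Breed one pair of parents
#'
#' Places \code{floor(minLineDensity * d)} linear children at evenly spaced
#' interior points of the segment joining the parents (distance \code{d}
#' over the free dimensions; endpoints excluded — parents are copied into
#' the next generation separately), then adds \code{mutantsPerChild} noisy
#' copies of each with i.i.d. Gaussian noise of variance \code{noiseVar}
#' per free dimension. Pairs whose distance implies fewer than one linear
#' child are deemed too closely related and produce nothing. At most
#' \code{childMax} children are kept (uniform random subset). Ids are
#' assigned by the caller; children are returned unevaluated. Consumes the
#' R RNG stream.
#'
#' @param p1,p2 parent individuals (as produced by \code{\link{seedSphere}}
#'   or a previous generation).
#' @param cfg a \code{\linkS4class{GAConfig}}.
#' @param noiseVar current mutant noise variance.
#' @param mutantsPerChild current number of mutants per linear child.
#' @return list of unevaluated child individuals (ids 0).
#' @export
breedPair <- function(p1, p2, cfg, noiseVar = cfg@noiseVarInit,
                      mutantsPerChild = 1L) {
  free <- .free_dims(cfg)
  v1 <- p1$phi[free]
  v2 <- p2$phi[free]
  d <- sqrt(sum((v2 - v1)^2))
  nLin <- if (cfg@useLineDensity) floor(cfg@minLineDensity * d)
          else cfg@linearChildren
  if (nLin < 1) return(list())
  parents <- c(p1$id, p2$id)
  fill <- function(freeVals, origin) {
    phi <- p1$phi
    phi[free] <- freeVals
    .individual(0L, phi, origin, parents)
  }
  children <- list()
  for (k in seq_len(nLin)) {
    lam <- k / (nLin + 1)
    lin <- (1 - lam) * v1 + lam * v2
    children[[length(children) + 1L]] <- fill(lin, "linear")
    for (m in seq_len(mutantsPerChild)) {
      mut <- lin + rnorm(length(free), sd = sqrt(noiseVar))
      children[[length(children) + 1L]] <- fill(mut, "mutant")
    }
  }
  if (length(children) > cfg@childMax)
    children <- children[sort(sample.int(length(children), cfg@childMax))]
  children
}

#' Evaluate the fitness of a coefficient vector
#'
#' Runs \code{reps} independent equilibrium draws of the model at
#' \code{nNodes} (coefficients converted with \code{\link{phiToTheta}}),
#' scores each with \code{\link{fibrilFraction}} against the configured
#' template, and returns the mean. Per-draw seeds derive deterministically
#' from the master seed and \code{id}, so evaluation is order-independent.
#' Degenerate (runaway-density) draws score 0 rather than aborting the
#' search.
#'
#' @param phi named coefficient vector over \code{statNames(cfg)}.
#' @param cfg a \code{\linkS4class{GAConfig}}.
#' @param id individual identifier keying the seed derivation.
#' @return list with \code{draws} (per-rep fibril fractions) and
#'   \code{mean}.
#' @export
evaluateFitness <- function(phi, cfg, id = 1L) {
  model <- nhmModel(phi[cfg@statNames])
  scfg <- samplerConfig(
    burninProposals = if (is.finite(cfg@burninProposals))
      cfg@burninProposals else NULL,
    maxEdgesGuard = if (is.finite(cfg@maxEdgesGuard))
      cfg@maxEdgesGuard else NULL)
  seeds <- .derive_seeds(cfg@masterSeed, cfg@reps, salt = id)
  draws <- vapply(seeds, function(s) {
    scfg$seed <- s
    tryCatch({
      d <- simulateDraw(model, cfg@nNodes, scfg)
      fibrilFraction(drawGraph(d), cfg@template)
    }, nhmDegeneracyError = function(e) 0)
  }, numeric(1))
  list(draws = draws, mean = mean(draws))
}

.evaluate_population <- function(pop, cfg, fitness = NULL) {
  lapply(pop, function(ind) {
    if (!is.na(ind$mean)) return(ind)   # parent copies keep their fitness
    if (is.null(fitness)) {
      f <- evaluateFitness(ind$phi, cfg, ind$id)
    } else {
      val <- fitness(ind$phi)
      f <- list(draws = val, mean = mean(val))
    }
    ind$draws <- f$draws
    ind$mean <- f$mean
    ind
  })
}

#' Select the survivors of a generation
#'
#' Ranks by mean fitness (ties broken by lower id) and keeps the top
#' \code{ceiling(topFraction * n)}; if that exceeds \code{maxSurvivors}, a
#' uniform random subset of the top fraction of size \code{maxSurvivors} is
#' kept (consumes the R RNG stream).
#'
#' @param population list of evaluated individuals.
#' @param cfg a \code{\linkS4class{GAConfig}}.
#' @return list of surviving individuals, ranked.
#' @export
selectSurvivors <- function(population, cfg) {
  if (length(population) == 0L) stop("population is empty")
  means <- vapply(population, `[[`, numeric(1), "mean")
  if (anyNA(means)) stop("population must be evaluated before selection")
  ids <- vapply(population, `[[`, integer(1), "id")
  ord <- order(-means, ids)
  k <- ceiling(cfg@topFraction * length(population))
  top <- population[ord[seq_len(k)]]
  if (length(top) > cfg@maxSurvivors)
    top <- top[sort(sample.int(length(top), cfg@maxSurvivors))]
  top
}

.ledger_rows <- function(pop, cfg, generation, attempt, accepted) {
  if (length(pop) == 0L) return(NULL)
  do.call(rbind, lapply(pop, function(ind) {
    row <- data.frame(generation = generation, attempt = attempt,
                      accepted = accepted, id = ind$id,
                      origin = ind$origin,
                      parent1 = ind$parents[1], parent2 = ind$parents[2],
                      mean = ind$mean,
                      sd = if (length(ind$draws) > 1) sd(ind$draws)
                           else NA_real_,
                      stringsAsFactors = FALSE)
    for (s in cfg@statNames) row[[paste0("phi_", s)]] <- ind$phi[[s]]
    for (j in seq_along(ind$draws)) row[[paste0("draw", j)]] <- ind$draws[j]
    row
  }))
}

.bind_ledger <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (cn in setdiff(names(a), names(b))) b[[cn]] <- NA
  for (cn in setdiff(names(b), names(a))) a[[cn]] <- NA
  rbind(a, b[names(a)])
}

#' Advance the genetic algorithm by one generation
#'
#' Breeds all survivor pairs, evaluates the children, and accepts the new
#' generation (children plus copies of all breeding parents) only if some
#' child strictly outperforms the best parent. A rejected generation is
#' removed from the gene pool entirely; the noise variance is doubled
#' (\code{smartVar}), the mutant count incremented (\code{smartPts}), and
#' breeding retried up to \code{maxRetries} times before the run stalls.
#' Because parents are copied into every accepted generation, a consistently
#' top-performing parameter can persist indefinitely.
#'
#' @param state generation state as produced by \code{\link{runEvolution}}
#'   internals: list with \code{index}, \code{survivors}, \code{noiseVar},
#'   \code{mutantsPerChild}, \code{bestMean}, \code{nextId}.
#' @param cfg a \code{\linkS4class{GAConfig}}.
#' @param fitness optional fitness function \code{phi -> numeric} replacing
#'   the simulation-based assay (used for synthetic landscapes).
#' @return the next state; \code{state$stalled} is \code{TRUE} when the
#'   retry budget was exhausted. \code{state$ledger} holds rows for every
#'   individual evaluated in this step, including rejected attempts.
#' @export
advanceGeneration <- function(state, cfg, fitness = NULL) {
  if (length(state$survivors) < 2L) {
    state$stalled <- TRUE
    state$ledger <- NULL
    return(state)
  }
  gen <- state$index + 1L
  ledger <- NULL
  parentBest <- max(vapply(state$survivors, `[[`, numeric(1), "mean"))
  pairs <- utils::combn(length(state$survivors), 2)
  for (attempt in 0:cfg@maxRetries) {
    set.seed(.derive_seeds(cfg@masterSeed, 1L,
                           salt = gen * 997 + attempt)[1])
    children <- list()
    for (p in seq_len(ncol(pairs))) {
      kids <- breedPair(state$survivors[[pairs[1, p]]],
                        state$survivors[[pairs[2, p]]], cfg,
                        noiseVar = state$noiseVar,
                        mutantsPerChild = state$mutantsPerChild)
      children <- c(children, kids)
    }
    if (length(children)) {
      for (i in seq_along(children))
        children[[i]]$id <- state$nextId + i - 1L
      state$nextId <- state$nextId + length(children)
      children <- .evaluate_population(children, cfg, fitness)
    }
    childMeans <- vapply(children, `[[`, numeric(1), "mean")
    if (length(children) && max(childMeans) > parentBest) {
      parentCopies <- lapply(state$survivors, function(p) {
        p$origin <- "parent-copy"
        p
      })
      population <- c(children, parentCopies)
      ledger <- .bind_ledger(ledger,
        .ledger_rows(population, cfg, gen, attempt, TRUE))
      survivors <- selectSurvivors(population, cfg)
      popMeans <- vapply(population, `[[`, numeric(1), "mean")
      state$index <- gen
      state$survivors <- survivors
      state$bestMean <- max(c(state$bestMean, popMeans))
      state$genBest <- population[[which.max(popMeans)]]
      state$ledger <- ledger
      state$stalled <- FALSE
      return(state)
    }
    # rejected: remove the generation from the gene pool, broaden the search
    ledger <- .bind_ledger(ledger,
      .ledger_rows(children, cfg, gen, attempt, FALSE))
    if (cfg@smartVar) state$noiseVar <- state$noiseVar * 2
    if (cfg@smartPts) state$mutantsPerChild <- state$mutantsPerChild + 1L
  }
  state$ledger <- ledger
  state$stalled <- TRUE
  state
}

#' Run the genetic algorithm
#'
#' Evolves network Hamiltonian coefficients toward maximal mean fibril
#' fraction: generation 0 comes from \code{init} (a list of individuals, a
#' list/matrix of phi vectors) or from \code{\link{seedSphere}}; each
#' subsequent generation breeds all survivor pairs and must strictly
#' outperform its parents to be accepted (see
#' \code{\link{advanceGeneration}}). The best-so-far fitness trajectory is
#' nondecreasing by construction.
#'
#' @param cfg a \code{\linkS4class{GAConfig}}.
#' @param init optional generation 0: a list of individuals or phi vectors,
#'   or a matrix with one phi vector per row (columns =
#'   \code{statNames(cfg)}).
#' @param center,radius,count sphere-sampling arguments used when
#'   \code{init} is missing (see \code{\link{seedSphere}}).
#' @param fitness optional synthetic fitness function \code{phi -> numeric}
#'   replacing the simulation assay.
#' @return an \code{\linkS4class{EvolutionRun}}.
#' @export
#' @examples
#' # recover the optimum of a synthetic Gaussian fitness landscape
#' cfg <- gaConfig(statNames = c("twostar", "nsp1"), maxGenerations = 8,
#'                 topFraction = 0.5, maxSurvivors = 4, childMax = 12,
#'                 masterSeed = 7)
#' run <- runEvolution(cfg, center = c(twostar = 0, nsp1 = 0), radius = 4,
#'                     count = 8,
#'                     fitness = function(phi)
#'                       exp(-sum((phi - c(twostar = 2, nsp1 = -1))^2)))
runEvolution <- function(cfg, init = NULL, center = NULL, radius = 40,
                         count = 100, fitness = NULL) {
  if (is.null(init)) {
    gen0 <- seedSphere(cfg, center, radius, count,
                       seed = .derive_seeds(cfg@masterSeed, 1L, salt = 0)[1])
  } else if (is.matrix(init)) {
    if (is.null(colnames(init))) colnames(init) <- cfg@statNames
    gen0 <- lapply(seq_len(nrow(init)), function(i)
      .individual(i, setNames(init[i, cfg@statNames], cfg@statNames),
                  "seed"))
  } else if (is.list(init) && length(init) && !is.null(init[[1]]$phi)) {
    gen0 <- lapply(seq_along(init), function(i) {
      ind <- init[[i]]
      ind$id <- i
      ind
    })
  } else if (is.list(init)) {
    gen0 <- lapply(seq_along(init), function(i)
      .individual(i, init[[i]][cfg@statNames], "seed"))
  } else stop("unsupported init")

  gen0 <- .evaluate_population(gen0, cfg, fitness)
  ledger <- .ledger_rows(gen0, cfg, 0L, 0L, TRUE)
  set.seed(.derive_seeds(cfg@masterSeed, 1L, salt = 499)[1])
  # generation 0 is the user's chosen breeding population: rank it and cap
  # at maxSurvivors, but do not thin it by topFraction (that applies to
  # bred generations)
  means0 <- vapply(gen0, `[[`, numeric(1), "mean")
  ids0 <- vapply(gen0, `[[`, integer(1), "id")
  survivors <- gen0[order(-means0, ids0)]
  if (length(survivors) > cfg@maxSurvivors)
    survivors <- survivors[seq_len(cfg@maxSurvivors)]

  state <- list(index = 0L, survivors = survivors,
                noiseVar = cfg@noiseVarInit, mutantsPerChild = 1L,
                bestMean = max(means0),
                nextId = max(vapply(gen0, `[[`, integer(1), "id")) + 1L,
                stalled = FALSE)
  generations <- list(list(index = 0L,
                           populationIds = vapply(gen0, `[[`, integer(1), "id"),
                           survivorIds = vapply(survivors, `[[`, integer(1), "id"),
                           noiseVar = state$noiseVar,
                           mutantsPerChild = state$mutantsPerChild,
                           bestMean = state$bestMean))
  best <- gen0[[which.max(means0)]]

  while (state$index < cfg@maxGenerations && !state$stalled) {
    state <- advanceGeneration(state, cfg, fitness)
    ledger <- .bind_ledger(ledger, state$ledger)
    if (state$stalled) break
    generations[[length(generations) + 1L]] <- list(
      index = state$index,
      populationIds = if (is.null(state$ledger)) integer(0) else
        state$ledger$id[state$ledger$accepted &
                        state$ledger$generation == state$index],
      survivorIds = vapply(state$survivors, `[[`, integer(1), "id"),
      noiseVar = state$noiseVar,
      mutantsPerChild = state$mutantsPerChild,
      bestMean = state$bestMean)
    if (!is.null(state$genBest) && state$genBest$mean > best$mean)
      best <- state$genBest
  }

  rownames(ledger) <- NULL
  new("EvolutionRun", generations = generations, ledger = ledger,
      best = best, stalled = state$stalled, config = cfg)
}
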