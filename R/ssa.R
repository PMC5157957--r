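#' @useDynLib ColE2sim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Derive a child seed from a base seed
#'
#' Counter-based derivation: each realization index maps deterministically
#' to its own seed, so ensembles are reproducible as a whole and any single
#' realization can be re-run in isolation.
#'
#' @param baseSeed integer base seed.
#' @param index realization index (1-based); may be a vector.
#' @return integer vector of seeds in \code{[1, 2^31 - 2]}.
#' @export
childSeed <- function(baseSeed, index) {
  m <- 2147483647  # 2^31 - 1 (Mersenne prime; exact in doubles)
  s <- (as.numeric(baseSeed) %% m) + 1
  out <- (s * 48271 + as.numeric(index) * 16807) %% m
  as.integer(out %% (m - 1) + 1)
}

#' Exact stochastic simulation of a reaction system
#'
#' Generates one statistically exact realization of the chemical master
#' equation with the Gillespie direct method (two uniform random numbers
#' per event: one for the waiting time, one for the reaction choice).
#' Time-dependent rates (the c_p(t) schedule) are piecewise constant; no
#' single step crosses a schedule breakpoint, which preserves exactness.
#' The event-driven path is sampled onto \code{tGrid} by
#' last-value-carried-forward.
#'
#' @param system a [ReactionSystem-class].
#' @param initial named numeric vector of initial copy numbers (integers);
#'   missing species start at 0.
#' @param tGrid increasing numeric output grid (min); the simulation runs
#'   from \code{tGrid[1]} to \code{tGrid[length(tGrid)]}.
#' @param seed integer RNG seed; identical (system, initial, seed) yield
#'   identical event sequences.
#' @param schedule optional [SignalSchedule-class] for flagged reactions.
#' @param maxEvents safety cap on the number of reaction events.
#' @return a [Trajectory-class] with integer counts.
#' @examples
#' sys <- buildReactionSystem(regulationParameters(), "reduced")
#' tr <- simulateSSA(sys, c(A = 800, S = 1), 0:50, seed = 1)
#' @export
simulateSSA <- function(system, initial, tGrid, seed, schedule = NULL,
                        maxEvents = 5e8) {
  stopifnot(is(system, "ReactionSystem"))
  if (length(tGrid) < 2L || any(diff(tGrid) <= 0))
    stop("'tGrid' must be increasing with at least two points")
  x0 <- stats::setNames(integer(length(system@species)), system@species)
  if (length(initial)) {
    bad <- setdiff(names(initial), system@species)
    if (length(bad)) stop("unknown species in 'initial': ",
                          paste(bad, collapse = ", "))
    if (any(initial < 0) || any(initial != round(initial)))
      stop("initial copy numbers must be non-negative integers")
    x0[names(initial)] <- as.integer(round(initial))
  }
  if (any(system@timeDependent) && is.null(schedule))
    stop("system has schedule-scaled reactions; supply a SignalSchedule")
  if (is.null(schedule)) {
    st <- 0; sv <- 1
  } else {
    stopifnot(is(schedule, "SignalSchedule"))
    st <- schedule@times; sv <- schedule@values
  }
  set.seed(as.integer(seed))
  counts <- .ssaCore(system@stoich, system@orders, system@rates,
                     system@timeDependent, st, sv, x0,
                     as.numeric(tGrid), maxEvents)
  colnames(counts) <- system@species
  new("Trajectory", time = as.numeric(tGrid), counts = counts,
      metadata = list(method = "ssa_direct", variant = system@variant,
                      params = system@params, seed = as.integer(seed),
                      schedule = schedule))
}

#' Simulate an ensemble of independent stochastic realizations
#'
#' Runs [simulateSSA()] \code{nRealizations} times with per-realization
#' seeds derived from \code{baseSeed} via [childSeed()], on a common output
#' grid.
#'
#' @inheritParams simulateSSA
#' @param nRealizations number of independent realizations (>= 1).
#' @param baseSeed integer base seed.
#' @return a [TrajectoryEnsemble-class].
#' @export
simulateEnsemble <- function(system, initial, tGrid, nRealizations,
                             baseSeed, schedule = NULL, maxEvents = 5e8) {
  stopifnot(nRealizations >= 1)
  seeds <- childSeed(baseSeed, seq_len(nRealizations))
  arr <- array(NA_real_,
               dim = c(length(tGrid), length(system@species),
                       nRealizations),
               dimnames = list(NULL, system@species, NULL))
  for (r in seq_len(nRealizations)) {
    tr <- simulateSSA(system, initial, tGrid, seeds[r], schedule,
                      maxEvents)
    arr[, , r] <- tr@counts
  }
  new("TrajectoryEnsemble", time = as.numeric(tGrid), counts = arr,
      seeds = as.numeric(seeds),
      metadata = list(variant = system@variant, params = system@params,
                      baseSeed = baseSeed, schedule = schedule))
}

setMethod("nRealizations", "TrajectoryEnsemble", function(object) {
  dim(object@counts)[3L]
})

setMethod("nRealizations", "LysisStatistics", function(object) {
  length(object@censored)
})

setMethod("speciesCounts", "Trajectory", function(object, species) {
  if (!species %in% colnames(object@counts))
    stop("unknown species: ", species)
  object@counts[, species]
})

setMethod("speciesCounts", "TrajectoryEnsemble", function(object, species) {
  if (!species %in% dimnames(object@counts)[[2L]])
    stop("unknown species: ", species)
  object@counts[, species, ]
})

setMethod("ensembleMean", "TrajectoryEnsemble", function(object,
                                                         species = NULL) {
  m <- apply(object@counts, c(1L, 2L), mean)
  if (!is.null(species)) m[, species] else m
})

setMethod("ensembleVar", "TrajectoryEnsemble", function(object,
                                                        species = NULL) {
  v <- apply(object@counts, c(1L, 2L), stats::var)
  if (!is.null(species)) v[, species] else v
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory [%s]: %d time points (%g-%g min), species: %s\n",
              object@metadata$method %||% "?", length(object@time),
              object@time[1L], object@time[length(object@time)],
              paste(colnames(object@counts), collapse = ", ")))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf(
    "TrajectoryEnsemble [%s]: %d realizations, %d time points, species: %s\n",
    object@metadata$variant %||% "?", nRealizations(object),
    length(object@time),
    paste(dimnames(object@counts)[[2L]], collapse = ", ")))
})

#' Compare detailed multi-site and reduced one-site models
#'
#' The reduction of the multi-site sRNA to an effective one-site species
#' assumes complex binding/unbinding to be much faster than production and
#' degradation. This report quantifies the assumption: for each speed-up
#' factor the detailed variant is simulated with all complex
#' binding/unbinding rates scaled by that factor, and the stationary means
#' of free M, free A and free effective-sRNA sites are compared against the
#' reduced variant.
#'
#' @param params a [RegulationParameters-class] (pM = pS = 1 required by the
#'   detailed variant).
#' @param speedupFactors numeric vector of scale factors for the complex
#'   binding/unbinding rates.
#' @param tMax simulated time per run (min); the first half is discarded as
#'   burn-in.
#' @param seed integer seed.
#' @param initial optional named initial state for the reduced variant
#'   (mapped onto the detailed one).
#' @return data.frame with one row per factor: stationary means of M, A and
#'   free sRNA sites for both variants and their absolute discrepancies.
#' @export
reducedVsDetailed <- function(params, speedupFactors = c(1, 10, 100),
                              tMax = 2000, seed = 1, initial = NULL) {
  stopifnot(is(params, "RegulationParameters"))
  grid <- seq(0, tMax, by = 1)
  burn <- grid > tMax / 2
  if (is.null(initial)) initial <- c(A = round(params@alphaA /
                                               max(params@deltaA, 1e-6)))
  redSys <- buildReactionSystem(params, "reduced")
  redTr <- simulateSSA(redSys, initial, grid, seed = childSeed(seed, 1e6))
  redMeans <- colMeans(redTr@counts[burn, c("M", "A", "S")])

  base <- .defaultDetailedRates(params)
  out <- data.frame()
  for (i in seq_along(speedupFactors)) {
    f <- speedupFactors[i]
    dr <- base
    # binding/unbinding rates scale; complex degradation does not (the
    # effective coupled-degradation constants kPlus*deltaCma/kMinus and
    # deltaS*vPlus/vMinus stay fixed while complex dynamics accelerate)
    dr$vPlus <- base$vPlus * f; dr$vMinus <- base$vMinus * f
    dr$kPlus <- base$kPlus * f; dr$kMinus <- base$kMinus * f
    detSys <- buildReactionSystem(params, "detailed", detailedRates = dr)
    detTr <- simulateSSA(detSys, initial, grid, seed = childSeed(seed, i))
    detM <- mean(detTr@counts[burn, "M"])
    detA <- mean(detTr@counts[burn, "A"])
    detS <- mean(freeSrnaSites(detTr@counts[burn, , drop = FALSE],
                               params@N))
    out <- rbind(out, data.frame(
      speedup = f,
      M_detailed = detM, A_detailed = detA, S_detailed = detS,
      M_reduced = redMeans[["M"]], A_reduced = redMeans[["A"]],
      S_reduced = redMeans[["S"]],
      dM = abs(detM - redMeans[["M"]]),
      dA = abs(detA - redMeans[["A"]]),
      dS = abs(detS - redMeans[["S"]])))
  }
  rownames(out) <- NULL
  out
}
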