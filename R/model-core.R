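#' Time derivatives of the reduced three-component model
#'
#' Evaluates the deterministic rate equations of the titration motif at a
#' given state:
#' \deqn{\dot M = \alpha_M - \delta_M M - k_M M A}
#' \deqn{\dot A = \alpha_A - \delta_A A - k_M p_M M A - k_S p_S A S}
#' \deqn{\dot S = N\alpha_S - \delta_S S - k_S A S}
#' where M, A, S are free long mRNA, free CsrA dimers and free effective
#' sRNA.
#'
#' @param state named numeric vector with components \code{M}, \code{A},
#'   \code{S} (molecules); all must be non-negative.
#' @param params a [RegulationParameters-class].
#' @return named numeric vector of derivatives (molecules/min).
#' @examples
#' reducedDerivatives(c(M = 0, A = 0, S = 0), regulationParameters())
#' @export
reducedDerivatives <- function(state, params) {
  stopifnot(is(params, "RegulationParameters"))
  if (!all(c("M", "A", "S") %in% names(state)))
    stop("'state' must be a named vector with components M, A, S")
  M <- state[["M"]]; A <- state[["A"]]; S <- state[["S"]]
  if (min(M, A, S) < 0)
    stop("state components must be non-negative (got M=", M,
         ", A=", A, ", S=", S, ")")
  p <- params
  c(M = p@alphaM - p@deltaM * M - p@kM * M * A,
    A = p@alphaA - p@deltaA * A - p@kM * p@pM * M * A - p@kS * p@pS * A * S,
    S = p@N * p@alphaS - p@deltaS * S - p@kS * A * S)
}

#' Stationary open fraction of a repressor-bound promoter
#'
#' For a two-state promoter with repressor binding rate \code{kOn * Le} and
#' unbinding rate \code{kOff}, the stationary probability of being open
#' (unbound) is \code{kOff / (kOff + kOn * Le)}.
#'
#' @param kOn binding rate constant (1/(molecule min)).
#' @param kOff unbinding rate (1/min).
#' @param repressor repressor copy number (LexA dimers).
#' @return probability in [0, 1].
#' @export
promoterOnProbability <- function(kOn, kOff, repressor) {
  stopifnot(kOn >= 0, kOff >= 0, repressor >= 0)
  if (kOff == 0 && kOn * repressor == 0) return(1)
  kOff / (kOff + kOn * repressor)
}

#' Effective long-mRNA transcription rate under fast promoter kinetics
#'
#' Adiabatic elimination of the SOS promoter state: when LexA
#' binding/unbinding is fast relative to mRNA production and degradation,
#' the promoter is replaced by its stationary open probability and the
#' effective transcription rate over all plasmid copies is
#' \code{nSos * perPlasmidRate * onProbability}.
#'
#' @param perPlasmidRate transcription rate per open promoter
#'   (molecules/min).
#' @param onProbability stationary open-promoter probability in [0, 1];
#'   alternatively supply \code{kOn}, \code{kOff} and \code{repressor} to
#'   compute it via [promoterOnProbability()].
#' @param nSos plasmid copy number (default 20).
#' @param kOn,kOff,repressor optional two-state promoter rates used when
#'   \code{onProbability} is missing.
#' @return effective rate alpha_M (molecules/min).
#' @examples
#' effectiveTranscriptionRate(1, onProbability = 1, nSos = 20)  # 20
#' @export
effectiveTranscriptionRate <- function(perPlasmidRate, onProbability = NULL,
                                       nSos = 20, kOn = NULL, kOff = NULL,
                                       repressor = NULL) {
  stopifnot(perPlasmidRate >= 0, nSos >= 1)
  if (is.null(onProbability)) {
    if (is.null(kOn) || is.null(kOff) || is.null(repressor))
      stop("supply either 'onProbability' or (kOn, kOff, repressor)")
    onProbability <- promoterOnProbability(kOn, kOff, repressor)
  }
  if (onProbability < 0 || onProbability > 1)
    stop("'onProbability' must lie in [0, 1] (got ", onProbability, ")")
  nSos * perPlasmidRate * onProbability
}

#' Reduce a multi-site sRNA to an effective single-site species
#'
#' The multi-site sRNA (N CsrA binding sites per molecule) is replaced by an
#' effective sRNA whose unit is one free binding site: production rate
#' \code{N * alphaS}, a single binding site, and coupled degradation with
#' CsrA. Under fast complex binding/unbinding relative to production and
#' degradation, the site occupancy equilibrates and the net coupled
#' degradation constant is \code{kS = deltaS * vPlus / vMinus} (binding
#' equilibrium constant times the sRNA decay rate): a bound CsrA dimer is
#' lost when its carrier sRNA degrades, so \code{pS = 1}.
#'
#' @param N number of binding sites per sRNA molecule (>= 1).
#' @param alphaS per-molecule sRNA transcription rate.
#' @param complexRates named list with components \code{vPlus} (per-site
#'   CsrA binding rate, 1/(molecule min)), \code{vMinus} (per-site
#'   unbinding rate, 1/min) and \code{deltaS} (sRNA degradation rate,
#'   1/min). If \code{vMinus = 0}, binding itself is irreversible
#'   sequestration and \code{kS = vPlus}.
#' @return list with components \code{alphaSEffective} (= N * alphaS),
#'   \code{kS}, \code{pS} (= 1), \code{N = 1} (the reduced site count) and
#'   an \code{assumptions} string documenting the fast-equilibration
#'   assumption.
#' @examples
#' effectiveSrnaReduction(22, 57.5 / 22,
#'   list(vPlus = 4, vMinus = 10, deltaS = 0.25))
#' @export
effectiveSrnaReduction <- function(N, alphaS, complexRates) {
  if (N < 1) stop("'N' must be >= 1 (got ", N, ")")
  stopifnot(alphaS >= 0)
  req <- c("vPlus", "vMinus", "deltaS")
  if (!all(req %in% names(complexRates)))
    stop("complexRates must contain: ", paste(req, collapse = ", "))
  vp <- complexRates$vPlus; vm <- complexRates$vMinus
  dS <- complexRates$deltaS
  stopifnot(vp >= 0, vm >= 0, dS >= 0)
  kS <- if (vm == 0) vp else dS * vp / vm
  list(alphaSEffective = N * alphaS,
       kS = kS,
       pS = 1,
       N = 1,
       assumptions = paste(
         "site binding/unbinding assumed fast relative to production and",
         "degradation; occupancy replaced by its equilibrium, collapsing",
         "complex formation, dissociation and decay into coupled",
         "degradation of one-site effective sRNA units"))
}

.massActionDeriv <- function(system, x, schedValue) {
  rates <- system@rates
  if (any(system@timeDependent)) {
    rates[system@timeDependent] <- rates[system@timeDependent] * schedValue
  }
  # mass-action fluxes: rate_j * prod_i x_i^orders_ij
  logterm <- rep(1, length(rates))
  for (i in seq_along(x)) {
    o <- system@orders[i, ]
    nz <- o > 0L
    if (any(nz)) logterm[nz] <- logterm[nz] * x[i]^o[nz]
  }
  as.numeric(system@stoich %*% (rates * logterm))
}

#' Integrate the deterministic rate equations
#'
#' Solves the macroscopic (mass-action) rate equations of a reaction system
#' with the stiff, adaptive \code{lsoda} integrator (deSolve). The
#' system mixes fast coupled degradation with very slow CsrA decay, and
#' near-threshold abundances are of order one molecule, so tight absolute
#' tolerances (default 1e-10) are used. Piecewise-constant schedules are
#' handled exactly by integrating segment by segment.
#'
#' @param system a [ReactionSystem-class] (e.g. from
#'   [buildReactionSystem()]), or a [RegulationParameters-class] for the
#'   reduced model.
#' @param initial named numeric vector of initial abundances; species
#'   missing from the vector start at 0.
#' @param tGrid increasing numeric vector of output times (min).
#' @param schedule optional [SignalSchedule-class] scaling the
#'   time-dependent reactions.
#' @param rtol,atol relative/absolute solver tolerances.
#' @return a [Trajectory-class].
#' @examples
#' p <- setParameters(regulationParameters(), alphaM = 5, kM = 0, kS = 0)
#' tr <- integrateDeterministic(p, c(M = 0, A = 0, S = 0), 0:100)
#' tail(speciesCounts(tr, "M"), 1)  # ~ alphaM / deltaM = 25
#' @export
integrateDeterministic <- function(system, initial, tGrid, schedule = NULL,
                                   rtol = 1e-8, atol = 1e-10) {
  if (is(system, "RegulationParameters"))
    system <- buildReactionSystem(system, "reduced")
  stopifnot(is(system, "ReactionSystem"))
  if (length(tGrid) < 2L || any(diff(tGrid) <= 0))
    stop("'tGrid' must be increasing with at least two points")
  x0 <- stats::setNames(numeric(length(system@species)), system@species)
  if (length(initial)) {
    bad <- setdiff(names(initial), system@species)
    if (length(bad)) stop("unknown species in 'initial': ",
                          paste(bad, collapse = ", "))
    x0[names(initial)] <- initial
  }
  if (any(x0 < 0)) stop("initial abundances must be non-negative")
  if (any(system@timeDependent) && is.null(schedule))
    stop("system has schedule-scaled reactions; supply a SignalSchedule")

  if (is.null(schedule)) {
    segs <- c(tGrid[1L], tGrid[length(tGrid)])
    vals <- 1
  } else {
    stopifnot(is(schedule, "SignalSchedule"))
    brk <- schedule@times[schedule@times > tGrid[1L] &
                          schedule@times < tGrid[length(tGrid)]]
    segs <- c(tGrid[1L], brk, tGrid[length(tGrid)])
    vals <- scheduleValue(schedule, segs[-length(segs)])
  }

  rhs <- function(t, y, parms) {
    list(.massActionDeriv(system, y, parms))
  }

  out <- matrix(NA_real_, nrow = length(tGrid), ncol = length(x0))
  colnames(out) <- system@species
  cur <- x0
  for (k in seq_len(length(segs) - 1L)) {
    t0 <- segs[k]; t1 <- segs[k + 1L]
    inner <- tGrid[tGrid >= t0 & tGrid <= t1]
    times <- sort(unique(c(t0, inner, t1)))
    sol <- deSolve::lsoda(y = cur, times = times, func = rhs,
                          parms = vals[k], rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("lsoda failed on segment [", t0, ", ", t1, "] (istate = ",
           attr(sol, "istate")[1L], ")")
    sm <- sol[, -1L, drop = FALSE]
    keep <- times %in% inner
    out[match(times[keep], tGrid), ] <- sm[keep, , drop = FALSE]
    cur <- sm[nrow(sm), ]
    cur[cur < 0] <- 0  # clip solver-tolerance-level undershoot
  }
  if (min(out, na.rm = TRUE) < -1e-6)
    stop("integration produced negative abundances beyond tolerance")
  out[out < 0] <- 0
  new("Trajectory", time = as.numeric(tGrid), counts = out,
      metadata = list(method = "lsoda", variant = system@variant,
                      params = system@params, rtol = rtol, atol = atol,
                      schedule = schedule))
}
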