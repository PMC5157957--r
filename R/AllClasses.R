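#' @import methods
NULL

.scalarNonNeg <- function(x, nm) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    return(sprintf("'%s' must be a single non-missing number", nm))
  if (x < 0) return(sprintf("'%s' must be >= 0 (got %g)", nm, x))
  NULL
}

#' Rate constants of the reduced post-transcriptional model
#'
#' Holds all rate constants of the reduced three-component titration motif:
#' free long mRNA (M), free CsrA dimers (A) and a free effective sRNA (S)
#' carrying a single CsrA binding site. All rates are per cell per minute;
#' abundances are molecules per cell. The effective sRNA production rate is
#' the product \code{N * alphaS}; the two factors are stored separately so
#' that both the per-molecule transcription rate and the effective production
#' can be reported without ambiguity.
#'
#' @slot alphaM effective long-mRNA transcription rate (molecules/min).
#' @slot alphaA CsrA-dimer production rate (molecules/min).
#' @slot alphaS per-sRNA-molecule transcription rate (molecules/min); the
#'   effective production entering the dynamics is \code{N * alphaS}.
#' @slot N effective number of CsrA binding sites per sRNA molecule.
#' @slot deltaM,deltaA,deltaS first-order degradation rates (1/min).
#' @slot kM,kS coupled-degradation rate constants (1/(molecule min)).
#' @slot pM,pS probabilities that the CsrA dimer is removed in the respective
#'   coupled-degradation event (the dimer survives with probability 1 - p).
#' @slot nSos ColE2 plasmid copy number (SOS promoter copies).
#' @slot cellVolume cell volume in cubic micrometres (bookkeeping only; all
#'   rates are already per cell).
#' @seealso [regulationParameters()], [reducedDerivatives()],
#'   [steadyStateExact()]
#' @export
setClass("RegulationParameters",
  representation(
    alphaM = "numeric", alphaA = "numeric", alphaS = "numeric",
    N = "numeric",
    deltaM = "numeric", deltaA = "numeric", deltaS = "numeric",
    kM = "numeric", kS = "numeric",
    pM = "numeric", pS = "numeric",
    nSos = "numeric", cellVolume = "numeric"
  )
)

setValidity("RegulationParameters", function(object) {
  msgs <- character()
  for (nm in c("alphaM", "alphaA", "alphaS", "N", "deltaM", "deltaA",
               "deltaS", "kM", "kS", "pM", "pS", "nSos", "cellVolume")) {
    m <- .scalarNonNeg(slot(object, nm), nm)
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  if (length(msgs)) return(msgs)
  if (object@pM > 1) msgs <- c(msgs, "'pM' must lie in [0, 1]")
  if (object@pS > 1) msgs <- c(msgs, "'pS' must lie in [0, 1]")
  if (object@N < 1) msgs <- c(msgs, "'N' must be >= 1")
  if (object@nSos < 1) msgs <- c(msgs, "'nSos' must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Rate constants of the LexA-RecA SOS response network
#'
#' Parameters of the transcriptional layer coupled upstream of the
#' post-transcriptional module: the auto-repressed \emph{lexA} and
#' \emph{recA} genes, LexA-dimer binding to the three promoter classes
#' (\emph{lexA}, \emph{recA}, and the \code{nSos} identical SOS promoters of
#' the ColE2 plasmids), RecA-mediated LexA auto-cleavage (coupling
#' \code{cP}), transcription of short and long mRNA from open SOS promoters,
#' and lysis-protein translation from free long mRNA. All rates are per cell
#' per minute.
#'
#' @slot alphaMlex,alphaMrec transcription rates of lexA/recA mRNA per open
#'   promoter (molecules/min).
#' @slot alphaMs,alphaMl transcription rates of short/long mRNA per open SOS
#'   promoter (molecules/min).
#' @slot betaLex,betaRec translation rates: LexA dimers (resp. RecA) produced
#'   per mRNA per minute.
#' @slot deltaMlex,deltaMrec,deltaMs degradation rates of the three mRNAs
#'   (1/min).
#' @slot deltaLe,deltaR basal degradation/dilution rates of LexA dimers and
#'   RecA (1/min).
#' @slot betaL,deltaL lysis-protein translation (per free long mRNA) and
#'   degradation rates.
#' @slot kOn,kOff LexA-dimer promoter binding (1/(molecule min)) and
#'   unbinding (1/min) rates, shared by all promoter classes.
#' @slot cP baseline LexA auto-cleavage coupling (1/(molecule min) per RecA);
#'   during runs this is driven by a [SignalSchedule].
#' @seealso [sosParameters()], [fullNetworkSystem()]
#' @export
setClass("SOSParameters",
  representation(
    alphaMlex = "numeric", alphaMrec = "numeric",
    alphaMs = "numeric", alphaMl = "numeric",
    betaLex = "numeric", betaRec = "numeric",
    deltaMlex = "numeric", deltaMrec = "numeric", deltaMs = "numeric",
    deltaLe = "numeric", deltaR = "numeric",
    betaL = "numeric", deltaL = "numeric",
    kOn = "numeric", kOff = "numeric",
    cP = "numeric"
  )
)

setValidity("SOSParameters", function(object) {
  msgs <- character()
  for (nm in slotNames("SOSParameters")) {
    m <- .scalarNonNeg(slot(object, nm), nm)
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  if (length(msgs)) msgs else TRUE
})

#' Piecewise-constant schedule for the SOS coupling c_p(t)
#'
#' An SOS signal is emulated by stepping the LexA auto-cleavage coupling
#' \code{c_p} between constant levels. The default schedule holds
#' \code{c_p = 0} until t = 200 min, \code{c_p = 6} during the signal
#' (200-500 min), and 0 afterwards.
#'
#' @slot times breakpoint start times (min), strictly increasing, first = 0.
#' @slot values value of c_p on each segment (>= 0).
#' @seealso [signalSchedule()], [scheduleValue()]
#' @export
setClass("SignalSchedule",
  representation(times = "numeric", values = "numeric")
)

setValidity("SignalSchedule", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@values))
    msgs <- c(msgs, "'times' and 'values' must have equal length")
  if (length(object@times) < 1L) msgs <- c(msgs, "schedule must be non-empty")
  if (length(object@times) && object@times[1L] != 0)
    msgs <- c(msgs, "first breakpoint must be at time 0")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "breakpoints must be strictly increasing")
  if (any(object@values < 0)) msgs <- c(msgs, "schedule values must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A chemical reaction system in mass-action form
#'
#' Species, stoichiometric change vectors and propensities of a
#' well-stirred reaction network. Propensities are mass-action:
#' \code{rate * prod_i x_i^(orders_i)} for the deterministic rate equations
#' and \code{rate * prod_i falling_factorial(x_i, orders_i)} for the
#' stochastic simulation. Reactions flagged \code{timeDependent} have their
#' rate multiplied by the current value of a piecewise-constant
#' [SignalSchedule] (used for the RecA-mediated LexA cleavage c_p(t)).
#'
#' @slot species character vector of species names.
#' @slot stoich integer matrix (species x reactions) of net changes.
#' @slot orders integer matrix (species x reactions) of reactant orders.
#' @slot rates numeric vector of rate constants, one per reaction.
#' @slot timeDependent logical vector; TRUE where the rate is scaled by the
#'   schedule value.
#' @slot reactionNames character vector of human-readable reaction labels.
#' @slot variant one of "reduced", "detailed", "full_sos", or "custom".
#' @slot params list of parameter objects used to build the system.
#' @seealso [buildReactionSystem()], [simulateSSA()],
#'   [integrateDeterministic()]
#' @export
setClass("ReactionSystem",
  representation(
    species = "character",
    stoich = "matrix",
    orders = "matrix",
    rates = "numeric",
    timeDependent = "logical",
    reactionNames = "character",
    variant = "character",
    params = "list"
  )
)

setValidity("ReactionSystem", function(object) {
  msgs <- character()
  nS <- length(object@species)
  nR <- length(object@rates)
  if (!identical(dim(object@stoich), c(nS, nR)))
    msgs <- c(msgs, "stoich must be species x reactions")
  if (!identical(dim(object@orders), c(nS, nR)))
    msgs <- c(msgs, "orders must be species x reactions")
  if (length(object@timeDependent) != nR)
    msgs <- c(msgs, "timeDependent must have one entry per reaction")
  if (length(object@reactionNames) != nR)
    msgs <- c(msgs, "reactionNames must have one entry per reaction")
  if (any(object@rates < 0)) msgs <- c(msgs, "rates must be >= 0")
  if (length(object@orders) && any(object@orders < 0))
    msgs <- c(msgs, "orders must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A single simulated trajectory
#'
#' Species abundances on an ordered time grid, from either deterministic
#' integration or a Gillespie realization (sampled onto the grid by
#' last-value-carried-forward).
#'
#' @slot time numeric time grid (min), strictly increasing.
#' @slot counts numeric matrix (time x species) with species column names.
#' @slot metadata list: parameters, seed, method identifier, variant.
#' @export
setClass("Trajectory",
  representation(time = "numeric", counts = "matrix", metadata = "list")
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  if (length(object@time) != nrow(object@counts))
    msgs <- c(msgs, "length(time) must equal nrow(counts)")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  if (is.null(colnames(object@counts)))
    msgs <- c(msgs, "counts must have species column names")
  if (length(msgs)) msgs else TRUE
})

#' An ensemble of stochastic trajectories on a common time grid
#'
#' @slot time shared time grid (min).
#' @slot counts numeric array (time x species x realization).
#' @slot seeds per-realization RNG seeds (derived from a base seed).
#' @slot metadata list: system variant, parameters, base seed.
#' @seealso [simulateEnsemble()], [ensembleMean()]
#' @export
setClass("TrajectoryEnsemble",
  representation(time = "numeric", counts = "array", seeds = "numeric",
                 metadata = "list")
)

setValidity("TrajectoryEnsemble", function(object) {
  msgs <- character()
  d <- dim(object@counts)
  if (length(d) != 3L) msgs <- c(msgs, "counts must be a 3-d array")
  else {
    if (d[1L] != length(object@time))
      msgs <- c(msgs, "dim 1 of counts must match time grid")
    if (d[3L] != length(object@seeds))
      msgs <- c(msgs, "dim 3 of counts must match number of seeds")
  }
  if (length(msgs)) msgs else TRUE
})

#' Stationary state of the reduced model
#'
#' @slot M,A,S stationary abundances (molecules).
#' @slot regime "sub_threshold" or "super_threshold" (from
#'   [thresholdCondition()]).
#' @slot branch which solution produced the values: "exact_numeric",
#'   "low_abundance_approx" (free CsrA nearly titrated away) or
#'   "high_abundance_approx" (free CsrA abundant).
#' @slot residual maximum absolute stationary residual of the three rate
#'   equations, relative to the largest production rate.
#' @slot params the [RegulationParameters-class] used.
#' @export
setClass("SteadyState",
  representation(M = "numeric", A = "numeric", S = "numeric",
                 regime = "character", branch = "character",
                 residual = "numeric", params = "RegulationParameters")
)

setValidity("SteadyState", function(object) {
  msgs <- character()
  if (min(object@M, object@A, object@S) < -1e-9)
    msgs <- c(msgs, "stationary abundances must be non-negative")
  if (!object@regime %in% c("sub_threshold", "super_threshold"))
    msgs <- c(msgs, "unknown regime label")
  if (!object@branch %in% c("low_abundance_approx", "high_abundance_approx",
                            "exact_numeric"))
    msgs <- c(msgs, "unknown branch label")
  if (length(msgs)) msgs else TRUE
})

#' Linear-noise summary of stationary fluctuations
#'
#' Means from the macroscopic rate equations and the stationary covariance
#' from the linear noise approximation (van Kampen system-size expansion,
#' first-order terms for second moments).
#'
#' @slot means named mean vector (M, A, S).
#' @slot covariance 3 x 3 stationary covariance matrix (molecules^2).
#' @slot fanoM Var(M)/mean(M), dimensionless.
#' @slot order expansion order used for second moments (only 1 implemented).
#' @slot reliable FALSE where the expansion is expected to break down
#'   (mean M below 5 molecules near the threshold).
#' @export
setClass("NoiseSummary",
  representation(means = "numeric", covariance = "matrix", fanoM = "numeric",
                 order = "integer", reliable = "logical")
)

setValidity("NoiseSummary", function(object) {
  msgs <- character()
  C <- object@covariance
  if (!all(dim(C) == c(3L, 3L))) msgs <- c(msgs, "covariance must be 3 x 3")
  else {
    if (max(abs(C - t(C))) > 1e-6 * (1 + max(abs(C))))
      msgs <- c(msgs, "covariance must be symmetric")
    ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(abs(ev)))
      msgs <- c(msgs, "covariance must be positive semi-definite")
  }
  if (!is.na(object@fanoM) && object@fanoM < 0)
    msgs <- c(msgs, "fanoM must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' First-peak (lysis) statistics of an ensemble
#'
#' Per-realization first-peak onset and peak times of the long mRNA, the
#' empirical peak-time distribution relative to signal onset, and the
#' derived survival function (fraction of cells with no peak yet). A
#' realization whose long-mRNA count never exceeds the onset threshold is
#' censored.
#'
#' @slot onset per-realization onset times (min; NA if censored).
#' @slot peak per-realization peak times (min; NA if censored).
#' @slot censored logical per realization.
#' @slot signalOnset time of SOS induction (min); peak times in summaries
#'   are reported relative to this.
#' @slot onsetThreshold molecule threshold defining a peak onset.
#' @slot binWidth histogram bin width (min) for summaries.
#' @slot metadata list (parameters, seeds).
#' @seealso [lysisTimeDistribution()], [survivalFunction()]
#' @export
setClass("LysisStatistics",
  representation(onset = "numeric", peak = "numeric", censored = "logical",
                 signalOnset = "numeric", onsetThreshold = "numeric",
                 binWidth = "numeric", metadata = "list")
)

setValidity("LysisStatistics", function(object) {
  msgs <- character()
  n <- length(object@censored)
  if (length(object@onset) != n || length(object@peak) != n)
    msgs <- c(msgs, "onset, peak and censored must have equal length")
  ok <- !object@censored
  if (any(ok) && any(object@onset[ok] > object@peak[ok] + 1e-9))
    msgs <- c(msgs, "onset must be <= peak for uncensored realizations")
  if (any(ok) && (any(is.na(object@onset[ok])) || any(is.na(object@peak[ok]))))
    msgs <- c(msgs, "uncensored realizations must have finite onset and peak")
  if (length(msgs)) msgs else TRUE
})
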