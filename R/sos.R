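#' Full SOS-coupled reaction system
#'
#' Couples the LexA-RecA SOS network to the post-transcriptional titration
#' module. Species: lexA/recA mRNAs (\code{Ml}, \code{Mr}), LexA dimers
#' (\code{Le}), RecA (\code{R}), free/bound promoter copies for the lexA
#' gene (\code{Pl}/\code{Bl}), the recA gene (\code{Pr}/\code{Br}) and the
#' \code{nSos} identical SOS promoters (\code{Ps}/\code{Bs}), short mRNA
#' (\code{Ms}), and the post-transcriptional species \code{M}, \code{A},
#' \code{S} plus the lysis protein \code{L}.
#'
#' LexA dimers repress all three promoter classes by mass-action binding
#' (\code{kOn Le P}) and unbinding (\code{kOff B}); the plasmid promoters
#' are modeled as a single free/bound species pair with combinatorial
#' propensities rather than 20 distinguishable sites (identical kinetics).
#' Long and short mRNA are transcribed in proportion to the number of open
#' SOS promoters. RecA-mediated LexA auto-cleavage fires with propensity
#' \code{c_p(t) R Le} (free dimers only; promoter-bound LexA is assumed
#' protected), where c_p(t) follows the [SignalSchedule]. The reduced
#' coupled-degradation reactions act on the long mRNA, and the lysis
#' protein is translated from free long mRNA.
#'
#' @param sos an [SOSParameters-class].
#' @param reg a [RegulationParameters-class] (supplies the
#'   post-transcriptional rates and \code{nSos}).
#' @return a [ReactionSystem-class] with variant \code{"full_sos"}; the
#'   cleavage reaction is flagged time-dependent.
#' @seealso [sosInitialState()], [sosEnsemble()]
#' @export
fullNetworkSystem <- function(sos, reg) {
  stopifnot(is(sos, "SOSParameters"), is(reg, "RegulationParameters"))
  p <- reg; q <- sos
  species <- c("Ml", "Mr", "Le", "R", "Pl", "Bl", "Pr", "Br", "Ps", "Bs",
               "Ms", "M", "A", "S", "L")
  bind <- function(nameP, nameB, lab) list(
    list(name = sprintf("LexA binds %s promoter", lab), rate = q@kOn,
         change = stats::setNames(c(-1, -1, 1), c("Le", nameP, nameB)),
         order = stats::setNames(c(1, 1), c("Le", nameP))),
    list(name = sprintf("LexA unbinds %s promoter", lab), rate = q@kOff,
         change = stats::setNames(c(1, 1, -1), c("Le", nameP, nameB)),
         order = stats::setNames(1, nameB)))
  rx <- c(
    bind("Pl", "Bl", "lexA"),
    bind("Pr", "Br", "recA"),
    bind("Ps", "Bs", "SOS"),
    list(
      list(name = "transcription lexA mRNA", rate = q@alphaMlex,
           change = c(Ml = 1), order = c(Pl = 1)),
      list(name = "transcription recA mRNA", rate = q@alphaMrec,
           change = c(Mr = 1), order = c(Pr = 1)),
      list(name = "transcription short mRNA", rate = q@alphaMs,
           change = c(Ms = 1), order = c(Ps = 1)),
      list(name = "transcription long mRNA", rate = q@alphaMl,
           change = c(M = 1), order = c(Ps = 1)),
      list(name = "translation LexA dimers", rate = q@betaLex,
           change = c(Le = 1), order = c(Ml = 1)),
      list(name = "translation RecA", rate = q@betaRec,
           change = c(R = 1), order = c(Mr = 1)),
      list(name = "degradation lexA mRNA", rate = q@deltaMlex,
           change = c(Ml = -1), order = c(Ml = 1)),
      list(name = "degradation recA mRNA", rate = q@deltaMrec,
           change = c(Mr = -1), order = c(Mr = 1)),
      list(name = "degradation short mRNA", rate = q@deltaMs,
           change = c(Ms = -1), order = c(Ms = 1)),
      list(name = "degradation LexA dimers", rate = q@deltaLe,
           change = c(Le = -1), order = c(Le = 1)),
      list(name = "degradation RecA", rate = q@deltaR,
           change = c(R = -1), order = c(R = 1)),
      list(name = "RecA-mediated LexA cleavage [c_p(t) R Le]", rate = 1,
           change = c(Le = -1), order = c(R = 1, Le = 1),
           timeDependent = TRUE),
      list(name = "translation lysis protein", rate = q@betaL,
           change = c(L = 1), order = c(M = 1)),
      list(name = "degradation lysis protein", rate = q@deltaL,
           change = c(L = -1), order = c(L = 1)),
      # post-transcriptional module (reduced variant) on the long mRNA
      list(name = "degradation M", rate = p@deltaM,
           change = c(M = -1), order = c(M = 1)),
      list(name = "production A", rate = p@alphaA, change = c(A = 1)),
      list(name = "degradation A", rate = p@deltaA,
           change = c(A = -1), order = c(A = 1)),
      list(name = "production S (N*alphaS)", rate = p@N * p@alphaS,
           change = c(S = 1)),
      list(name = "degradation S", rate = p@deltaS,
           change = c(S = -1), order = c(S = 1))
    )
  )
  if (p@pM > 0)
    rx <- c(rx, list(list(name = "coupled degradation M+A (A removed)",
                          rate = p@kM * p@pM, change = c(M = -1, A = -1),
                          order = c(M = 1, A = 1))))
  if (p@pM < 1)
    rx <- c(rx, list(list(name = "coupled degradation M+A (A survives)",
                          rate = p@kM * (1 - p@pM), change = c(M = -1),
                          order = c(M = 1, A = 1))))
  if (p@pS > 0)
    rx <- c(rx, list(list(name = "coupled degradation S+A (A removed)",
                          rate = p@kS * p@pS, change = c(S = -1, A = -1),
                          order = c(S = 1, A = 1))))
  if (p@pS < 1)
    rx <- c(rx, list(list(name = "coupled degradation S+A (A survives)",
                          rate = p@kS * (1 - p@pS), change = c(S = -1),
                          order = c(S = 1, A = 1))))
  .newReactionSystem(species, rx, "full_sos",
                     list(regulation = p, sos = q))
}

#' Uninduced initial state of the full network
#'
#' Returns integer copy numbers near the c_p = 0 fixed point (computed by
#' deterministic integration of the full system over \code{relaxTime}
#' minutes from a repressed start), so that stochastic runs begin close to
#' the uninduced stationary state and the pre-signal burn-in only has to
#' equilibrate fluctuations.
#'
#' @param sos an [SOSParameters-class].
#' @param reg a [RegulationParameters-class].
#' @param nSos plasmid copy number override (defaults to \code{reg@nSos});
#'   must not exceed the promoter copies available.
#' @param relaxTime deterministic relaxation time (min).
#' @return named integer vector over the full species set.
#' @export
sosInitialState <- function(sos, reg, nSos = NULL, relaxTime = 3000) {
  stopifnot(is(sos, "SOSParameters"), is(reg, "RegulationParameters"))
  n <- if (is.null(nSos)) reg@nSos else nSos
  if (n > reg@nSos * 50)
    stop("implausible plasmid copy number: ", n)
  sys <- fullNetworkSystem(sos, reg)
  # analytic guess for the sub-threshold CsrA level speeds up relaxation
  # (CsrA itself relaxes on the slow 1/deltaA scale)
  aGuess <- max((reg@alphaA - reg@pS * srnaProduction(reg)) /
                  max(reg@deltaA, 1e-9), 0)
  start <- c(Le = round(sos@kOff / max(sos@kOn, 1e-12)) + 100,
             Bl = 1, Br = 1, Bs = n,
             A = round(aGuess))
  baseline <- signalSchedule(0, sos@cP)
  tr <- integrateDeterministic(sys, start, c(0, relaxTime / 2, relaxTime),
                               schedule = baseline)
  x <- tr@counts[nrow(tr@counts), ]
  x <- pmax(round(x), 0)
  # promoter bookkeeping must be integer-consistent
  x["Pl"] <- 1 - min(x["Bl"], 1); x["Bl"] <- min(x["Bl"], 1)
  x["Pr"] <- 1 - min(x["Br"], 1); x["Br"] <- min(x["Br"], 1)
  x["Bs"] <- min(x["Bs"], n); x["Ps"] <- n - x["Bs"]
  stats::setNames(as.integer(x), names(x))
}

#' Stochastic ensemble of the full SOS response
#'
#' Simulates \code{nRealizations} Gillespie realizations of the full
#' network under a c_p(t) schedule, starting from the uninduced state
#' ([sosInitialState()]), on a uniform 1-min output grid. The window before
#' signal onset serves as stochastic burn-in of the uninduced state.
#'
#' @param reg a [RegulationParameters-class].
#' @param sos an [SOSParameters-class].
#' @param schedule a [SignalSchedule-class] (default: c_p 0 -> 6 at 200 min,
#'   back to 0 at 500 min).
#' @param tMax end of the simulated window (min).
#' @param nRealizations ensemble size (500 reproduces the reference
#'   protocol; smaller values are useful for quick looks).
#' @param baseSeed integer base seed (per-realization seeds derived via
#'   [childSeed()]).
#' @param gridDt output grid spacing (min).
#' @return a [TrajectoryEnsemble-class].
#' @export
sosEnsemble <- function(reg = regulationParameters(),
                        sos = sosParameters(),
                        schedule = signalSchedule(),
                        tMax = 700, nRealizations = 500, baseSeed = 1,
                        gridDt = 1) {
  sys <- fullNetworkSystem(sos, reg)
  init <- sosInitialState(sos, reg)
  grid <- seq(0, tMax, by = gridDt)
  ens <- simulateEnsemble(sys, init, grid, nRealizations, baseSeed,
                          schedule = schedule)
  ens@metadata$schedule <- schedule
  ens@metadata$signalOnset <- signalOnsetTime(schedule)
  ens
}

#' Deterministic trajectory of the full SOS response
#'
#' Integrates the macroscopic rate equations of the full network under the
#' same schedule and initial state as [sosEnsemble()].
#'
#' @inheritParams sosEnsemble
#' @return a [Trajectory-class].
#' @export
sosDeterministic <- function(reg = regulationParameters(),
                             sos = sosParameters(),
                             schedule = signalSchedule(),
                             tMax = 700, gridDt = 1) {
  sys <- fullNetworkSystem(sos, reg)
  init <- sosInitialState(sos, reg)
  integrateDeterministic(sys, init, seq(0, tMax, by = gridDt),
                         schedule = schedule)
}

#' Lysis-time ensemble with Poisson-distributed plasmid numbers
#'
#' Repeats the SOS protocol with the plasmid copy number of each
#' realization drawn once from Poisson(\code{meanCopies}) at
#' initialization. Realizations that draw zero plasmids cannot express the
#' lysis gene and are counted as censored without simulation.
#'
#' @param meanCopies mean plasmid copy number (default 20).
#' @inheritParams sosEnsemble
#' @param onsetThreshold molecule threshold for peak detection.
#' @return a [LysisStatistics-class].
#' @export
poissonPlasmidVariant <- function(meanCopies = 20,
                                  reg = regulationParameters(),
                                  sos = sosParameters(),
                                  schedule = signalSchedule(),
                                  tMax = 700, nRealizations = 500,
                                  baseSeed = 1, onsetThreshold = 8) {
  set.seed(as.integer(childSeed(baseSeed, 999983)))
  copies <- stats::rpois(nRealizations, meanCopies)
  seeds <- childSeed(baseSeed, seq_len(nRealizations))
  onset <- peak <- rep(NA_real_, nRealizations)
  censored <- rep(TRUE, nRealizations)
  grid <- seq(0, tMax, by = 1)
  sysCache <- list(); initCache <- list()
  for (r in seq_len(nRealizations)) {
    if (copies[r] == 0L) next  # cannot lyse; censored
    key <- as.character(copies[r])
    if (is.null(sysCache[[key]])) {
      regR <- setParameters(reg, nSos = copies[r])
      sysCache[[key]] <- fullNetworkSystem(sos, regR)
      initCache[[key]] <- sosInitialState(sos, regR, nSos = copies[r])
    }
    sys <- sysCache[[key]]
    init <- initCache[[key]]
    tr <- simulateSSA(sys, init, grid, seeds[r], schedule = schedule)
    fp <- detectFirstPeak(tr, onsetThreshold = onsetThreshold)
    if (!fp$censored) {
      onset[r] <- fp$onset; peak[r] <- fp$peak; censored[r] <- FALSE
    }
  }
  new("LysisStatistics", onset = onset, peak = peak, censored = censored,
      signalOnset = signalOnsetTime(schedule),
      onsetThreshold = onsetThreshold, binWidth = 10,
      metadata = list(plasmidCopies = copies, seeds = seeds,
                      meanCopies = meanCopies))
}
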