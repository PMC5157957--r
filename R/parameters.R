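#' Construct reduced-model rate parameters
#'
#' Creates a [RegulationParameters-class] object. Called without arguments it
#' returns the package default parameterization of the colicin E2
#' post-transcriptional module: the CsrA production rate is
#' \code{alphaA = 58.52} molecules/min and the effective sRNA production
#' \code{N * alphaS = 57.5} molecules/min (with \code{N = 22} CsrA binding
#' sites per sRNA), which places the uninduced cell just below the expression
#' threshold. Rates not printed in the main literature are package defaults
#' calibrated to the documented regime (see the methods vignette for the
#' derivation of each value).
#'
#' @param alphaM effective long-mRNA transcription rate (molecules/min).
#'   Defaults to 0: in the full model this rate is generated by the SOS
#'   promoter dynamics, and the uninduced promoter is repressed.
#' @param alphaA CsrA-dimer production rate (molecules/min).
#' @param alphaS per-sRNA transcription rate; effective sRNA production is
#'   \code{N * alphaS}.
#' @param N effective CsrA binding sites per sRNA molecule.
#' @param deltaM,deltaA,deltaS first-order degradation rates (1/min).
#' @param kM,kS coupled-degradation rate constants (1/(molecule min)).
#' @param pM,pS CsrA removal probabilities in coupled degradation.
#' @param nSos ColE2 plasmid copy number.
#' @param cellVolume cell volume (um^3), bookkeeping only.
#' @return a validated [RegulationParameters-class] object.
#' @examples
#' p <- regulationParameters()
#' srnaProduction(p)  # 57.5
#' @export
regulationParameters <- function(alphaM = 0,
                                 alphaA = 58.52,
                                 alphaS = 57.5 / 22,
                                 N = 22,
                                 deltaM = 0.2,
                                 deltaA = 0.0014,
                                 deltaS = 0.25,
                                 kM = 1.0,
                                 kS = 1.0,
                                 pM = 1,
                                 pS = 1,
                                 nSos = 20,
                                 cellVolume = 0.65) {
  new("RegulationParameters",
      alphaM = alphaM, alphaA = alphaA, alphaS = alphaS, N = N,
      deltaM = deltaM, deltaA = deltaA, deltaS = deltaS,
      kM = kM, kS = kS, pM = pM, pS = pS,
      nSos = nSos, cellVolume = cellVolume)
}

#' Effective sRNA production rate N * alphaS
#' @param params a [RegulationParameters-class].
#' @return numeric scalar, molecules/min.
#' @export
srnaProduction <- function(params) {
  stopifnot(is(params, "RegulationParameters"))
  params@N * params@alphaS
}

#' Update fields of a parameter object
#'
#' Returns a copy of \code{params} with the named slots replaced, re-running
#' validity checks.
#'
#' @param params a [RegulationParameters-class] or [SOSParameters-class].
#' @param ... named scalar replacements, e.g. \code{alphaM = 3}.
#' @return object of the same class.
#' @examples
#' p <- setParameters(regulationParameters(), alphaM = 5, kM = 0)
#' @export
setParameters <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  bad <- setdiff(names(repl), slotNames(class(params)))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(repl)) slot(params, nm) <- as.numeric(repl[[nm]])
  validObject(params)
  params
}

#' Construct SOS network rate parameters
#'
#' Creates an [SOSParameters-class] object with the package default
#' LexA-RecA parameterization. The defaults put the uninduced cell in the
#' documented regime: LexA dimers are abundant (around 400 per cell), all
#' three promoter classes are almost always bound (open-promoter fraction
#' about 1 percent), short mRNA is present only in small numbers, and the
#' effective long-mRNA transcription rate stays well below the titration
#' threshold margin. During an SOS signal (c_p stepped to 6) the promoters
#' derepress and the effective long-mRNA rate rises to about 18
#' molecules/min, which drives CsrA titration on the documented ~40 min
#' deterministic time scale. Each default is motivated in the methods
#' vignette.
#'
#' @param alphaMlex,alphaMrec lexA/recA mRNA transcription per open promoter.
#' @param alphaMs,alphaMl short/long mRNA transcription per open SOS
#'   promoter.
#' @param betaLex,betaRec translation rates (protein per mRNA per min).
#' @param deltaMlex,deltaMrec,deltaMs mRNA degradation rates (1/min).
#' @param deltaLe,deltaR LexA-dimer and RecA degradation rates (1/min).
#' @param betaL,deltaL lysis-protein translation and degradation rates.
#' @param kOn,kOff LexA-promoter binding/unbinding rates.
#' @param cP baseline auto-cleavage coupling (overridden by the schedule).
#' @return a validated [SOSParameters-class] object.
#' @export
sosParameters <- function(alphaMlex = 12,
                          alphaMrec = 5,
                          alphaMs = 5,
                          alphaMl = 1.0,
                          betaLex = 5,
                          betaRec = 2,
                          deltaMlex = 0.3,
                          deltaMrec = 0.3,
                          deltaMs = 0.2,
                          deltaLe = 0.005,
                          deltaR = 0.5,
                          betaL = 1,
                          deltaL = 0.05,
                          kOn = 0.05,
                          kOff = 0.2,
                          cP = 0) {
  new("SOSParameters",
      alphaMlex = alphaMlex, alphaMrec = alphaMrec,
      alphaMs = alphaMs, alphaMl = alphaMl,
      betaLex = betaLex, betaRec = betaRec,
      deltaMlex = deltaMlex, deltaMrec = deltaMrec, deltaMs = deltaMs,
      deltaLe = deltaLe, deltaR = deltaR,
      betaL = betaL, deltaL = deltaL,
      kOn = kOn, kOff = kOff, cP = cP)
}

#' Construct a piecewise-constant c_p(t) schedule
#'
#' @param times segment start times (min); must begin at 0 and increase.
#' @param values c_p on each segment.
#' @return a [SignalSchedule-class].
#' @examples
#' signalSchedule()                       # default 0 -> 6 -> 0 step
#' signalSchedule(c(0, 100), c(0, 12))    # stronger, earlier signal
#' @export
signalSchedule <- function(times = c(0, 200, 500), values = c(0, 6, 0)) {
  new("SignalSchedule", times = as.numeric(times), values = as.numeric(values))
}

#' Evaluate a schedule at given times
#'
#' @param schedule a [SignalSchedule-class].
#' @param t numeric vector of times (min).
#' @return numeric vector of c_p values (left-closed segments).
#' @export
scheduleValue <- function(schedule, t) {
  stopifnot(is(schedule, "SignalSchedule"))
  idx <- findInterval(t, schedule@times, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  schedule@values[idx]
}

#' @describeIn signalSchedule time of SOS induction: the first breakpoint
#'   with a positive c_p (NA if the schedule never switches on).
#' @param schedule a [SignalSchedule-class].
#' @export
signalOnsetTime <- function(schedule) {
  stopifnot(is(schedule, "SignalSchedule"))
  on <- which(schedule@values > 0)
  if (length(on)) schedule@times[on[1L]] else NA_real_
}

setMethod("show", "RegulationParameters", function(object) {
  cat("RegulationParameters (reduced post-transcriptional model)\n")
  cat(sprintf("  production : alphaM = %g, alphaA = %g, N*alphaS = %g (N = %g)\n",
              object@alphaM, object@alphaA, srnaProduction(object), object@N))
  cat(sprintf("  degradation: deltaM = %g, deltaA = %g, deltaS = %g [1/min]\n",
              object@deltaM, object@deltaA, object@deltaS))
  cat(sprintf("  coupling   : kM = %g (pM = %g), kS = %g (pS = %g)\n",
              object@kM, object@pM, object@kS, object@pS))
  cat(sprintf("  plasmids   : nSos = %g, cell volume = %g um^3\n",
              object@nSos, object@cellVolume))
})

setMethod("show", "SOSParameters", function(object) {
  cat("SOSParameters (LexA-RecA SOS response network)\n")
  cat(sprintf("  transcription: lexA %g, recA %g, short %g, long %g per open promoter\n",
              object@alphaMlex, object@alphaMrec, object@alphaMs, object@alphaMl))
  cat(sprintf("  translation  : betaLex = %g, betaRec = %g, betaL = %g\n",
              object@betaLex, object@betaRec, object@betaL))
  cat(sprintf("  promoters    : kOn = %g, kOff = %g\n", object@kOn, object@kOff))
  cat(sprintf("  cleavage     : baseline cP = %g\n", object@cP))
})

setMethod("show", "SignalSchedule", function(object) {
  cat("SignalSchedule: c_p(t) piecewise constant\n")
  for (i in seq_along(object@times)) {
    end <- if (i < length(object@times)) sprintf("%g", object@times[i + 1L])
           else "Inf"
    cat(sprintf("  [%g, %s) min : c_p = %g\n", object@times[i], end,
                object@values[i]))
  }
})
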