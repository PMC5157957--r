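#' Detect the first long-mRNA peak of a trajectory
#'
#' The onset of the first peak is the first time the long-mRNA copy number
#' exceeds \code{onsetThreshold} (default 8 molecules); the peak time is
#' the time of the maximum within the contiguous excursion that starts at
#' the onset (while the count stays above the threshold; ties resolve to
#' the earliest time). A trajectory that never exceeds the threshold is
#' censored. The first burst is used as the proxy for cell lysis and toxin
#' release.
#'
#' @param trajectory a [Trajectory-class], or a numeric vector of counts
#'   (then \code{time} must be given).
#' @param species species to scan (default "M").
#' @param onsetThreshold molecule threshold (exceeded strictly).
#' @param time optional time vector when \code{trajectory} is a plain
#'   vector.
#' @return list with \code{onset}, \code{peak} (times, min),
#'   \code{peakHeight} and \code{censored}.
#' @examples
#' tt <- 0:10 * 10
#' m <- c(0, 0, 0, 9, 15, 25, 12, 5, 0, 0, 0)
#' detectFirstPeak(m, time = tt)  # onset 30, peak 50
#' @export
detectFirstPeak <- function(trajectory, species = "M", onsetThreshold = 8,
                            time = NULL) {
  if (is(trajectory, "Trajectory")) {
    m <- speciesCounts(trajectory, species)
    time <- trajectory@time
  } else {
    m <- as.numeric(trajectory)
    if (is.null(time)) time <- seq_along(m) - 1
  }
  stopifnot(length(m) == length(time))
  above <- m > onsetThreshold
  i0 <- which(above)[1L]
  if (is.na(i0))
    return(list(onset = NA_real_, peak = NA_real_,
                peakHeight = NA_real_, censored = TRUE))
  iEnd <- i0
  while (iEnd < length(m) && above[iEnd + 1L]) iEnd <- iEnd + 1L
  seg <- i0:iEnd
  iPeak <- seg[which.max(m[seg])]
  list(onset = time[i0], peak = time[iPeak], peakHeight = m[iPeak],
       censored = FALSE)
}

#' First-peak (lysis) time statistics of an ensemble
#'
#' Applies [detectFirstPeak()] to every realization and assembles the
#' empirical peak-time distribution relative to signal onset, censored
#' counts, and a bootstrap confidence interval on the histogram mode.
#'
#' @param ensemble a [TrajectoryEnsemble-class] (e.g. from
#'   [sosEnsemble()]).
#' @param species species to scan (default "M").
#' @param signalOnset induction time (min); defaults to the value recorded
#'   in the ensemble metadata, or 0.
#' @param onsetThreshold molecule threshold for the onset rule.
#' @param binWidth histogram bin width in minutes (left-closed bins with
#'   origin at signal onset).
#' @return a [LysisStatistics-class]; if every realization is censored the
#'   object is returned with a warning flag in its metadata.
#' @export
lysisTimeDistribution <- function(ensemble, species = "M",
                                  signalOnset = NULL, onsetThreshold = 8,
                                  binWidth = 10) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  if (is.null(signalOnset))
    signalOnset <- ensemble@metadata$signalOnset %||% 0
  n <- nRealizations(ensemble)
  onset <- peak <- rep(NA_real_, n)
  censored <- rep(TRUE, n)
  for (r in seq_len(n)) {
    fp <- detectFirstPeak(ensemble@counts[, species, r],
                          onsetThreshold = onsetThreshold,
                          time = ensemble@time)
    if (!fp$censored) {
      onset[r] <- fp$onset; peak[r] <- fp$peak; censored[r] <- FALSE
    }
  }
  meta <- list(seeds = ensemble@seeds, species = species)
  if (all(censored)) {
    warning("all realizations censored: no peak ever exceeded ",
            onsetThreshold, " molecules")
    meta$allCensored <- TRUE
  }
  new("LysisStatistics", onset = onset, peak = peak, censored = censored,
      signalOnset = signalOnset, onsetThreshold = onsetThreshold,
      binWidth = binWidth, metadata = meta)
}

#' Histogram of first-peak times relative to signal onset
#'
#' @param stats a [LysisStatistics-class].
#' @param nBoot bootstrap replicates for the CI on the mode.
#' @return list with data.frame \code{histogram} (bin left edge, count,
#'   density over uncensored runs), \code{mode} (bin midpoint of the
#'   maximal bin), \code{modeCI} (bootstrap percentile interval),
#'   \code{meanPeak}, \code{meanOnsetDelay} and \code{nCensored}.
#' @export
peakTimeHistogram <- function(stats, nBoot = 200L) {
  stopifnot(is(stats, "LysisStatistics"))
  ok <- !stats@censored
  rel <- stats@peak[ok] - stats@signalOnset
  relOnset <- stats@onset[ok] - stats@signalOnset
  if (!length(rel))
    return(list(histogram = data.frame(), mode = NA_real_,
                modeCI = c(NA_real_, NA_real_), meanPeak = NA_real_,
                meanOnsetDelay = NA_real_, nCensored = sum(!ok)))
  bw <- stats@binWidth
  lo <- floor(min(rel) / bw) * bw
  hi <- ceiling((max(rel) + 1e-9) / bw) * bw
  edges <- seq(lo, hi, by = bw)
  counts <- tabulate(findInterval(rel, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  hist <- data.frame(binStart = edges[-length(edges)], count = counts,
                     density = counts / sum(counts) / bw)
  modeOf <- function(x) {
    cnt <- tabulate(findInterval(x, edges), nbins = length(edges) - 1L)
    edges[which.max(cnt)] + bw / 2
  }
  mode <- modeOf(rel)
  boots <- replicate(nBoot,
                     modeOf(sample(rel, length(rel), replace = TRUE)))
  list(histogram = hist, mode = mode,
       modeCI = stats::quantile(boots, c(0.025, 0.975), names = FALSE),
       meanPeak = mean(rel), meanOnsetDelay = mean(relOnset),
       nCensored = sum(!ok))
}

setMethod("survivalFunction", "LysisStatistics", function(object,
                                                          times = NULL) {
  ok <- !object@censored
  pk <- object@peak[ok]
  if (is.null(times)) {
    hi <- if (length(pk)) max(pk) else object@signalOnset + 1
    times <- seq(0, ceiling(hi), by = 1)
  }
  n <- length(object@censored)
  surv <- vapply(times, function(t) {
    # censored realizations never peak: they survive every time point
    (sum(pk > t) + sum(!ok)) / n
  }, numeric(1))
  data.frame(time = times, survival = surv)
})

setMethod("show", "LysisStatistics", function(object) {
  ok <- !object@censored
  cat(sprintf("LysisStatistics: %d realizations, %d censored\n",
              length(ok), sum(!ok)))
  if (any(ok)) {
    cat(sprintf(
      "  first-peak time (rel. to signal at %g min): mean %.1f, range [%.0f, %.0f]\n",
      object@signalOnset, mean(object@peak[ok]) - object@signalOnset,
      min(object@peak[ok]) - object@signalOnset,
      max(object@peak[ok]) - object@signalOnset))
  }
})

#' Mean lysis time as a function of SOS signal strength
#'
#' Emulates different external stress levels by varying the LexA
#' auto-cleavage coupling c_p during the signal window and simulating one
#' ensemble per value. Stronger stress depletes LexA (and hence CsrA)
#' faster, so the mean first-peak time decreases with c_p.
#'
#' @param cPValues vector of c_p levels (the reference protocol uses 1, 3,
#'   6, 12, 15, 20, 30, 90).
#' @param reg,sos parameter objects.
#' @param signalStart,signalEnd signal window (min).
#' @param tMax simulation end (min).
#' @param nRealizations ensemble size per c_p value.
#' @param baseSeed integer base seed.
#' @param onsetThreshold molecule threshold for peak detection.
#' @return data.frame with one row per c_p: mean first-peak time relative
#'   to signal onset, its normal-approximation 95 percent CI, number
#'   censored, and ensemble size.
#' @export
stressSweep <- function(cPValues = c(1, 3, 6, 12, 15, 20, 30, 90),
                        reg = regulationParameters(),
                        sos = sosParameters(),
                        signalStart = 200, signalEnd = 500, tMax = 700,
                        nRealizations = 100, baseSeed = 1,
                        onsetThreshold = 8) {
  out <- data.frame()
  for (i in seq_along(cPValues)) {
    cp <- cPValues[i]
    sched <- signalSchedule(c(0, signalStart, signalEnd), c(0, cp, 0))
    ens <- sosEnsemble(reg, sos, sched, tMax = tMax,
                       nRealizations = nRealizations,
                       baseSeed = childSeed(baseSeed, i))
    st <- suppressWarnings(
      lysisTimeDistribution(ens, onsetThreshold = onsetThreshold))
    ok <- !st@censored
    rel <- st@peak[ok] - signalStart
    m <- if (length(rel)) mean(rel) else NA_real_
    se <- if (length(rel) > 1L) stats::sd(rel) / sqrt(length(rel)) else NA_real_
    out <- rbind(out, data.frame(
      cP = cp, meanLysisTime = m,
      ciLow = m - 1.96 * se, ciHigh = m + 1.96 * se,
      nCensored = sum(!ok), n = nRealizations(st)))
  }
  rownames(out) <- NULL
  out
}
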