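#' Linear-noise (van Kampen) moments of the reduced model
#'
#' Expands the chemical master equation of the reduced three-component
#' system around the macroscopic fixed point. To first order (the dominant
#' terms for second moments), the stationary fluctuations are Gaussian with
#' covariance C solving the Lyapunov equation
#' \deqn{J C + C J^\top + D = 0,}
#' where J is the Jacobian of the rate equations at the fixed point and
#' \eqn{D = \sum_j a_j(x^*) \nu_j \nu_j^\top} is the diffusion matrix built
#' from the propensities \eqn{a_j} and change vectors \eqn{\nu_j} of the
#' reaction scheme (including the split coupled-degradation channels).
#' The long-mRNA Fano factor is \code{Var(M)/mean(M)}.
#'
#' In the unregulated limit (\code{kM = kS = 0}) each species is an
#' independent birth-death process and the Fano factor is exactly 1.
#'
#' @param params a [RegulationParameters-class]; \code{alphaM} must be
#'   positive for the Fano factor to be defined.
#' @param order expansion order for second moments; only the first-order
#'   (dominant) terms are implemented, which the package treats as the
#'   reference noise computation. The expansion overestimates fluctuations
#'   close to the threshold, where mean abundances drop to a few molecules;
#'   summaries with mean M below 5 molecules are flagged unreliable.
#' @return a [NoiseSummary-class].
#' @examples
#' p <- setParameters(regulationParameters(), alphaM = 5, kM = 0, kS = 0)
#' lnaMoments(p)@fanoM  # exactly 1
#' @export
lnaMoments <- function(params, order = 1L) {
  stopifnot(is(params, "RegulationParameters"))
  if (!identical(as.integer(order), 1L))
    stop("only first-order (dominant) terms are implemented for second ",
         "moments; higher-order corrections are not available")
  p <- params
  if (p@alphaM <= 0)
    stop("fano factor undefined: mean long-mRNA abundance is 0 ",
         "(alphaM = 0)")
  ss <- steadyStateExact(p)
  M <- ss@M; A <- ss@A; S <- ss@S

  J <- matrix(c(
    -p@deltaM - p@kM * A, -p@kM * M,                              0,
    -p@kM * p@pM * A,     -p@deltaA - p@kM * p@pM * M - p@kS * p@pS * S,
                                                      -p@kS * p@pS * A,
    0,                    -p@kS * S,            -p@deltaS - p@kS * A),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("M", "A", "S"), c("M", "A", "S")))

  cMA <- p@kM * M * A   # total coupled-degradation flux M+A
  cSA <- p@kS * S * A
  D <- matrix(0, 3, 3, dimnames = dimnames(J))
  D["M", "M"] <- p@alphaM + p@deltaM * M + cMA
  D["A", "A"] <- p@alphaA + p@deltaA * A + p@pM * cMA + p@pS * cSA
  D["S", "S"] <- p@N * p@alphaS + p@deltaS * S + cSA
  D["M", "A"] <- D["A", "M"] <- p@pM * cMA
  D["S", "A"] <- D["A", "S"] <- p@pS * cSA

  I3 <- diag(3)
  K <- kronecker(I3, J) + kronecker(J, I3)
  if (abs(det(K)) < 1e-300)
    stop("non-hyperbolic fixed point: singular Lyapunov operator")
  C <- matrix(solve(K, -as.numeric(D)), 3, 3, dimnames = dimnames(J))
  C <- (C + t(C)) / 2
  new("NoiseSummary",
      means = c(M = M, A = A, S = S),
      covariance = C,
      fanoM = C["M", "M"] / M,
      order = 1L,
      reliable = M >= 5)
}

#' Fano factor of a named species from a NoiseSummary
#' @param summary a [NoiseSummary-class].
#' @param species one of "M", "A", "S".
#' @return numeric Fano factor Var/mean.
#' @export
fanoFactor <- function(summary, species = "M") {
  stopifnot(is(summary, "NoiseSummary"), species %in% c("M", "A", "S"))
  summary@covariance[species, species] / summary@means[[species]]
}

setMethod("show", "NoiseSummary", function(object) {
  cat("NoiseSummary (linear noise approximation, first-order terms)\n")
  cat(sprintf("  means: M = %.4g, A = %.4g, S = %.4g\n",
              object@means[["M"]], object@means[["A"]],
              object@means[["S"]]))
  cat(sprintf("  fano(M) = %.4g%s\n", object@fanoM,
              if (!object@reliable) "  [LNA-unreliable: mean M < 5]" else ""))
})

#' Long-mRNA Fano-factor heatmap over production rates
#'
#' Evaluates the linear-noise Fano factor of the long mRNA on a grid of
#' effective transcription rate alpha_M and effective sRNA production
#' N*alphaS. Fluctuations peak in a band along the expression threshold and
#' shrink with increasing sRNA production. Cells where the macroscopic mean
#' of M is below 5 molecules are flagged unreliable (small-number breakdown
#' of the expansion).
#'
#' @param alphaMGrid positive ascending vector of alpha_M values.
#' @param srnaProductionGrid positive ascending vector of N*alphaS values.
#' @param params a [RegulationParameters-class] with the remaining rates.
#' @return list with matrix \code{fanoM} (rows = alphaM), logical matrix
#'   \code{reliable}, matrix \code{meanM}, and the threshold locus.
#' @export
fanoHeatmap <- function(alphaMGrid, srnaProductionGrid, params) {
  stopifnot(is(params, "RegulationParameters"))
  if (any(alphaMGrid <= 0) || any(srnaProductionGrid <= 0))
    stop("grids must be positive")
  nM <- length(alphaMGrid); nS <- length(srnaProductionGrid)
  fan <- meanM <- matrix(NA_real_, nM, nS,
                         dimnames = list(alphaMGrid, srnaProductionGrid))
  rel <- matrix(NA, nM, nS)
  for (j in seq_len(nS)) {
    for (i in seq_len(nM)) {
      pij <- setParameters(params, alphaM = alphaMGrid[i],
                           alphaS = srnaProductionGrid[j] / params@N)
      ns <- lnaMoments(pij)
      fan[i, j] <- ns@fanoM
      meanM[i, j] <- ns@means[["M"]]
      rel[i, j] <- ns@reliable
    }
  }
  list(fanoM = fan, reliable = rel, meanM = meanM,
       threshold = thresholdLocus(srnaProductionGrid, params),
       alphaMGrid = alphaMGrid, srnaProductionGrid = srnaProductionGrid)
}

#' Empirical Fano factor from stochastic trajectories
#'
#' Pools post-burn-in grid samples over time and realizations to estimate
#' the stationary variance/mean ratio of one species, with a bootstrap
#' standard error over realizations. Stationarity is checked by a
#' split-half comparison of the pooled means; a drifting ensemble is
#' flagged (and a warning emitted).
#'
#' @param ensemble a [TrajectoryEnsemble-class] (or a single
#'   [Trajectory-class], treated as an ensemble of one).
#' @param species species name (default "M").
#' @param burnIn time (min) discarded from the start of each realization.
#' @param nBoot bootstrap replicates (over realizations when several are
#'   available, otherwise over time blocks).
#' @return list with \code{estimate}, \code{stderr}, \code{mean},
#'   \code{variance}, \code{stationary} (logical) and \code{nSamples}.
#' @export
empiricalFano <- function(ensemble, species = "M", burnIn = 0,
                          nBoot = 200L) {
  if (is(ensemble, "Trajectory")) {
    arr <- array(ensemble@counts,
                 dim = c(nrow(ensemble@counts), ncol(ensemble@counts), 1L),
                 dimnames = list(NULL, colnames(ensemble@counts), NULL))
    ensemble <- new("TrajectoryEnsemble", time = ensemble@time,
                    counts = arr, seeds = NA_real_, metadata = list())
  }
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  keep <- ensemble@time >= burnIn
  if (sum(keep) < 10L) stop("fewer than 10 post-burn-in samples")
  x <- ensemble@counts[keep, species, , drop = TRUE]
  x <- as.matrix(x)  # time x realization
  nT <- nrow(x); nR <- ncol(x)

  half1 <- mean(x[seq_len(nT %/% 2L), ])
  half2 <- mean(x[(nT %/% 2L + 1L):nT, ])
  pooledSd <- stats::sd(as.numeric(x))
  nEff <- max(nR, 2)  # realizations are the independent units
  stationary <- abs(half1 - half2) <= 3 * pooledSd / sqrt(nEff) +
    0.02 * (abs(half1) + abs(half2)) / 2 + 1e-12
  if (!stationary)
    warning("ensemble appears non-stationary after burn-in (split-half ",
            "means ", signif(half1, 4), " vs ", signif(half2, 4), ")")

  fanoOf <- function(v) {
    m <- mean(v)
    if (m == 0) return(NA_real_)
    stats::var(v) / m
  }
  est <- fanoOf(as.numeric(x))
  boots <- numeric(nBoot)
  if (nR > 1L) {
    for (b in seq_len(nBoot)) {
      idx <- sample.int(nR, nR, replace = TRUE)
      boots[b] <- fanoOf(as.numeric(x[, idx]))
    }
  } else {
    # block bootstrap over time for a single long trajectory
    nBlocks <- 20L
    bl <- split(seq_len(nT),
                cut(seq_len(nT), nBlocks, labels = FALSE))
    for (b in seq_len(nBoot)) {
      idx <- unlist(bl[sample.int(nBlocks, nBlocks, replace = TRUE)],
                    use.names = FALSE)
      boots[b] <- fanoOf(x[idx, 1L])
    }
  }
  list(estimate = est, stderr = stats::sd(boots, na.rm = TRUE),
       mean = mean(x), variance = stats::var(as.numeric(x)),
       stationary = stationary, nSamples = length(x))
}
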