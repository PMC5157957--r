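# Stationarity of the reduced model reduces to a cubic in the free CsrA
# abundance A: substituting the stationary M = alphaM/(deltaM + kM*A) and
# S = N*alphaS/(deltaS + kS*A) into the CsrA balance and clearing
# denominators gives P(A) = c3 A^3 + c2 A^2 + c1 A + c0 = 0.
.cubicCoefficients <- function(p) {
  aM <- p@alphaM; aA <- p@alphaA; aSN <- p@N * p@alphaS
  dM <- p@deltaM; dA <- p@deltaA; dS <- p@deltaS
  kM <- p@kM; kS <- p@kS; pM <- p@pM; pS <- p@pS
  c0 <- aA * dM * dS
  c1 <- aA * (dM * kS + dS * kM) - dA * dM * dS -
        kM * dS * pM * aM - kS * dM * pS * aSN
  c2 <- aA * kM * kS - dA * (dM * kS + dS * kM) -
        kM * kS * (pM * aM + pS * aSN)
  c3 <- -dA * kM * kS
  c(c0, c1, c2, c3)
}

.stateFromA <- function(p, A) {
  c(M = p@alphaM / (p@deltaM + p@kM * A),
    A = A,
    S = p@N * p@alphaS / (p@deltaS + p@kS * A))
}

.relativeResidual <- function(p, st) {
  scale <- max(p@alphaM, p@alphaA, p@N * p@alphaS, 1)
  max(abs(reducedDerivatives(st, p))) / scale
}

.regimeLabel <- function(p) {
  if (p@kM <= 0 || p@kS <= 0) {
    # no coupled degradation, no titration threshold: expression is free
    return(if (p@alphaM > 0) "super_threshold" else "sub_threshold")
  }
  if (thresholdCondition(p)$superThreshold) "super_threshold" else
    "sub_threshold"
}

#' Exact stationary state of the reduced model
#'
#' Solves the stationary cubic for the free CsrA abundance (obtained by
#' eliminating M and S from the rate equations) with a numerical polynomial
#' root finder and back-substitutes. Among real non-negative roots that give
#' non-negative abundances for all three species, the unique admissible one
#' is returned; if several qualify the one reached by forward integration
#' from the empty state is selected.
#'
#' @param params a [RegulationParameters-class].
#' @return a [SteadyState-class] with branch \code{"exact_numeric"}.
#' @examples
#' steadyStateExact(regulationParameters())  # sub-threshold: A* ~ 850
#' @export
steadyStateExact <- function(params) {
  stopifnot(is(params, "RegulationParameters"))
  p <- params
  co <- .cubicCoefficients(p)
  # trim numerically-zero leading coefficients (degenerate limits such as
  # kM = kS = 0 or deltaA = 0 lower the polynomial degree)
  tol <- 1e-14 * max(abs(co), 1)
  deg <- max(which(abs(co) > tol))
  roots <- if (deg == 1L) numeric(0) else polyroot(co[seq_len(deg)])
  A <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + Mod(roots))])
  A <- A[A > -1e-9]
  A[A < 0] <- 0
  if (!length(A)) stop("no admissible non-negative stationary root found")
  if (length(A) > 1L) {
    # multiple admissible roots: pick the one reached from the empty state
    tr <- integrateDeterministic(p, c(M = 0, A = 0, S = 0),
                                 c(0, 10^(1:5)))
    Aend <- speciesCounts(tr, "A")[6L]
    A <- A[which.min(abs(A - Aend))]
  }
  st <- .stateFromA(p, A)
  res <- .relativeResidual(p, st)
  if (res > 1e-9) {
    # polish with one round of damped Newton on P(A)
    f <- function(a) sum(co * a^(0:3))
    fp <- function(a) sum(co[-1] * (1:3) * a^(0:2))
    for (i in 1:50) {
      step <- f(A) / fp(A)
      A <- max(A - step, 0)
      if (abs(step) < 1e-14 * (1 + A)) break
    }
    st <- .stateFromA(p, A)
    res <- .relativeResidual(p, st)
  }
  new("SteadyState", M = st[["M"]], A = st[["A"]], S = st[["S"]],
      regime = .regimeLabel(p), branch = "exact_numeric",
      residual = res, params = p)
}

# numerically stable roots of a*x^2 + b*x + c = 0
.quadRoots <- function(a, b, c) {
  if (abs(a) < 1e-300) {
    if (abs(b) < 1e-300) return(numeric(0))
    return(-c / b)
  }
  disc <- b^2 - 4 * a * c
  if (disc < 0) return(numeric(0))
  q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
  r <- c(q / a, if (abs(q) > 0) c / q else -b / a)
  unique(r)
}

#' Approximate stationary state (two quadratic branches)
#'
#' The stationary cubic is simplified in the two abundance regimes of free
#' CsrA: for small A the cubic term is negligible
#' (\emph{low_abundance_approx}, the super-threshold side), for large A the
#' constant term is negligible (\emph{high_abundance_approx}, the
#' sub-threshold side). Each case is an easily solvable quadratic. Equating
#' the omitted terms (\code{|c3| A^3 = c0}) yields the transition criterion
#' between the branches; the branch whose omitted term is smaller at its own
#' root is returned.
#'
#' @param params a [RegulationParameters-class].
#' @return a [SteadyState-class] with the branch label recorded.
#' @export
steadyStateApprox <- function(params) {
  stopifnot(is(params, "RegulationParameters"))
  p <- params
  co <- .cubicCoefficients(p)
  c0 <- co[1]; c1 <- co[2]; c2 <- co[3]; c3 <- co[4]
  tol <- 1e-14 * max(abs(co), 1)

  if (abs(c3) <= tol || abs(c2) <= tol) {
    # the cubic already degenerates to (at most) a quadratic: the
    # approximation coincides with the exact solution
    ex <- steadyStateExact(p)
    ex@branch <- "exact_numeric"
    return(ex)
  }

  pickNonNeg <- function(r) {
    r <- r[is.finite(r) & r > -1e-12]
    if (!length(r)) return(NA_real_)
    sort(pmax(r, 0))
  }
  lowRoots <- pickNonNeg(.quadRoots(c2, c1, c0))   # omit c3 A^3
  highRoots <- pickNonNeg(.quadRoots(c3, c2, c1))  # omit c0
  Alow <- if (all(is.na(lowRoots))) NA_real_ else lowRoots[1L]
  Ahigh <- if (all(is.na(highRoots))) NA_real_ else
    highRoots[length(highRoots)]

  omittedLow <- if (is.na(Alow)) Inf else abs(c3) * Alow^3
  omittedHigh <- c0
  useLow <- is.na(Ahigh) || (!is.na(Alow) && omittedLow <= omittedHigh)
  A <- if (useLow) Alow else Ahigh
  branch <- if (useLow) "low_abundance_approx" else "high_abundance_approx"
  if (is.na(A)) stop("no admissible approximate root found")
  st <- .stateFromA(p, A)
  new("SteadyState", M = st[["M"]], A = st[["A"]], S = st[["S"]],
      regime = .regimeLabel(p), branch = branch,
      residual = .relativeResidual(p, st), params = p)
}

#' Expression threshold of the reduced model
#'
#' The free long mRNA stays at (near) zero as long as CsrA production
#' outpaces the total production of its titrating targets. From the
#' high-abundance (sub-threshold) quadratic branch, the abundant-CsrA root
#' exists while its leading coefficient ratio is positive, which vanishes at
#' \deqn{p_M \alpha_M + p_S N \alpha_S =
#'       \alpha_A - \delta_A(\delta_M/k_M + \delta_S/k_S).}
#' For slow CsrA degradation (\eqn{\delta_A \to 0}) and certain coupled
#' removal (\eqn{p = 1}) this is exactly
#' \eqn{\alpha_M + N\alpha_S = \alpha_A}: the threshold lies where CsrA
#' production equals the summed production of long mRNA and effective sRNA.
#'
#' @param params a [RegulationParameters-class]; requires \code{kM, kS > 0}.
#' @return list with \code{superThreshold} (logical), \code{margin}
#'   (effective target production minus the locus value, molecules/min) and
#'   \code{locusAlphaA} (the threshold value of the combined production).
#' @seealso [thresholdLocus()]
#' @export
thresholdCondition <- function(params) {
  stopifnot(is(params, "RegulationParameters"))
  p <- params
  if (p@kM <= 0 || p@kS <= 0)
    stop("threshold requires positive coupled-degradation rates kM and kS")
  effProd <- p@pM * p@alphaM + p@pS * p@N * p@alphaS
  locus <- p@alphaA - p@deltaA * (p@deltaM / p@kM + p@deltaS / p@kS)
  list(superThreshold = effProd > locus,
       margin = effProd - locus,
       locusAlphaA = locus)
}

#' Threshold locus in the (alpha_M, effective sRNA production) plane
#'
#' @param srnaProductionGrid numeric vector of effective sRNA production
#'   values N*alphaS (molecules/min).
#' @param params a [RegulationParameters-class] providing all other rates.
#' @return data.frame with columns \code{srnaProduction} and
#'   \code{alphaM}: the long-mRNA production rate on the threshold
#'   (negative values are reported as NA: the threshold is unreachable
#'   there).
#' @export
thresholdLocus <- function(srnaProductionGrid, params) {
  stopifnot(is(params, "RegulationParameters"))
  p <- params
  if (p@kM <= 0 || p@kS <= 0)
    stop("threshold requires positive coupled-degradation rates kM and kS")
  locus <- p@alphaA - p@deltaA * (p@deltaM / p@kM + p@deltaS / p@kS)
  aM <- (locus - p@pS * srnaProductionGrid) / p@pM
  aM[aM < 0] <- NA_real_
  data.frame(srnaProduction = srnaProductionGrid, alphaM = aM)
}

#' Stationary abundance maps over a production-rate grid
#'
#' Evaluates stationary abundances of all three species over a grid of
#' long-mRNA transcription rates and effective sRNA production rates,
#' together with the branch-transition line of the quadratic approximation.
#' Abundances below \code{zeroTol} are reported as 0 in the \code{display}
#' maps (the raw values remain in \code{M}, \code{A}, \code{S}).
#'
#' @param alphaMGrid ascending positive vector of alpha_M values.
#' @param srnaProductionGrid ascending positive vector of effective sRNA
#'   production values (N*alphaS).
#' @param params a [RegulationParameters-class] providing the other rates.
#' @param exact use [steadyStateExact()] instead of the quadratic
#'   approximation.
#' @param zeroTol display threshold in molecules (default 1e-3).
#' @return list with matrices \code{M}, \code{A}, \code{S} (rows = alphaM,
#'   columns = sRNA production), clipped \code{display} copies, a
#'   \code{branch} character matrix, the approximation \code{transition}
#'   line (data.frame) and the threshold locus.
#' @export
phaseSurface <- function(alphaMGrid, srnaProductionGrid, params,
                         exact = FALSE, zeroTol = 1e-3) {
  stopifnot(is(params, "RegulationParameters"))
  if (any(alphaMGrid < 0) || any(diff(alphaMGrid) <= 0))
    stop("'alphaMGrid' must be non-negative and ascending")
  if (any(srnaProductionGrid < 0) || any(diff(srnaProductionGrid) <= 0))
    stop("'srnaProductionGrid' must be non-negative and ascending")
  nM <- length(alphaMGrid); nS <- length(srnaProductionGrid)
  M <- A <- S <- matrix(NA_real_, nM, nS,
                        dimnames = list(alphaMGrid, srnaProductionGrid))
  branch <- matrix(NA_character_, nM, nS)
  solver <- if (exact) steadyStateExact else steadyStateApprox
  for (j in seq_len(nS)) {
    for (i in seq_len(nM)) {
      pij <- setParameters(params, alphaM = alphaMGrid[i],
                           alphaS = srnaProductionGrid[j] / params@N)
      ss <- solver(pij)
      M[i, j] <- ss@M; A[i, j] <- ss@A; S[i, j] <- ss@S
      branch[i, j] <- ss@branch
    }
  }
  clip <- function(x) { x[x < zeroTol] <- 0; x }
  # branch-transition line: for each sRNA production, the alpha_M at which
  # the selected quadratic branch switches
  transAlphaM <- rep(NA_real_, nS)
  for (j in seq_len(nS)) {
    sw <- which(branch[-1, j] != branch[-nM, j])
    if (length(sw))
      transAlphaM[j] <- (alphaMGrid[sw[1L]] + alphaMGrid[sw[1L] + 1L]) / 2
  }
  list(M = M, A = A, S = S,
       display = list(M = clip(M), A = clip(A), S = clip(S)),
       branch = branch,
       transition = data.frame(srnaProduction = srnaProductionGrid,
                               alphaM = transAlphaM),
       threshold = thresholdLocus(srnaProductionGrid, params),
       alphaMGrid = alphaMGrid, srnaProductionGrid = srnaProductionGrid)
}

setMethod("abundances", "SteadyState", function(object) {
  c(M = object@M, A = object@A, S = object@S)
})

setMethod("show", "SteadyState", function(object) {
  cat(sprintf("SteadyState [%s, %s]\n", object@regime, object@branch))
  cat(sprintf("  M* = %.6g  A* = %.6g  S* = %.6g molecules\n",
              object@M, object@A, object@S))
  cat(sprintf("  relative stationary residual: %.3g\n", object@residual))
})
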