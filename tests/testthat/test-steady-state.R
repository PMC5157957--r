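test_that("stationary solutions recover the decoupled closed forms", {
  p <- setParameters(smallTitration(), kM = 0, kS = 0)
  ss <- steadyStateExact(p)
  expect_equal(unname(abundances(ss)),
               c(p@alphaM / p@deltaM, p@alphaA / p@deltaA,
                 srnaProduction(p) / p@deltaS), tolerance = 1e-9)
  # no targets to titrate: all CsrA stays free
  p2 <- setParameters(regulationParameters(), alphaM = 0, alphaS = 0)
  ss2 <- steadyStateExact(p2)
  expect_equal(ss2@M, 0)
  expect_equal(ss2@S, 0)
  expect_equal(ss2@A, p2@alphaA / p2@deltaA, tolerance = 1e-9)
})

test_that("exact stationary roots agree with forward integration and have
           tiny residuals", {
  p <- regulationParameters()
  for (aM in c(5, 30, 45)) {
    for (prod in c(20, 40)) {
      pc <- setParameters(p, alphaM = aM, alphaS = prod / p@N)
      ss <- steadyStateExact(pc)
      # residual invariant: far below 1e-6 of the largest production rate
      expect_lt(ss@residual, 1e-9)
      # independent oracle: integrate the rate equations to stationarity
      tr <- integrateDeterministic(pc, c(M = 0, A = 0, S = 0),
                                   c(0, 2e4, 6e4))
      expect_equal(unname(tr@counts[3, "A"]), ss@A, tolerance = 1e-3)
      expect_equal(unname(tr@counts[3, "M"]), ss@M, tolerance = 1e-3)
    }
  }
})

test_that("quadratic approximation stays within 5% of the exact solution
           outside the threshold band", {
  p <- regulationParameters()
  for (prod in c(20, 40)) {
    locus <- thresholdLocus(prod, p)$alphaM
    for (aM in seq(2, 56, by = 3)) {
      if (abs(aM + prod - (p@alphaA)) < 2) next  # threshold band
      if (abs(aM - locus) < 2) next
      pc <- setParameters(p, alphaM = aM, alphaS = prod / p@N)
      ex <- steadyStateExact(pc)
      ap <- steadyStateApprox(pc)
      for (sp in c("M", "A", "S")) {
        e <- abundances(ex)[[sp]]; a <- abundances(ap)[[sp]]
        expect_lt(abs(a - e), 0.05 * max(e, 1))
      }
      expect_true(ap@branch %in% c("low_abundance_approx",
                                   "high_abundance_approx"))
    }
  }
})

test_that("regime labels and branch selection are consistent with the
           threshold condition", {
  p <- regulationParameters()  # alphaM = 0, N alphaS = 57.5 < alphaA
  expect_false(thresholdCondition(p)$superThreshold)
  expect_identical(steadyStateExact(p)@regime, "sub_threshold")
  expect_identical(steadyStateApprox(p)@branch, "high_abundance_approx")
  # far above the locus: combined production twice the CsrA supply
  pSup <- setParameters(p, alphaM = 2 * p@alphaA - srnaProduction(p))
  expect_true(thresholdCondition(pSup)$superThreshold)
  expect_identical(steadyStateApprox(pSup)@branch, "low_abundance_approx")
  expect_error(thresholdCondition(setParameters(p, kM = 0)), "positive")
})

test_that("the expression threshold is sharp at balanced production", {
  p <- regulationParameters()
  for (prod in c(20, 40)) {
    locus <- thresholdLocus(prod, p)$alphaM
    aMs <- seq(0.3, 1.5, length.out = 50) * locus
    Mstar <- vapply(aMs, function(aM)
      steadyStateExact(setParameters(p, alphaM = aM,
                                     alphaS = prod / p@N))@M,
      numeric(1))
    # deep sub-threshold mRNA is numerically zero, super-threshold it is
    # macroscopic, and the half-molecule crossing hugs the locus
    expect_lt(min(Mstar), 1e-3)
    expect_gt(max(Mstar), 1)
    expect_true(all(diff(Mstar) > -1e-9))
    cross <- aMs[which(Mstar > 0.5)[1]]
    expect_lt(abs(cross - locus), 2)
  }
})

test_that("phase surfaces show mutual exclusion and monotone response", {
  p <- regulationParameters()
  surf <- phaseSurface(seq(2, 60, length.out = 9),
                       seq(5, 55, length.out = 9), p)
  M <- surf$M; A <- surf$A
  # mutual exclusion: away from the threshold band, at most one of free
  # mRNA and free CsrA is macroscopic. The crossover region is wider on
  # the super-threshold side, where residual free CsrA decays on the
  # scale of the saturation terms (N alphaS deltaS/kS + alphaM deltaM/kM,
  # about 15 molecules/min for the default rates)
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    d <- surf$alphaMGrid[i] + surf$srnaProductionGrid[j] - p@alphaA
    if (d < -4 || d > 15) expect_lt(min(M[i, j], A[i, j]), 1)
  }
  # monotone: more production of either target raises free mRNA and
  # depletes free CsrA
  expect_true(all(apply(M, 2, diff) > -1e-8))
  expect_true(all(apply(t(M), 2, diff) > -1e-8))
  expect_true(all(apply(A, 2, diff) < 1e-8))
  expect_true(all(apply(t(A), 2, diff) < 1e-8))
  # transition line of the approximation is located on each column
  expect_true(any(is.finite(surf$transition$alphaM)))
})
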