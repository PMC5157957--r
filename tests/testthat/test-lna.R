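test_that("the unregulated limit has Fano factor exactly one", {
  p <- regulationParameters(alphaM = 7, alphaA = 3, alphaS = 4, N = 2,
                            deltaM = 0.5, deltaA = 0.1, deltaS = 0.3,
                            kM = 0, kS = 0)
  ns <- lnaMoments(p)
  expect_equal(ns@fanoM, 1, tolerance = 1e-12)
  expect_equal(fanoFactor(ns, "A"), 1, tolerance = 1e-12)
  expect_equal(fanoFactor(ns, "S"), 1, tolerance = 1e-12)
  # independent species: vanishing cross-covariances
  expect_lt(max(abs(ns@covariance[upper.tri(ns@covariance)])), 1e-10)
  expect_error(lnaMoments(setParameters(p, alphaM = 0)), "undefined")
  expect_error(lnaMoments(p, order = 2), "first-order")
})

test_that("relabeling symmetry swaps mRNA and sRNA fluctuations", {
  p <- regulationParameters(alphaM = 12, alphaA = 30, alphaS = 25, N = 1,
                            deltaM = 0.4, deltaA = 0.02, deltaS = 0.15,
                            kM = 0.08, kS = 0.2, pM = 0.7, pS = 0.9)
  swapped <- regulationParameters(
    alphaM = srnaProduction(p), deltaM = p@deltaS, kM = p@kS, pM = p@pS,
    alphaS = p@alphaM, N = 1, deltaS = p@deltaM, kS = p@kM, pS = p@pM,
    alphaA = p@alphaA, deltaA = p@deltaA)
  expect_equal(lnaMoments(swapped)@fanoM,
               fanoFactor(lnaMoments(p), "S"), tolerance = 1e-9)
})

test_that("near-threshold covariance is anti-correlated and the heatmap
           localizes fluctuations to the threshold", {
  p <- regulationParameters()
  pn <- setParameters(p, alphaM = 40, alphaS = 20 / p@N)
  ns <- lnaMoments(pn)
  expect_lt(ns@covariance["M", "A"], 0)
  expect_lt(ns@covariance["S", "A"], 0)
  ev <- eigen(ns@covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)

  hm <- fanoHeatmap(seq(32, 70, by = 2), c(20, 30), p)
  locus20 <- thresholdLocus(20, p)$alphaM
  ridge <- hm$alphaMGrid[which.max(hm$fanoM[, 1])]
  # largest fluctuations slightly above the threshold
  expect_gt(ridge, locus20)
  expect_lt(ridge, locus20 + 10)
  # deep super-threshold tail decays toward the Poisson value from above
  lastRow <- hm$fanoM[nrow(hm$fanoM), 1]
  expect_lt(lastRow, max(hm$fanoM[, 1]))
  expect_gt(lastRow, 1)
  # stronger sRNA production dampens fluctuations above threshold
  above <- hm$alphaMGrid > locus20 + 2
  expect_true(all(hm$fanoM[above, 2] < hm$fanoM[above, 1]))
  # cells with tiny mean mRNA are flagged unreliable
  expect_true(any(!hm$reliable) || all(hm$meanM >= 5))
})

test_that("the empirical Fano estimator recovers known statistics", {
  # birth-death: Poisson, Fano 1
  fx <- fixtureGenerator("birth_death")
  ens <- simulateEnsemble(fx$system, c(M = 10), seq(0, 150, by = 1),
                          nRealizations = 30, baseSeed = 7)
  ef <- empiricalFano(ens, "M", burnIn = 15)
  expect_true(ef$stationary)
  expect_lt(abs(ef$estimate - 1), 3 * ef$stderr + 0.02)
  # immigration in pairs: batch size 2 gives Fano (b + 1)/2 = 1.5
  sys2 <- pairImmigrationSystem(lambda = 5, delta = 1)
  ens2 <- simulateEnsemble(sys2, c(X = 10), seq(0, 150, by = 1),
                           nRealizations = 30, baseSeed = 8)
  ef2 <- empiricalFano(ens2, "X", burnIn = 15)
  expect_lt(abs(ef2$estimate - 1.5), 3 * ef2$stderr + 0.05)
  # a drifting ensemble is flagged
  drift <- simulateEnsemble(pureBirthSystem(5), c(X = 0),
                            seq(0, 100, by = 1), 5, 3)
  expect_warning(efd <- empiricalFano(drift, "X"), "non-stationary")
  expect_false(efd$stationary)
})
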