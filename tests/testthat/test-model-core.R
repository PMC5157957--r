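test_that("reduced derivatives match the reaction-network evaluation", {
  p <- regulationParameters()
  # all bilinear terms vanish at the origin
  expect_equal(reducedDerivatives(c(M = 0, A = 0, S = 0), p),
               c(M = p@alphaM, A = p@alphaA, S = srnaProduction(p)))
  # decoupled birth-death fixed point
  p0 <- setParameters(smallTitration(), kM = 0, kS = 0)
  fp <- c(M = p0@alphaM / p0@deltaM, A = p0@alphaA / p0@deltaA,
          S = srnaProduction(p0) / p0@deltaS)
  expect_equal(reducedDerivatives(fp, p0), c(M = 0, A = 0, S = 0))
  # random states: closed-form derivatives vs the independently assembled
  # stoichiometry-times-flux evaluation of the reaction system
  set.seed(101)
  for (i in 1:20) {
    pr <- regulationParameters(
      alphaM = runif(1, 0, 50), alphaA = runif(1, 0, 80),
      alphaS = runif(1, 0, 5), N = sample(1:25, 1),
      deltaM = runif(1, 0.01, 1), deltaA = runif(1, 0.001, 0.1),
      deltaS = runif(1, 0.01, 1), kM = runif(1, 0, 0.5),
      kS = runif(1, 0, 0.5), pM = runif(1), pS = runif(1))
    st <- c(M = runif(1, 0, 100), A = runif(1, 0, 1000),
            S = runif(1, 0, 300))
    sys <- buildReactionSystem(pr, "reduced")
    expected <- ColE2sim:::.massActionDeriv(sys, st[sys@species], 1)
    expect_equal(unname(reducedDerivatives(st, pr)[sys@species]),
                 expected, tolerance = 1e-12)
  }
  expect_error(reducedDerivatives(c(M = -1, A = 0, S = 0), p),
               "non-negative")
})

test_that("effective transcription rate follows stationary promoter occupancy", {
  expect_equal(effectiveTranscriptionRate(2, onProbability = 1, nSos = 20),
               40)
  expect_equal(effectiveTranscriptionRate(2, onProbability = 0, nSos = 20),
               0)
  expect_error(effectiveTranscriptionRate(2, onProbability = 1.4),
               "\\[0, 1\\]")
  # occupancy formula against a long SSA run of the two-state promoter
  kOn <- 0.02; kOff <- 0.3; Le <- 40
  pOn <- promoterOnProbability(kOn, kOff, Le)
  expect_equal(pOn, kOff / (kOff + kOn * Le))
  sys <- promoterSystem(kOn, kOff, Le)
  tr <- simulateSSA(sys, c(P = 1), seq(0, 20000, by = 0.5), seed = 4)
  occ <- mean(speciesCounts(tr, "P"))
  # switching rate ~ 1/min: 2e4 min gives ~2e4 sojourns, se ~ 0.005
  expect_lt(abs(occ - pOn), 0.02)
})

test_that("multi-site sRNA reduction yields the one-site effective rates", {
  r1 <- effectiveSrnaReduction(1, 3, list(vPlus = 2, vMinus = 8,
                                          deltaS = 0.4))
  expect_equal(r1$alphaSEffective, 3)   # N = 1: production unchanged
  r22 <- effectiveSrnaReduction(22, 3, list(vPlus = 2, vMinus = 8,
                                            deltaS = 0.4))
  expect_equal(r22$alphaSEffective, 66)
  expect_equal(r22$kS, 0.4 * 2 / 8)
  expect_equal(r22$pS, 1)
  expect_match(r22$assumptions, "fast")
  # irreversible binding: sequestration at the bare binding rate
  expect_equal(effectiveSrnaReduction(2, 1, list(vPlus = 5, vMinus = 0,
                                                 deltaS = 0.4))$kS, 5)
  expect_error(effectiveSrnaReduction(0.5, 1, list(vPlus = 1, vMinus = 1,
                                                   deltaS = 1)), ">= 1")
})

test_that("deterministic integration is exact in the linear limit and
           converges to the stationary cubic root", {
  p <- setParameters(smallTitration(), kM = 0, kS = 0)
  tt <- seq(0, 40, by = 2)
  tr <- integrateDeterministic(p, c(M = 0, A = 0, S = 0), tt)
  # closed-form exponential relaxation of each birth-death species
  expect_equal(speciesCounts(tr, "M"),
               p@alphaM / p@deltaM * (1 - exp(-p@deltaM * tt)),
               tolerance = 1e-6)
  expect_equal(speciesCounts(tr, "A"),
               p@alphaA / p@deltaA * (1 - exp(-p@deltaA * tt)),
               tolerance = 1e-6)

  # long-time limit matches the exact stationary state of the full model
  p2 <- smallTitration()
  ss <- steadyStateExact(p2)
  tr2 <- integrateDeterministic(p2, c(M = 3, A = 100, S = 0),
                                c(0, 500, 2000))
  expect_equal(unname(tr2@counts[3, c("M", "A", "S")]),
               unname(abundances(ss)), tolerance = 1e-5)

  # halving the tolerances barely moves the endpoint
  tr3 <- integrateDeterministic(p2, c(M = 3, A = 100, S = 0),
                                c(0, 500, 2000),
                                rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(tr3@counts[3, ] - tr2@counts[3, ])) /
              max(tr2@counts[3, ]), 1e-6)

  expect_error(integrateDeterministic(p2, c(M = -1), c(0, 1)),
               "non-negative")
  expect_error(integrateDeterministic(p2, c(M = 0), c(1, 0)),
               "increasing")
})
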