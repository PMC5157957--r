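test_that("reaction systems encode the documented reaction sets", {
  p <- smallTitration()  # pM = pS = 1
  sys <- buildReactionSystem(p, "reduced")
  # certain co-degradation: 3 productions + 3 degradations + 2 joint
  # removals
  expect_length(sys@rates, 8)
  j <- grep("M\\+A \\(A removed\\)", sys@reactionNames)
  expect_equal(unname(sys@stoich[c("M", "A", "S"), j]), c(-1, -1, 0))
  expect_equal(sys@rates[j], p@kM)

  # survival probability: split propensities kM pM and kM (1 - pM)
  ph <- setParameters(p, pM = 0.5)
  sysH <- buildReactionSystem(ph, "reduced")
  jr <- grep("M\\+A \\(A removed\\)", sysH@reactionNames)
  js <- grep("M\\+A \\(A survives\\)", sysH@reactionNames)
  expect_equal(sysH@rates[jr], ph@kM * 0.5)
  expect_equal(sysH@rates[js], ph@kM * 0.5)
  expect_equal(unname(sysH@stoich[c("M", "A"), js]), c(-1, 0))
  # both channels consume the M-A encounter
  expect_equal(unname(sysH@orders[c("M", "A"), js]), c(1, 1))

  # detailed variant: free-site combinatorics (N - n) on binding
  sysD <- buildReactionSystem(p, "detailed",
                              detailedRates = list(vPlus = 1, vMinus = 2))
  b0 <- grep("^CsrA binding C0", sysD@reactionNames)
  b1 <- grep("^CsrA binding C1", sysD@reactionNames)
  expect_equal(sysD@rates[b0], 2 * 1)  # two free sites on C0
  expect_equal(sysD@rates[b1], 1 * 1)
  u2 <- grep("unbinding C2", sysD@reactionNames)
  expect_equal(sysD@rates[u2], 2 * 2)  # two bound dimers leave C2
  expect_error(buildReactionSystem(setParameters(p, pM = 0.5), "detailed"),
               "pM = pS = 1")
  expect_error(buildReactionSystem(p, "full_sos"), "SOSParameters")
  # the audit serialization lists every reaction once
  expect_length(writeReactionList(sys), 8)
})

test_that("the direct method is exact for elementary processes and
           deterministic under a fixed seed", {
  # pure birth: event count over [0, T] is Poisson(lambda T)
  lam <- 4; T <- 25
  counts <- vapply(1:200, function(i) {
    tr <- simulateSSA(pureBirthSystem(lam), c(X = 0), c(0, T),
                      seed = childSeed(12, i))
    tr@counts[2, "X"]
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam * T), 3 * sqrt(lam * T / 200))
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.3)

  # seed determinism: byte-identical paths
  sys <- buildReactionSystem(smallTitration(), "reduced")
  t1 <- simulateSSA(sys, c(A = 20), seq(0, 100, 1), seed = 99)
  t2 <- simulateSSA(sys, c(A = 20), seq(0, 100, 1), seed = 99)
  expect_identical(t1@counts, t2@counts)
  t3 <- simulateSSA(sys, c(A = 20), seq(0, 100, 1), seed = 100)
  expect_false(identical(t1@counts, t3@counts))
})

test_that("birth-death sampling matches the Poisson stationary law", {
  fx <- fixtureGenerator("birth_death")  # rate 10, decay 1, mean 10
  tr <- simulateSSA(fx$system, c(M = 10), seq(0, 10100, by = 1),
                    seed = 21)
  x <- speciesCounts(tr, "M")[tr@time > 100]  # ~1e4 weakly-coupled samples
  expect_lt(abs(mean(x) - 10), 0.2)
  # chi-square goodness of fit against Poisson(10), pooled tails
  ks <- 0:25
  pk <- dpois(ks, 10); pk[length(pk)] <- 1 - ppois(24, 10)
  obs <- vapply(ks, function(k) sum(x == k), numeric(1))
  obs[length(obs)] <- sum(x >= 25)
  keep <- pk * length(x) >= 5
  chi <- sum((obs[keep] - length(x) * pk[keep])^2 /
               (length(x) * pk[keep]))
  # samples 1 min apart are close to independent (relaxation time 1 min);
  # demand only gross consistency
  expect_lt(chi, 3 * sum(keep))
})

test_that("ensemble statistics reduce correctly and match linear ODE
           means", {
  sys <- buildReactionSystem(
    setParameters(smallTitration(), kM = 0, kS = 0), "reduced")
  one <- simulateEnsemble(sys, c(A = 5), seq(0, 30, 1), 1, baseSeed = 2)
  single <- simulateSSA(sys, c(A = 5), seq(0, 30, 1),
                        seed = childSeed(2, 1))
  expect_equal(ensembleMean(one), single@counts * 1,
               ignore_attr = TRUE)

  ens <- simulateEnsemble(sys, c(A = 5), seq(0, 30, 1), 60, baseSeed = 3)
  ode <- integrateDeterministic(
    setParameters(smallTitration(), kM = 0, kS = 0),
    c(A = 5), seq(0, 30, 1))
  mM <- ensembleMean(ens, "M"); vM <- ensembleVar(ens, "M")
  for (i in c(10, 20, 31)) {
    se <- sqrt(vM[i] / 60)
    expect_lt(abs(mM[i] - speciesCounts(ode, "M")[i]), 3 * se + 1e-9)
  }
})

test_that("detailed-scheme bookkeeping conserves molecules between
           production and degradation events", {
  p <- regulationParameters(alphaM = 2, alphaA = 0, alphaS = 0, N = 3,
                            deltaM = 0.1, deltaA = 0, deltaS = 0,
                            kM = 0.05, kS = 0.05)
  sysD <- buildReactionSystem(p, "detailed",
                              detailedRates = list(deltaCma = 0))
  init <- c(A = 15, C0 = 6)
  tr <- simulateSSA(sysD, init, seq(0, 50, 1), seed = 31)
  cn <- tr@counts[, paste0("C", 0:3)]
  # total sRNA molecules change only via production/degradation (both off)
  expect_true(all(rowSums(cn) == 6))
  # CsrA conservation: free + mRNA-bound + sum n C_n constant while
  # production, degradation and complex decay are off
  boundS <- cn %*% (0:3)
  total <- tr@counts[, "A"] + tr@counts[, "Cma"] + boundS
  expect_true(all(total == 15))
})

test_that("the detailed model converges to the reduced model under fast
           complex dynamics", {
  p <- smallTitration()
  rep <- reducedVsDetailed(p, speedupFactors = c(1, 25), tMax = 1500,
                           seed = 9)
  # discrepancy in free mRNA shrinks as complex dynamics accelerate
  expect_lt(rep$dM[2], rep$dM[1])
  # free CsrA within 10% (plus Monte-Carlo slack) at high speed-up
  expect_lt(rep$dA[2], 0.1 * max(rep$A_reduced[2], 1) + 0.5)

  # N = 1 with no unbinding is the reduced model by construction
  p1 <- regulationParameters(alphaM = 4, alphaA = 5, alphaS = 3, N = 1,
                             deltaM = 0.3, deltaA = 0.05, deltaS = 0.3,
                             kM = 0.1, kS = 0.2)
  det <- buildReactionSystem(p1, "detailed",
                             detailedRates = list(vPlus = 0.2, vMinus = 0,
                                                  kPlus = 0.1, kMinus = 0,
                                                  deltaCma = 50))
  grid <- seq(0, 1500, 1)
  trD <- simulateSSA(det, c(A = 10), grid, seed = 17)
  trR <- simulateSSA(buildReactionSystem(p1, "reduced"), c(A = 10), grid,
                     seed = 18)
  burn <- grid > 300
  for (sp in c("M", "A")) {
    mD <- mean(trD@counts[burn, sp]); mR <- mean(trR@counts[burn, sp])
    sdPool <- sd(trD@counts[burn, sp]) + sd(trR@counts[burn, sp])
    expect_lt(abs(mD - mR), 0.15 * max(mR, 1) + 0.1 * sdPool)
  }
})
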