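test_that("the full network has the documented structure", {
  reg <- regulationParameters(); sos <- sosParameters()
  sys <- fullNetworkSystem(sos, reg)
  expect_setequal(sys@species,
                  c("Ml", "Mr", "Le", "R", "Pl", "Bl", "Pr", "Br", "Ps",
                    "Bs", "Ms", "M", "A", "S", "L"))
  # the only schedule-driven reaction is RecA-mediated LexA cleavage
  td <- which(sys@timeDependent)
  expect_length(td, 1)
  expect_match(sys@reactionNames[td], "cleavage")
  expect_equal(unname(sys@orders[c("R", "Le"), td]), c(1, 1))
  # long/short mRNA transcription proportional to open SOS promoters
  jl <- grep("transcription long", sys@reactionNames)
  expect_equal(unname(sys@orders["Ps", jl]), 1)
  # promoter copies are bounded by the plasmid number
  init <- sosInitialState(sos, reg)
  expect_lte(init[["Bs"]], reg@nSos)
  expect_equal(init[["Bs"]] + init[["Ps"]], reg@nSos)
  expect_error(sosInitialState(sos, reg, nSos = 1e5), "implausible")
})

test_that("uninduced cells are repressed; induction derepresses the
           operon after a CsrA titration delay", {
  reg <- regulationParameters(); sos <- sosParameters()
  init <- sosInitialState(sos, reg)
  # high LexA, mostly bound promoters, little short mRNA, abundant CsrA
  expect_gt(init[["Le"]], 100)
  expect_gt(init[["Bs"]], 0.8 * reg@nSos)
  expect_lt(init[["Ms"]], 30)
  expect_gt(init[["A"]], 100)
  expect_lt(init[["M"]], 1)

  sched <- signalSchedule(c(0, 50), c(0, 6))
  tr <- integrateDeterministic(fullNetworkSystem(sos, reg), init,
                               seq(0, 250, 1), schedule = sched)
  Ms <- speciesCounts(tr, "Ms"); M <- speciesCounts(tr, "M")
  tt <- tr@time
  # short mRNA responds promptly, long mRNA only after CsrA is titrated
  expect_gt(Ms[tt == 70], 10 * Ms[tt == 45])
  tShort <- tt[which(Ms > 5 * Ms[tt == 45] & tt > 50)[1]]
  tLong <- tt[which(M > 1 & tt > 50)[1]]
  expect_gt(tLong - tShort, 15)
  expect_gt(max(M), 8)

  # infinite-repression limit: binding overwhelming keeps transcription off
  sosRep <- sosParameters(kOn = 50, kOff = 1e-3)
  initR <- sosInitialState(sosRep, reg)
  trR <- integrateDeterministic(fullNetworkSystem(sosRep, reg), initR,
                                seq(0, 200, 1),
                                schedule = signalSchedule(0, 0))
  expect_lt(max(speciesCounts(trR, "M")), 0.1)
})

test_that("first-peak detection follows the onset and excursion rules", {
  # flat zero trace is censored
  expect_true(detectFirstPeak(rep(0, 50))$censored)
  # constructed series: onset when M first exceeds 8, peak at the
  # excursion maximum
  tt <- seq(300, 400, by = 10)
  m <- c(0, 9, 15, 25, 20, 12, 5, 30, 40, 10, 0)
  fp <- detectFirstPeak(m, time = tt)
  expect_false(fp$censored)
  expect_equal(fp$onset, 310)
  expect_equal(fp$peak, 330)  # the later, higher excursion is not first
  expect_equal(fp$peakHeight, 25)
  # ties resolve to the earliest time within the excursion
  fp2 <- detectFirstPeak(c(0, 12, 12, 9, 0), time = 0:4)
  expect_equal(fp2$peak, 1)
  # the value 8 itself does not open an excursion
  expect_true(detectFirstPeak(c(0, 8, 8, 0), time = 0:3)$censored)
})

test_that("survival function identities hold exactly", {
  mkStats <- function(peak, censored, onset = peak - 5) {
    new("LysisStatistics", onset = onset, peak = peak,
        censored = censored, signalOnset = 0, onsetThreshold = 8,
        binWidth = 10, metadata = list())
  }
  # no peaks at all: survival stays at one
  s0 <- survivalFunction(mkStats(rep(NA_real_, 4), rep(TRUE, 4)),
                         times = 0:10)
  expect_true(all(s0$survival == 1))

  peaks <- c(12, 30, 30, 55, NA)
  st <- mkStats(peaks, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  sv <- survivalFunction(st, times = 0:60)
  expect_equal(sv$survival[1], 1)
  expect_true(all(diff(sv$survival) <= 0))
  # complement of the empirical peak-time CDF (censored never counted)
  cdf <- ecdf(peaks[1:4])
  expect_equal(sv$survival, 1 - cdf(sv$time) * 4 / 5)
})

test_that("lysis statistics summarize synthetic ensembles correctly", {
  tt <- 0:120
  n <- 6
  arr <- array(0, dim = c(length(tt), 1, n),
               dimnames = list(NULL, "M", NULL))
  peaksAt <- c(40, 50, 50, 80, NA, NA)
  for (r in 1:4) {
    arr[tt >= peaksAt[r] - 5 & tt <= peaksAt[r] + 5, 1, r] <- 9
    arr[tt == peaksAt[r], 1, r] <- 20
  }
  ens <- new("TrajectoryEnsemble", time = as.numeric(tt), counts = arr,
             seeds = seq_len(n), metadata = list(signalOnset = 20))
  st <- lysisTimeDistribution(ens)
  expect_equal(sum(st@censored), 2)
  expect_equal(sort(st@peak[!st@censored]), c(40, 50, 50, 80))
  h <- peakTimeHistogram(st)
  expect_equal(h$mode, 35)  # 50 min absolute, 30-40 bin rel. to onset
  expect_equal(h$nCensored, 2)
  expect_equal(sum(h$histogram$count), 4)
  # all-censored ensembles are flagged
  arr0 <- arr; arr0[] <- 0
  ens0 <- new("TrajectoryEnsemble", time = as.numeric(tt), counts = arr0,
              seeds = seq_len(n), metadata = list())
  expect_warning(st0 <- lysisTimeDistribution(ens0), "censored")
  expect_true(st0@metadata$allCensored)
})

test_that("cells without plasmids never lyse", {
  pv <- poissonPlasmidVariant(meanCopies = 0, nRealizations = 4,
                              baseSeed = 5, tMax = 10)
  expect_true(all(pv@censored))
  expect_equal(nRealizations(pv), 4)
})
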