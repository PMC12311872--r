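test_that("the same seed reproduces a participant bit-for-bit", {
  a <- simulateParticipant(metsGroupSpec(), seed = 99, group = "case")
  b <- simulateParticipant(metsGroupSpec(), seed = 99, group = "case")
  expect_identical(seriesValues(heartRate(a)), seriesValues(heartRate(b)))
  expect_identical(seriesValues(stepCounts(a)), seriesValues(stepCounts(b)))
  expect_identical(sleepEpisodes(a), sleepEpisodes(b))
  c <- simulateParticipant(metsGroupSpec(), seed = 100, group = "case")
  expect_false(identical(seriesValues(heartRate(a)), seriesValues(heartRate(c))))
})

test_that("a noiseless, gap-free participant round-trips through the cosinor fit", {
  spec <- groupSpec(n = 2, hrMesorMean = 72, hrMesorSd = 0,
                    hrCircAmplitude = 11, hrAcrophase = 14.5,
                    ultradian70Amplitude = 0, lowfreq1000Amplitude = 0,
                    noiseSd = 0, ar1 = 0, hrHourlySd = 0, nightHrElevation = 0,
                    stepsDayRate = 10, stepsHourCv = 0,
                    mstMean = 210, mstSd = 0, tstMean = 420, tstSd = 0,
                    missingRate = 0, missingBurstMinutes = 30)
  r <- simulateParticipant(spec, seed = 3, group = "control")
  expect_false(any(missingMask(heartRate(r))))
  f <- fitCosinor(heartRate(r))
  expect_equal(f@mesor, 72, tolerance = 1e-9)
  expect_equal(f@amplitude, 11, tolerance = 1e-9)
  expect_equal(f@acrophase, 14.5, tolerance = 1e-9)
})

test_that("zero-coded gap fraction matches the target missing rate", {
  fracs <- vapply(1:30, function(i) {
    r <- simulateParticipant(nonMetsGroupSpec(), seed = 1000 + i, group = "control")
    mean(missingMask(heartRate(r)))
  }, numeric(1))
  # bursts overlap slightly, so coverage is just under the nominal rate
  expect_lt(abs(mean(fracs) - 0.05), 0.006)
  expect_gt(min(fracs), 0)
})

test_that("simulated records honour the generative contracts", {
  r <- simulateParticipant(nonMetsGroupSpec(), seed = 5, group = "control")
  hr <- heartRate(r); st <- stepCounts(r)
  expect_equal(nDays(hr), 5)
  expect_equal(as.POSIXlt(seriesStart(hr))$wday, 1)   # Monday start
  expect_true(all(seriesValues(st) >= 0))
  expect_true(all(seriesValues(hr)[!missingMask(hr)] > 0))
  expect_true(all(seriesValues(hr)[missingMask(hr)] == 0))
  # steps are zero during sleep
  sl <- sleepEpisodes(r)
  aon <- ceiling(as.numeric(sl$onset[2] - seriesStart(st), units = "mins"))
  aoff <- floor(as.numeric(sl$offset[2] - seriesStart(st), units = "mins"))
  expect_true(all(seriesValues(st)[(aon + 1):(aoff + 1)] == 0))
  expect_error(groupSpec(n = 2, hrMesorMean = 20, hrMesorSd = 0,
                         hrCircAmplitude = 25, hrAcrophase = 15,
                         ultradian70Amplitude = 0, lowfreq1000Amplitude = 0,
                         noiseSd = 0, ar1 = 0, nightHrElevation = 0,
                         stepsDayRate = 5, mstMean = 210, mstSd = 10,
                         tstMean = 420, tstSd = 10), "negative HR floor")
})

test_that("cohort files round-trip through the reader and are seed-stable", {
  cfg <- simConfig(case = metsGroupSpec(2L), control = nonMetsGroupSpec(2L),
                   seed = 17)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  simulateCohort(cfg, dir = d1)
  simulateCohort(cfg, dir = d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))  # byte-identical
  expect_error(simulateCohort(cfg, dir = d1), "collision")

  records <- readCohort(file.path(d1, "manifest.csv"))
  expect_length(records, 4)
  mem <- simulateCohort(cfg)$records
  # file round trip preserves the signals up to CSV numeric formatting
  expect_equal(seriesValues(heartRate(records[[1]])),
               seriesValues(heartRate(mem[[1]])), tolerance = 1e-6)
  expect_identical(groupLabel(records[[1]]), "control")
  mc <- buildMarkerCohort(records, markers = c("MESOR_HR", "RA_HR", "TST_Mean"),
                          verbose = FALSE)
  expect_equal(dim(mc), c(3L, 4L))
  expect_false(anyNA(markerMatrix(mc)))
})

test_that("group means converge to the specified generative values", {
  n <- 120
  recs <- lapply(1:n, function(i)
    simulateParticipant(nonMetsGroupSpec(), seed = 5000 + i, group = "control"))
  mc <- buildMarkerCohort(recs, markers = c("MESOR_HR", "MST_Mean", "TST_Mean", "L5_HR"),
                          checkEligibility = FALSE, verbose = FALSE)
  M <- markerMatrix(mc)
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(M["MESOR_HR", ]) - 71.89), 3 * se(M["MESOR_HR", ]) + 0.3)
  expect_lt(abs(mean(M["MST_Mean", ]) - 207.55), 3 * se(M["MST_Mean", ]) + 2)
  expect_lt(abs(mean(M["TST_Mean", ]) - 414.92), 3 * se(M["TST_Mean", ]) + 5)
  # L5 of heart rate sits below the MESOR by roughly the circadian amplitude
  expect_lt(mean(M["L5_HR", ]), 71.89 - 5)
})

test_that("injected group effects surface in the marker directions", {
  mc <- simMarkerCohort(25, 25, seed = 29,
                        markers = c("CCE_MF_HR", "CCE_LF_HR", "RA_HR",
                                    "L5_HR", "IS_SC"))
  M <- markerMatrix(mc)
  ca <- groupLabels(mc) == "case"
  gm <- function(mk) c(case = mean(M[mk, ca]), control = mean(M[mk, !ca]))
  expect_lt(gm("CCE_MF_HR")["case"], gm("CCE_MF_HR")["control"])
  expect_gt(gm("CCE_LF_HR")["case"], gm("CCE_LF_HR")["control"])
  expect_lt(gm("RA_HR")["case"], gm("RA_HR")["control"])
  expect_gt(gm("L5_HR")["case"], gm("L5_HR")["control"])
  expect_lt(gm("IS_SC")["case"], gm("IS_SC")["control"])
})
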