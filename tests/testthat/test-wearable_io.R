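test_that("a clean whole-day file reads with an all-false mask", {
  p <- writeMinuteCsv(minuteRows(7200))
  ms <- readMinuteSeries(p)
  expect_equal(length(seriesValues(ms$hr)), 7200)
  expect_equal(nDays(ms$hr), 5)
  expect_false(any(missingMask(ms$hr)))
  expect_equal(seriesStart(ms$hr), MON)
  expect_equal(signalKind(ms$steps), "steps")
})

test_that("zero-coded heart rate is flagged exactly where it occurs", {
  rows <- minuteRows(2880)
  rows$heart_rate[101:161] <- 0
  ms <- readMinuteSeries(writeMinuteCsv(rows))
  expect_equal(which(missingMask(ms$hr)), 101:161)
  expect_false(any(missingMask(ms$steps)))
})

test_that("a dropped minute is regridded and flagged, matching a hand-built grid", {
  rows <- minuteRows(1440)
  rows$heart_rate <- 60 + seq_len(1440) %% 7   # non-constant, recognisable
  dropped <- rows[-500, ]
  ms <- readMinuteSeries(writeMinuteCsv(dropped))
  expect_equal(length(seriesValues(ms$hr)), 1440)
  expect_true(missingMask(ms$hr)[500])
  expect_equal(sum(missingMask(ms$hr)), 1)
  # hand-built oracle grid: original values everywhere else, 0 at the gap
  oracle <- rows$heart_rate
  oracle[500] <- 0
  expect_equal(seriesValues(ms$hr), oracle)
})

test_that("partial leading/trailing days are trimmed to whole days", {
  rows <- minuteRows(3000, start = MON - 60 * 100)  # 100 min before midnight
  ms <- readMinuteSeries(writeMinuteCsv(rows))
  expect_equal(seriesStart(ms$hr), MON)
  expect_equal(length(seriesValues(ms$hr)), 2880)
})

test_that("malformed timestamps and duplicate minutes are rejected with context", {
  rows <- minuteRows(1440)
  rows$timestamp[7] <- "not-a-time"
  expect_error(readMinuteSeries(writeMinuteCsv(rows)), "malformed timestamp at line 8")
  rows <- minuteRows(1440)
  rows$timestamp[10] <- rows$timestamp[9]
  expect_error(readMinuteSeries(writeMinuteCsv(rows)), "duplicate minute")
})

test_that("linear interpolation repairs masked runs between anchors", {
  s <- MinuteSeries(c(70, 0, 0, 76, 74), MON,
                    missing = c(FALSE, TRUE, TRUE, FALSE, FALSE))
  r <- interpolateMissingHr(s)
  expect_equal(seriesValues(r), c(70, 72, 74, 76, 74))
  expect_equal(missingMask(r), missingMask(s))  # mask preserved for audit

  lead <- MinuteSeries(c(0, 0, 80, 82), MON,
                       missing = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(seriesValues(interpolateMissingHr(lead)), c(80, 80, 80, 82))
})

test_that("interpolation recovers a ramp exactly, is idempotent and anchor-bounded", {
  set.seed(42)
  for (i in 1:10) {
    n <- 600
    ramp <- 60 + 0.05 * (0:(n - 1))
    miss <- runif(n) < 0.3
    miss[c(1, n)] <- FALSE   # keep outer anchors so the line is recoverable
    vals <- ifelse(miss, 0, ramp)
    s <- MinuteSeries(vals, MON, missing = miss)
    r <- interpolateMissingHr(s)
    expect_equal(seriesValues(r), ramp, tolerance = 1e-12)
    # idempotence
    expect_identical(seriesValues(interpolateMissingHr(r)), seriesValues(r))
  }
  # repaired samples lie within the range of their two anchors
  set.seed(7)
  vals <- runif(500, 50, 110)
  miss <- runif(500) < 0.4
  s <- MinuteSeries(ifelse(miss, 0, vals), MON, missing = miss)
  y <- seriesValues(interpolateMissingHr(s))
  ok <- which(!miss)
  for (j in which(miss)) {
    lo <- max(c(ok[ok < j], ok[1]))
    hi <- min(c(ok[ok > j], ok[length(ok)]))
    expect_gte(y[j], min(vals[lo], vals[hi]) - 1e-12)
    expect_lte(y[j], max(vals[lo], vals[hi]) + 1e-12)
  }
  expect_error(interpolateMissingHr(
    MinuteSeries(c(0, 0), MON, missing = c(TRUE, TRUE))), "no valid heart-rate")
})

test_that("wear eligibility enforces the 6-h nonwear and 5-weekday rules", {
  rec <- mkRecord(function(t) 70 + 5 * cos(2 * pi * t / 1440))
  expect_true(checkWearEligibility(rec)$eligible)

  # one day with 361 missing minutes -> nonwear > 6 h
  miss <- logical(7200); miss[1441:1801] <- TRUE
  bad <- ParticipantRecord("x", hr = mkSeries(function(t) rep(70, length(t)),
                                              missing = miss),
                           steps = mkSeries(0, kind = "steps"),
                           sleep = regularSleep(), group = "control")
  v <- checkWearEligibility(bad)
  expect_false(v$eligible)
  expect_equal(v$reason, "nonwear > 6 h")
  # exactly 360 is still allowed
  miss360 <- logical(7200); miss360[1441:1800] <- TRUE
  ok <- ParticipantRecord("y", hr = mkSeries(function(t) rep(70, length(t)),
                                             missing = miss360),
                          steps = mkSeries(0, kind = "steps"),
                          sleep = regularSleep(), group = "control")
  expect_true(checkWearEligibility(ok)$eligible)

  # Thu..Mon span: weekend breaks the weekday run
  thu <- as.POSIXct("2023-01-05 00:00:00", tz = "UTC")
  rec2 <- ParticipantRecord("z",
    hr = mkSeries(function(t) 70 + 5 * cos(2 * pi * t / 1440), start = thu),
    steps = mkSeries(0, kind = "steps", start = thu),
    sleep = regularSleep(start = thu), group = "control")
  v2 <- checkWearEligibility(rec2)
  expect_false(v2$eligible)
  expect_match(v2$reason, "consecutive weekdays")
})

test_that("eligibility verdict equals a brute-force per-day scan", {
  set.seed(11)
  for (i in 1:20) {
    miss <- runif(7200) < runif(1, 0, 0.35)
    rec <- ParticipantRecord("bf",
      hr = mkSeries(function(t) rep(70, length(t)), missing = miss),
      steps = mkSeries(0, kind = "steps"),
      sleep = regularSleep(), group = "control")
    v <- checkWearEligibility(rec)
    perDay <- vapply(1:5, function(d) sum(miss[((d - 1) * 1440 + 1):(d * 1440)]), 0L)
    # record starts Monday: 5 weekdays present, so brute-force verdict is the
    # 6-h rule alone
    expect_equal(v$eligible, all(perDay <= 360))
  }
})
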