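# Synthetic wearable cohort generator.
#
# Heart rate is built mechanistically from the components the markers measure:
#   HR(t) = mesor_i
#         + A_circ cos(2 pi (t - 60 acrophase) / 1440)
#         + A_70   cos(2 pi t /   70 + U)
#         + A_1000 cos(2 pi t / 1000 + U')
#         + nightHrElevation * sleep(t)
#         + hourly behavioural level shifts + AR(1) noise,
# with the participant's mesor drawn from the group distribution and the
# ultradian phases U, U' randomized per participant (only energies are
# group-structured, matching what the wavelet band markers measure). Steps are
# zero during sleep and Poisson with hourly activity-level modulation while
# awake. Nightly sleep episodes are drawn from (MST, TST) Gaussians. Device
# missingness is injected as zero-coded heart-rate bursts. Group effects are
# injected through these mechanisms, never by perturbing markers directly.

#' Group-level simulation parameters
#'
#' @param n participants in the group.
#' @param hrMesorMean,hrMesorSd between-participant mean/SD of the heart-rate
#'   MESOR (bpm).
#' @param hrCircAmplitude circadian (24 h) HR amplitude (bpm).
#' @param hrAcrophase clock time of the circadian HR peak (decimal hours).
#' @param ultradian70Amplitude amplitude of the 70-min ultradian HR component
#'   (bpm); the mid-frequency CCE band measures its energy.
#' @param lowfreq1000Amplitude amplitude of the 1000-min HR component (bpm);
#'   the low-frequency CCE band measures its energy.
#' @param noiseSd stationary SD of the AR(1) HR noise (bpm).
#' @param ar1 lag-1 autocorrelation of the HR noise, in \[0, 1).
#' @param hrHourlySd SD of behavioural HR shifts while awake (bpm), applied as
#'   piecewise-constant episodes of exponential duration (mean 60 min); models
#'   activity, meals and posture changes, and sets the day-to-day irregularity
#'   that IS/IV of heart rate measure.
#' @param nightHrElevation additive HR offset while asleep (bpm; negative
#'   values model the nocturnal dip, less negative means a blunted dip).
#' @param stepsDayRate mean awake step rate (steps/min).
#' @param stepsRateSd between-participant SD of the awake step rate
#'   (steps/min); rates are gamma-distributed with this mean and SD, matching
#'   the large activity heterogeneity of real cohorts.
#' @param stepsHourCv coefficient of variation of the hourly activity-level
#'   multipliers (behavioural irregularity; larger values lower IS).
#' @param mstMean,mstSd night-to-night mean/SD of midsleep time (minutes after
#'   midnight).
#' @param tstMean,tstSd night-to-night mean/SD of total sleep time (minutes).
#' @param missingRate target fraction of zero-coded HR minutes (< 0.25 so the
#'   6-h nonwear rule keeps headroom).
#' @param missingBurstMinutes mean length of a missing burst.
#' @return list of class "groupSpec".
#' @export
groupSpec <- function(n, hrMesorMean, hrMesorSd, hrCircAmplitude, hrAcrophase,
                      ultradian70Amplitude, lowfreq1000Amplitude,
                      noiseSd, ar1, hrHourlySd = 0, nightHrElevation,
                      stepsDayRate, stepsRateSd = 0, stepsHourCv = 1,
                      mstMean, mstSd, tstMean, tstSd,
                      missingRate = 0.05, missingBurstMinutes = 30) {
  spec <- as.list(environment())
  with(spec, {
    stopifnot(n >= 1, hrMesorSd >= 0, hrCircAmplitude >= 0,
              ultradian70Amplitude >= 0, lowfreq1000Amplitude >= 0,
              noiseSd >= 0, ar1 >= 0, ar1 < 1, hrHourlySd >= 0,
              stepsDayRate >= 0, stepsRateSd >= 0,
              stepsHourCv >= 0, mstSd >= 0, tstSd >= 0, tstMean > 0,
              missingRate >= 0, missingRate < 0.25, missingBurstMinutes >= 1)
    floorHr <- hrMesorMean - 3 * hrMesorSd - hrCircAmplitude -
      ultradian70Amplitude - lowfreq1000Amplitude - abs(nightHrElevation)
    if (floorHr <= 0)
      stop("spec implies negative HR floor (deterministic components exceed the mesor)")
  })
  structure(spec, class = "groupSpec")
}

#' Default non-MetS (control) group parameters
#'
#' Defaults calibrated to the control column of the reference marker tables:
#' MESOR 71.89 (6.39) bpm, circadian amplitude 11.66 bpm, acrophase 14.97 h,
#' MST 207.55 min (night-to-night SD 39.76), TST 414.92 min (SD 79.50), awake
#' step rate 12.8 steps/min, a -1.5 bpm nocturnal HR dip beyond the cosine,
#' ultradian 70-min / 1000-min HR amplitudes of 2.4 bpm each, behavioural HR
#' shifts of 5 bpm SD, awake step rate 12.8 (SD 6.4) steps/min, and hourly
#' step-activity CV 0.6 (set so the interdaily stability of step count lands
#' near 0.5).
#'
#' @param n group size (default 184).
#' @return a [groupSpec()].
#' @export
nonMetsGroupSpec <- function(n = 184L) {
  groupSpec(n = n, hrMesorMean = 71.89, hrMesorSd = 6.39,
            hrCircAmplitude = 11.66, hrAcrophase = 14.97,
            ultradian70Amplitude = 2.4, lowfreq1000Amplitude = 2.4,
            noiseSd = 3, ar1 = 0.8, hrHourlySd = 5, nightHrElevation = -1.5,
            stepsDayRate = 12.8, stepsRateSd = 6.4, stepsHourCv = 0.6,
            mstMean = 207.55, mstSd = 39.76, tstMean = 414.92, tstSd = 79.50,
            missingRate = 0.05, missingBurstMinutes = 30)
}

#' Default MetS (case) group parameters
#'
#' Case-control contrasts are injected mechanistically: higher MESOR (75.05 vs
#' 71.89 bpm), a blunted nocturnal dip (-0.3 vs -1.5 bpm, raising L5 and
#' lowering RA of heart rate), an attenuated 70-min component (2.0 vs 2.4 bpm,
#' lowering mid-frequency CCE), a stronger 1000-min component (3.5 vs 2.4 bpm,
#' raising the normalized low-frequency CCE by about the reference panel's
#' relative contrast), slightly lower and more irregular daytime
#' activity (11.02 steps/min, SD 4.4, hourly CV 0.75, lowering IS of step
#' count), and
#' near-identical sleep timing (MST 207.08, TST 410.70), so sleep markers
#' carry no group signal.
#'
#' @param n group size (default 88).
#' @return a [groupSpec()].
#' @export
metsGroupSpec <- function(n = 88L) {
  groupSpec(n = n, hrMesorMean = 75.05, hrMesorSd = 7.23,
            hrCircAmplitude = 11.22, hrAcrophase = 15.00,
            ultradian70Amplitude = 2.0, lowfreq1000Amplitude = 3.5,
            noiseSd = 3, ar1 = 0.8, hrHourlySd = 5, nightHrElevation = -0.3,
            stepsDayRate = 11.02, stepsRateSd = 4.4, stepsHourCv = 0.75,
            mstMean = 207.08, mstSd = 45.00, tstMean = 410.70, tstSd = 84.00,
            missingRate = 0.05, missingBurstMinutes = 30)
}

#' Cohort simulation configuration
#'
#' @param case,control [groupSpec()] objects (defaults: [metsGroupSpec()] and
#'   [nonMetsGroupSpec()]).
#' @param days whole days of recording (>= 5; the record starts on a Monday so
#'   the consecutive-weekday filter is exercised deterministically).
#' @param seed integer master seed; all randomness derives from it.
#' @param startDate first day of recording (a Monday).
#' @return list of class "simConfig".
#' @export
simConfig <- function(case = metsGroupSpec(), control = nonMetsGroupSpec(),
                      days = 5L, seed = 1L,
                      startDate = as.POSIXct("2023-01-02 00:00:00", tz = "UTC")) {
  stopifnot(days >= 5, case$n >= 2, control$n >= 2)
  if (as.POSIXlt(startDate)$wday != 1L) stop("startDate must be a Monday")
  structure(list(case = case, control = control, days = as.integer(days),
                 seed = as.integer(seed), startDate = startDate),
            class = "simConfig")
}

# nightly sleep episodes covering nights -1 .. days-2 (so the record's first
# morning and last night are both covered); returns POSIXct onset/offset
.simSleep <- function(spec, days, startDate) {
  nights <- (-1):(days - 2L)
  mst <- rnorm(length(nights), spec$mstMean, spec$mstSd)
  tst <- pmin(pmax(rnorm(length(nights), spec$tstMean, spec$tstSd), 120), 840)
  onsetMin <- (nights + 1) * 1440 + mst - tst / 2
  data.frame(onset = startDate + 60 * onsetMin,
             offset = startDate + 60 * (onsetMin + tst))
}

#' Simulate one participant record
#'
#' @param spec a [groupSpec()].
#' @param seed integer seed (all randomness for this participant flows from
#'   it; the same seed reproduces the record bit-for-bit).
#' @param group label for the record ("case" or "control").
#' @param days whole days (default 5).
#' @param startDate first midnight (a Monday by default).
#' @param participantId identifier.
#' @return a [ParticipantRecord-class].
#' @export
simulateParticipant <- function(spec, seed, group = "control", days = 5L,
                                startDate = as.POSIXct("2023-01-02 00:00:00", tz = "UTC"),
                                participantId = sprintf("sim_%d", seed)) {
  set.seed(seed)
  n <- days * 1440L
  t <- seq_len(n) - 1

  sleep <- .simSleep(spec, days, startDate)
  sleepInd <- logical(n)
  for (i in seq_len(nrow(sleep))) {
    a <- max(0, ceiling(as.numeric(sleep$onset[i] - startDate, units = "mins")))
    b <- min(n - 1, floor(as.numeric(sleep$offset[i] - startDate, units = "mins")))
    if (b >= a) sleepInd[(a + 1):(b + 1)] <- TRUE
  }

  mesor <- rnorm(1, spec$hrMesorMean, spec$hrMesorSd)
  u1 <- runif(1, 0, 2 * pi); u2 <- runif(1, 0, 2 * pi)
  hr <- mesor +
    spec$hrCircAmplitude * cos(2 * pi * (t - 60 * spec$hrAcrophase) / 1440) +
    spec$ultradian70Amplitude * cos(2 * pi * t / 70 + u1) +
    spec$lowfreq1000Amplitude * cos(2 * pi * t / 1000 + u2) +
    spec$nightHrElevation * sleepInd
  # behavioural HR shifts (activity, meals, posture): piecewise-constant
  # episodes with exponential durations (mean 60 min), awake only
  if (spec$hrHourlySd > 0) {
    lens <- pmax(1L, ceiling(rexp(ceiling(n / 15), rate = 1 / 60)))
    lens <- lens[cumsum(lens) - lens < n]
    if (sum(lens) < n) lens[length(lens)] <- lens[length(lens)] + n - sum(lens)
    shifts <- rep(rnorm(length(lens), 0, spec$hrHourlySd), times = lens)[1:n]
    hr <- hr + shifts * !sleepInd
  }
  if (spec$noiseSd > 0) {
    innov <- rnorm(n, 0, spec$noiseSd * sqrt(1 - spec$ar1^2))
    hr <- hr + as.numeric(stats::filter(innov, spec$ar1, method = "recursive"))
  }
  hr <- pmax(hr, 25)   # physiological floor; noise excursions only

  # zero-coded missing bursts
  miss <- logical(n)
  if (spec$missingRate > 0) {
    nBursts <- rpois(1, n * spec$missingRate / spec$missingBurstMinutes)
    if (nBursts > 0) {
      starts <- sample.int(n, nBursts, replace = TRUE)
      lens <- rgeom(nBursts, 1 / spec$missingBurstMinutes) + 1L
      for (i in seq_len(nBursts))
        miss[starts[i]:min(n, starts[i] + lens[i] - 1L)] <- TRUE
    }
  }
  hrObserved <- ifelse(miss, 0, hr)

  # steps: Poisson while awake, hourly activity-level modulation around a
  # participant-level mean rate
  baseRate <- if (spec$stepsRateSd > 0)
    rgamma(1, shape = (spec$stepsDayRate / spec$stepsRateSd)^2,
           scale = spec$stepsRateSd^2 / spec$stepsDayRate)
  else spec$stepsDayRate
  nHours <- n %/% 60L
  cv <- spec$stepsHourCv
  mult <- if (cv > 0) rgamma(nHours, shape = 1 / cv^2, scale = cv^2) else rep(1, nHours)
  rate <- baseRate * rep(mult, each = 60L) * !sleepInd
  steps <- rpois(n, rate)

  ParticipantRecord(
    participantId,
    hr = MinuteSeries(hrObserved, startDate, kind = "heart_rate", missing = miss),
    steps = MinuteSeries(steps, startDate, kind = "steps"),
    sleep = sleep, group = group,
    covariates = .simCovariates(group)
  )
}

# covariates loosely matching the cohort demographics (control: age 44.0 (6.5),
# BMI 21.7 (2.1), 85% female; case: age 48.9 (6.9), BMI 27.9 (2.9), 50% female)
.simCovariates <- function(group) {
  if (group == "case")
    list(age = round(rnorm(1, 48.94, 6.92), 1),
         sex = if (runif(1) < 0.5) "F" else "M",
         bmi = round(rnorm(1, 27.90, 2.94), 1))
  else
    list(age = round(rnorm(1, 44.04, 6.48), 1),
         sex = if (runif(1) < 156 / 184) "F" else "M",
         bmi = round(rnorm(1, 21.70, 2.08), 1))
}

#' Simulate a cohort
#'
#' Generates \code{control$n + case$n} participant records. With \code{dir}
#' unset the records stay in memory; otherwise the minute, sleep and manifest
#' CSV files read by [readCohort()] are written to \code{dir} (which must not
#' already contain files).
#'
#' @param cfg a [simConfig()].
#' @param dir optional output directory for the CSV file set.
#' @return invisibly for file output, else a list with \code{records} (list of
#'   [ParticipantRecord-class]) and \code{manifest} (data.frame).
#' @export
simulateCohort <- function(cfg = simConfig(), dir = NULL) {
  ids <- c(sprintf("ctrl_%04d", seq_len(cfg$control$n)),
           sprintf("case_%04d", seq_len(cfg$case$n)))
  groups <- rep(c("control", "case"), c(cfg$control$n, cfg$case$n))
  records <- lapply(seq_along(ids), function(i) {
    spec <- if (groups[i] == "case") cfg$case else cfg$control
    simulateParticipant(spec, seed = .deriveSeed(cfg$seed, ids[i]),
                        group = groups[i], days = cfg$days,
                        startDate = cfg$startDate, participantId = ids[i])
  })
  manifest <- data.frame(
    participant_id = ids,
    minute_file = paste0(ids, "_minutes.csv"),
    sleep_file = paste0(ids, "_sleep.csv"),
    group = groups,
    age = vapply(records, function(r) r@covariates$age, numeric(1)),
    sex = vapply(records, function(r) r@covariates$sex, character(1)),
    bmi = vapply(records, function(r) r@covariates$bmi, numeric(1))
  )
  if (is.null(dir)) return(list(records = records, manifest = manifest))

  if (dir.exists(dir) && length(list.files(dir)) > 0)
    stop("output path collision: ", dir, " already contains files")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  for (i in seq_along(records)) {
    r <- records[[i]]
    grid <- r@hr@startTime + 60 * (seq_along(r@hr@values) - 1)
    .atomicWrite(function(tmp) write.csv(
      data.frame(timestamp = fmt(grid), heart_rate = r@hr@values,
                 steps = r@steps@values),
      tmp, row.names = FALSE, quote = FALSE), file.path(dir, manifest$minute_file[i]))
    .atomicWrite(function(tmp) write.csv(
      data.frame(onset = fmt(r@sleep$onset), offset = fmt(r@sleep$offset)),
      tmp, row.names = FALSE, quote = FALSE), file.path(dir, manifest$sleep_file[i]))
  }
  .atomicWrite(function(tmp) write.csv(manifest, tmp, row.names = FALSE, quote = FALSE),
               file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}
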