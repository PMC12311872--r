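# Shared fixture builders (all fixtures are generated in code).

MON <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")  # a Monday

# minute series of `days` whole days from a function of minute index
mkSeries <- function(f, days = 5, kind = "heart_rate", start = MON,
                     missing = NULL) {
  t <- 0:(days * 1440 - 1)
  v <- if (is.function(f)) f(t) else rep_len(f, length(t))
  MinuteSeries(v, start, kind = kind,
               missing = if (is.null(missing)) logical(length(t)) else missing)
}

# write a toy minute CSV; rows is a data.frame(timestamp, heart_rate, steps)
writeMinuteCsv <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

minuteRows <- function(n, start = MON, hr = 70, steps = 5) {
  data.frame(timestamp = format(start + 60 * (seq_len(n) - 1),
                                "%Y-%m-%d %H:%M:%S", tz = "UTC"),
             heart_rate = rep_len(hr, n), steps = rep_len(steps, n))
}

# sleep episode data.frame from vectors of onset/offset minute offsets from MON
mkSleep <- function(onsetMin, offsetMin, start = MON) {
  data.frame(onset = start + 60 * onsetMin, offset = start + 60 * offsetMin)
}

# a default nightly schedule: sleep mst-centred each night of `days` days
regularSleep <- function(days = 5, mst = 210, tst = 420, start = MON) {
  nights <- (-1):(days - 2)
  onset <- (nights + 1) * 1440 + mst - tst / 2
  mkSleep(onset, onset + tst, start)
}

# hand-built participant record
mkRecord <- function(hrFun, stepFun = function(t) rep(5, length(t)), days = 5,
                     sleep = regularSleep(days), group = "control",
                     id = "toy") {
  ParticipantRecord(id,
    hr = mkSeries(hrFun, days, "heart_rate"),
    steps = mkSeries(stepFun, days, "steps"),
    sleep = sleep, group = group)
}

# small simulated marker cohort used by several tests
simMarkerCohort <- function(nCase = 20, nControl = 20, seed = 1,
                            markers = markerNames()) {
  sim <- simulateCohort(simConfig(case = metsGroupSpec(nCase),
                                  control = nonMetsGroupSpec(nControl),
                                  seed = seed))
  buildMarkerCohort(sim$records, markers = markers, verbose = FALSE)
}

# synthetic marker matrix cohort (direct, no simulator): one informative
# feature among noise
syntheticFeatureCohort <- function(n = 60, p = 12, shift = 2, seed = 1,
                                   informative = "f01") {
  set.seed(seed)
  g <- rep(c("case", "control"), each = n / 2)
  M <- matrix(rnorm(p * n), nrow = p,
              dimnames = list(sprintf("f%02d", 1:p), sprintf("id%03d", 1:n)))
  M[informative, g == "case"] <- M[informative, g == "case"] + shift
  MarkerCohort(M, group = g)
}
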