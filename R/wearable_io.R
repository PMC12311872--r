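# Reading minute-level wearable exports, repairing zero-coded heart-rate gaps
# and enforcing the wear-time eligibility rules.

.parseTimestamps <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")
  ts <- best <- NULL
  for (f in fmts) {
    p <- as.POSIXct(strptime(x, f, tz = "UTC"))
    if (!anyNA(p)) { ts <- p; break }
    if (is.null(best) || sum(!is.na(p)) > sum(!is.na(best))) best <- p
  }
  if (is.null(ts)) {
    bad <- which(is.na(best))[1]
    stop("malformed timestamp at line ", bad + 1L, ": '", x[bad], "'")
  }
  # snap to the minute grid
  as.POSIXct(floor(as.numeric(ts) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

#' Read a minute-level wearable export into heart-rate and step series
#'
#' Parses a delimited minute file (columns \code{timestamp}, \code{heart_rate},
#' \code{steps}), regrids it onto a strict 1-minute grid, flags zero-coded or
#' absent heart-rate samples in the missingness mask, and trims to whole
#' calendar days (midnight to midnight).
#'
#' @param path path to the minute CSV.
#' @return list with elements \code{hr} and \code{steps}, both
#'   [MinuteSeries-class] objects on the same whole-day grid.
#' @export
readMinuteSeries <- function(path) {
  if (!file.exists(path)) stop("minute file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("timestamp", "heart_rate", "steps")
  if (!all(need %in% names(df)))
    stop("minute file must have columns: ", paste(need, collapse = ", "))
  ts <- .parseTimestamps(df$timestamp)
  if (anyDuplicated(ts)) {
    d <- ts[which(duplicated(ts))[1]]
    stop("duplicate minute in ", path, ": ", format(d, "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  o <- order(ts)
  ts <- ts[o]
  grid <- seq(ts[1], ts[length(ts)], by = 60)
  idx <- match(as.numeric(grid), as.numeric(ts))
  gap <- is.na(idx)
  hr <- ifelse(gap, 0, df$heart_rate[o][idx])
  st <- ifelse(gap, 0, df$steps[o][idx])
  hr[is.na(hr)] <- 0
  st[is.na(st)] <- 0
  hrMiss <- gap | hr <= 0
  stMiss <- gap

  # trim to whole calendar days
  mod <- .minuteOfDay(grid[1])
  from <- if (mod == 0) 1L else as.integer(1440 - mod + 1)
  nWhole <- (length(grid) - from + 1L) %/% 1440L
  if (nWhole < 1L) stop("record in ", path, " does not cover a whole calendar day")
  keep <- from:(from + nWhole * 1440L - 1L)
  list(
    hr = MinuteSeries(hr[keep], grid[from], kind = "heart_rate", missing = hrMiss[keep]),
    steps = MinuteSeries(st[keep], grid[from], kind = "steps", missing = stMiss[keep])
  )
}

#' Read a sleep-episode log
#'
#' @param path CSV with ISO-8601 columns \code{onset} and \code{offset}.
#' @return data.frame with POSIXct \code{onset} and \code{offset}, sorted by
#'   onset.
#' @export
readSleepFile <- function(path) {
  if (!file.exists(path)) stop("sleep file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("onset", "offset") %in% names(df)))
    stop("sleep file must have columns onset, offset")
  out <- data.frame(onset = .parseTimestamps(df$onset),
                    offset = .parseTimestamps(df$offset))
  out[order(out$onset), , drop = FALSE]
}

#' Read one participant's record
#'
#' @param minuteFile path to the minute-level CSV (timestamp, heart_rate,
#'   steps; heart_rate 0 means missing).
#' @param sleepFile path to the sleep episode CSV (onset, offset).
#' @param participantId identifier string.
#' @param group "case" or "control".
#' @param covariates optional named list (age, sex, bmi).
#' @return A [ParticipantRecord-class].
#' @export
readParticipant <- function(minuteFile, sleepFile, participantId,
                            group = "control", covariates = list()) {
  ms <- readMinuteSeries(minuteFile)
  sl <- readSleepFile(sleepFile)
  ParticipantRecord(participantId, hr = ms$hr, steps = ms$steps, sleep = sl,
                    group = group, covariates = covariates)
}

#' Read a cohort manifest and all participant records
#'
#' @param manifest path to a CSV with columns \code{participant_id},
#'   \code{minute_file}, \code{sleep_file}, \code{group} and optional
#'   \code{age}, \code{sex}, \code{bmi}. Relative file paths are resolved
#'   against the manifest's directory.
#' @return list of [ParticipantRecord-class] objects.
#' @export
readCohort <- function(manifest) {
  mf <- read.csv(manifest, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("participant_id", "minute_file", "sleep_file", "group")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  lapply(seq_len(nrow(mf)), function(i) {
    cov <- list()
    for (k in c("age", "sex", "bmi")) if (k %in% names(mf)) cov[[k]] <- mf[[k]][i]
    readParticipant(resolve(mf$minute_file[i]), resolve(mf$sleep_file[i]),
                    participantId = as.character(mf$participant_id[i]),
                    group = mf$group[i], covariates = cov)
  })
}

#' Repair missing heart-rate samples by linear interpolation
#'
#' Every masked run is replaced by linear interpolation between the nearest
#' valid neighbours; leading/trailing runs are filled with the nearest valid
#' value. The mask is preserved for audit, so the operation is idempotent.
#'
#' @param series a heart-rate [MinuteSeries-class].
#' @return a [MinuteSeries-class] with strictly positive values and the
#'   original mask.
#' @export
interpolateMissingHr <- function(series) {
  stopifnot(is(series, "MinuteSeries"))
  if (series@kind != "heart_rate")
    stop("interpolateMissingHr expects a heart_rate series")
  miss <- series@missing
  if (all(miss)) stop("no valid heart-rate data")
  if (!any(miss)) return(series)
  ok <- which(!miss)
  y <- approx(ok, series@values[ok], xout = seq_along(series@values),
              method = "linear", rule = 2)$y
  new("MinuteSeries", startTime = series@startTime, values = y,
      missing = miss, kind = "heart_rate")
}

#' Wear-time eligibility verdict
#'
#' A record is eligible when it contains at least 5 consecutive weekdays
#' (Monday-Friday, consecutive calendar dates) of valid wear AND no calendar
#' day has more than 6 hours (360 minutes) of missing (nonwear) heart-rate
#' data.
#'
#' @param record a [ParticipantRecord-class].
#' @param maxNonwearMinutes nonwear allowance per calendar day (default 360).
#' @param minWeekdays required run of consecutive weekdays (default 5).
#' @return list with \code{eligible} (logical), \code{reason} (string) and
#'   \code{nonwearByDay} (named integer vector of masked minutes per day).
#' @export
checkWearEligibility <- function(record, maxNonwearMinutes = 360L,
                                 minWeekdays = 5L) {
  hr <- record@hr
  nd <- length(hr@values) %/% 1440L
  dayStart <- .dateOf(hr@startTime)
  dates <- dayStart + seq_len(nd) - 1L
  perDay <- vapply(seq_len(nd), function(d)
    sum(hr@missing[((d - 1L) * 1440L + 1L):(d * 1440L)]), integer(1))
  names(perDay) <- as.character(dates)

  if (any(perDay > maxNonwearMinutes)) {
    return(list(eligible = FALSE, reason = "nonwear > 6 h", nonwearByDay = perDay))
  }
  # longest run of consecutive calendar dates that are all weekdays
  wday <- as.POSIXlt(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC"))$wday
  isWd <- wday %in% 1:5
  run <- 0L; best <- 0L
  for (d in seq_len(nd)) {
    run <- if (isWd[d] && (d == 1L || isWd[d - 1L])) run + 1L else as.integer(isWd[d])
    best <- max(best, run)
  }
  if (best < minWeekdays) {
    return(list(eligible = FALSE,
                reason = sprintf("fewer than %d consecutive weekdays", minWeekdays),
                nonwearByDay = perDay))
  }
  list(eligible = TRUE, reason = "eligible", nonwearByDay = perDay)
}
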