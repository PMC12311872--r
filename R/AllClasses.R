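#' MinuteSeries: one participant's 1-minute-grid wearable signal
#'
#' Holds a uniformly gridded minute-resolution signal (heart rate in bpm or
#' step counts in steps/min) together with its start time and a missingness
#' mask. Heart-rate gaps in device exports are zero-coded; the reader flags
#' them in the mask and [interpolateMissingHr()] repairs them while keeping
#' the mask for audit.
#'
#' @slot startTime POSIXct timestamp of the first sample.
#' @slot values numeric vector of non-negative samples on a strict 1-min grid.
#' @slot missing logical vector, same length; TRUE where the sample was
#'   originally missing or zero-coded.
#' @slot kind "heart_rate" or "steps".
#' @export
setClass("MinuteSeries",
  representation(
    startTime = "POSIXct",
    values    = "numeric",
    missing   = "logical",
    kind      = "character"
  )
)

setValidity("MinuteSeries", function(object) {
  msg <- character()
  if (length(object@startTime) != 1L || is.na(object@startTime))
    msg <- c(msg, "startTime must be a single non-NA POSIXct")
  if (length(object@values) < 2L)
    msg <- c(msg, "values must contain at least 2 samples")
  if (length(object@missing) != length(object@values))
    msg <- c(msg, "missing mask must match values in length")
  if (anyNA(object@values) || any(object@values < 0))
    msg <- c(msg, "values must be non-negative and non-NA (gaps are masked, not NA)")
  if (!object@kind %in% c("heart_rate", "steps"))
    msg <- c(msg, "kind must be 'heart_rate' or 'steps'")
  if (length(msg)) msg else TRUE
})

#' Construct a MinuteSeries
#'
#' @param values numeric samples on a 1-minute grid.
#' @param startTime POSIXct start of the grid (UTC recommended).
#' @param kind "heart_rate" or "steps".
#' @param missing logical missingness mask (default: all observed).
#' @return A [MinuteSeries-class] object.
#' @examples
#' s <- MinuteSeries(70 + sin(2 * pi * (0:2879) / 1440),
#'                   as.POSIXct("2023-01-02", tz = "UTC"))
#' nDays(s)
#' @export
MinuteSeries <- function(values, startTime, kind = "heart_rate",
                         missing = logical(length(values))) {
  new("MinuteSeries", startTime = as.POSIXct(startTime, tz = "UTC"),
      values = as.numeric(values), missing = missing, kind = kind)
}

#' @describeIn MinuteSeries-class signal samples
#' @param x,object a MinuteSeries
#' @export
seriesValues <- function(x) x@values

#' @describeIn MinuteSeries-class missingness mask
#' @export
missingMask <- function(x) x@missing

#' @describeIn MinuteSeries-class signal kind ("heart_rate" or "steps")
#' @export
signalKind <- function(x) x@kind

#' @describeIn MinuteSeries-class start timestamp
#' @export
seriesStart <- function(x) x@startTime

#' @describeIn MinuteSeries-class number of whole 1440-min days spanned
#' @export
nDays <- function(x) length(x@values) / 1440

setMethod("show", "MinuteSeries", function(object) {
  cat(sprintf("MinuteSeries <%s>: %d min (%.2f days) from %s; %d masked (%.1f%%)\n",
              object@kind, length(object@values), nDays(object),
              format(object@startTime, "%Y-%m-%d %H:%M", tz = "UTC"),
              sum(object@missing), 100 * mean(object@missing)))
})

setMethod("length", "MinuteSeries", function(x) length(x@values))

#' ParticipantRecord: one participant's wearable data and metadata
#'
#' @slot participantId character identifier.
#' @slot hr heart-rate [MinuteSeries-class].
#' @slot steps step-count [MinuteSeries-class].
#' @slot sleep data.frame of sleep episodes with POSIXct columns
#'   \code{onset} and \code{offset}.
#' @slot group "case" or "control".
#' @slot covariates named list, optionally holding \code{age} (years),
#'   \code{sex} ("M"/"F") and \code{bmi} (kg/m^2).
#' @export
setClass("ParticipantRecord",
  representation(
    participantId = "character",
    hr            = "MinuteSeries",
    steps         = "MinuteSeries",
    sleep         = "data.frame",
    group         = "character",
    covariates    = "list"
  )
)

setValidity("ParticipantRecord", function(object) {
  msg <- character()
  if (length(object@participantId) != 1L || !nzchar(object@participantId))
    msg <- c(msg, "participantId must be a non-empty string")
  if (object@hr@kind != "heart_rate") msg <- c(msg, "hr slot must be a heart_rate series")
  if (object@steps@kind != "steps") msg <- c(msg, "steps slot must be a steps series")
  if (length(object@hr@values) != length(object@steps@values) ||
      object@hr@startTime != object@steps@startTime)
    msg <- c(msg, "hr and steps must cover the same calendar span")
  if (length(object@hr@values) %% 1440 != 0)
    msg <- c(msg, "record must be trimmed to whole calendar days")
  if (!object@group %in% c("case", "control"))
    msg <- c(msg, "group must be 'case' or 'control'")
  if (nrow(object@sleep) > 0) {
    if (!all(c("onset", "offset") %in% names(object@sleep)))
      msg <- c(msg, "sleep must have onset and offset columns")
    else if (any(object@sleep$offset <= object@sleep$onset))
      msg <- c(msg, "sleep episodes must have offset > onset")
    else if (any(as.numeric(object@sleep$offset - object@sleep$onset, units = "hours") >= 24))
      msg <- c(msg, "sleep episodes must be shorter than 24 h")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ParticipantRecord
#'
#' @param participantId identifier string.
#' @param hr,steps [MinuteSeries-class] objects covering the same span.
#' @param sleep data.frame with POSIXct \code{onset}/\code{offset} columns.
#' @param group "case" or "control".
#' @param covariates optional named list (age, sex, bmi).
#' @return A [ParticipantRecord-class] object.
#' @export
ParticipantRecord <- function(participantId, hr, steps, sleep, group = "control",
                              covariates = list()) {
  new("ParticipantRecord", participantId = participantId, hr = hr, steps = steps,
      sleep = sleep, group = group, covariates = covariates)
}

#' @describeIn ParticipantRecord-class participant identifier
#' @param x,object a ParticipantRecord
#' @export
participantId <- function(x) x@participantId

#' @describeIn ParticipantRecord-class heart-rate series
#' @export
heartRate <- function(x) x@hr

#' @describeIn ParticipantRecord-class step-count series
#' @export
stepCounts <- function(x) x@steps

#' @describeIn ParticipantRecord-class sleep episode table
#' @export
sleepEpisodes <- function(x) x@sleep

#' @describeIn ParticipantRecord-class group label
#' @export
groupLabel <- function(x) x@group

setMethod("show", "ParticipantRecord", function(object) {
  cat(sprintf("ParticipantRecord %s (%s): %.0f days, %d sleep episodes\n",
              object@participantId, object@group, nDays(object@hr),
              nrow(object@sleep)))
})

#' EnergyProfile: per-central-period wavelet energy of one signal
#'
#' Total Morlet spectrogram energy (squared coefficient magnitude summed over
#' time) at each central period of the analysis grid. When \code{normalized},
#' the energies are fractions of the total over the grid and sum to 1.
#'
#' @slot periods central periods in minutes (strictly increasing).
#' @slot energy non-negative energy per period.
#' @slot totalEnergy total (pre-normalization) energy over the grid.
#' @slot normalized logical; TRUE if \code{energy} sums to 1.
#' @slot kind signal kind the profile was computed from.
#' @export
setClass("EnergyProfile",
  representation(
    periods     = "numeric",
    energy      = "numeric",
    totalEnergy = "numeric",
    normalized  = "logical",
    kind        = "character"
  )
)

setValidity("EnergyProfile", function(object) {
  msg <- character()
  if (length(object@periods) != length(object@energy))
    msg <- c(msg, "periods and energy must have equal length")
  if (is.unsorted(object@periods, strictly = TRUE))
    msg <- c(msg, "periods must be strictly increasing")
  if (any(object@energy < 0)) msg <- c(msg, "energy must be non-negative")
  if (object@normalized && abs(sum(object@energy) - 1) > 1e-9)
    msg <- c(msg, "normalized energy must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnergyProfile-class grid of central periods (minutes)
#' @param x,object an EnergyProfile
#' @export
profilePeriods <- function(x) x@periods

#' @describeIn EnergyProfile-class energy at each central period
#' @export
profileEnergy <- function(x) x@energy

setMethod("show", "EnergyProfile", function(object) {
  cat(sprintf("EnergyProfile <%s>: %d periods in [%.0f, %.0f] min, %s, peak at %.0f min\n",
              object@kind, length(object@periods), min(object@periods),
              max(object@periods),
              if (object@normalized) "normalized" else "absolute",
              object@periods[which.max(object@energy)]))
})

#' MarkerCohort: marker panel by participant, with group labels
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] with one
#' assay \code{"markers"} (markers in rows, participants in columns) and a
#' mandatory \code{group} column ("case"/"control") in \code{colData};
#' optional covariate columns (age, sex, bmi) ride along in \code{colData}.
#'
#' @export
setClass("MarkerCohort", contains = "SummarizedExperiment")

setValidity("MarkerCohort", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (!all(cd$group %in% c("case", "control")))
    msg <- c(msg, "group must be 'case' or 'control'")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "participant ids must be unique")
  if (!"markers" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'markers' is required")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerCohort
#'
#' @param markers numeric matrix, markers in rows, participants in columns
#'   (column names are participant ids). A participants-by-markers matrix is
#'   also accepted and transposed if its column names match [markerNames()].
#' @param group character/factor of "case"/"control" per participant.
#' @param covariates optional data.frame of per-participant covariates.
#' @return A [MarkerCohort-class] object.
#' @export
MarkerCohort <- function(markers, group, covariates = NULL) {
  if (!is.null(colnames(markers)) && all(colnames(markers) %in% markerNames()) &&
      !all(rownames(markers) %in% markerNames()))
    markers <- t(markers)
  cd <- S4Vectors::DataFrame(group = as.character(group))
  if (!is.null(covariates)) cd <- cbind(cd, S4Vectors::DataFrame(covariates))
  rownames(cd) <- colnames(markers)
  se <- SummarizedExperiment(assays = list(markers = markers), colData = cd)
  new("MarkerCohort", se)
}

#' @describeIn MarkerCohort-class the markers-by-participants matrix
#' @param x a MarkerCohort
#' @export
markerMatrix <- function(x) assay(x, "markers")

#' @describeIn MarkerCohort-class group labels per participant
#' @export
groupLabels <- function(x) as.character(colData(x)$group)

setMethod("show", "MarkerCohort", function(object) {
  g <- groupLabels(object)
  cat(sprintf("MarkerCohort: %d markers x %d participants (%d case / %d control)\n",
              nrow(object), ncol(object), sum(g == "case"), sum(g == "control")))
})
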