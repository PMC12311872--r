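# Assembly of the 26-marker panel for one participant.

.MARKER_NAMES <- c(
  "MST_Mean", "MST_SD", "TST_Mean", "TST_SD",
  "MESOR_SC", "MESOR_HR", "Amplitude_SC", "Amplitude_HR",
  "Acrophase_SC", "Acrophase_HR", "CQ_SC", "CQ_HR",
  "L5_SC", "L5_HR", "M10_SC", "M10_HR", "RA_SC", "RA_HR",
  "IS_SC", "IS_HR", "IV_SC", "IV_HR",
  "SSA_CARE_SC",
  "CCE_MF_HR", "CCE_LF_HR", "CCE_Ratio_HR"
)

#' Names of the 26-marker panel
#'
#' Four sleep summaries (mean/SD of MST and TST), eight cosinor indicators
#' (MESOR, amplitude, acrophase, CQ for step count and heart rate), ten
#' nonparametric indicators (L5, M10, RA, IS, IV for both signals), the
#' SSA-based CARE of step counts, and the three heart-rate CCE markers.
#'
#' @return character vector of length 26, in panel (reporting) order.
#' @export
markerNames <- function() .MARKER_NAMES

#' Compute the marker panel for one participant
#'
#' Upstream failures (e.g. a constant signal making acrophase, IS/IV or the
#' wavelet markers undefined) are recorded as NA with a reason, never as a
#' silent zero; the vector is always returned with all requested entries.
#' Heart-rate markers are computed on the linearly repaired series; step
#' markers on the raw series (zero steps are genuine rest). CCE is computed on
#' heart rate and CARE on step counts.
#'
#' @param record an eligible [ParticipantRecord-class].
#' @param markers subset of [markerNames()] to compute (default: all 26; only
#'   the marker families actually requested are evaluated).
#' @param binMinutes IV/IS bin width (default 60).
#' @param waveletCfg a [waveletConfig()].
#' @param ssaCfg an [ssaConfig()].
#' @return named numeric vector over \code{markers}, with attributes
#'   \code{reasons} (named character vector for NA entries) and
#'   \code{configHash} (provenance).
#' @export
computeMarkerVector <- function(record, markers = markerNames(),
                                binMinutes = 60L,
                                waveletCfg = waveletConfig(),
                                ssaCfg = ssaConfig()) {
  stopifnot(is(record, "ParticipantRecord"))
  bad <- setdiff(markers, .MARKER_NAMES)
  if (length(bad)) stop("unknown markers: ", paste(bad, collapse = ", "))
  out <- setNames(rep(NA_real_, length(markers)), markers)
  reasons <- character()
  want <- function(x) any(x %in% markers)
  put <- function(vals) {
    k <- intersect(names(vals), markers)
    out[k] <<- vals[k]
  }
  grab <- function(key, expr) {
    tryCatch(expr, error = function(e) {
      reasons[key] <<- conditionMessage(e)
      NULL
    })
  }

  hrRep <- NULL
  needHr <- want(c("MESOR_HR", "Amplitude_HR", "Acrophase_HR", "CQ_HR", "L5_HR",
                   "M10_HR", "RA_HR", "IS_HR", "IV_HR",
                   "CCE_MF_HR", "CCE_LF_HR", "CCE_Ratio_HR"))
  if (needHr)
    hrRep <- grab("HR", interpolateMissingHr(record@hr))

  if (want(c("MST_Mean", "MST_SD", "TST_Mean", "TST_SD"))) {
    v <- grab("sleep", {
      sm <- computeSleepMarkers(mainSleepPerNight(record@sleep))
      c(MST_Mean = unname(sm["mst_mean"]), MST_SD = unname(sm["mst_sd"]),
        TST_Mean = unname(sm["tst_mean"]), TST_SD = unname(sm["tst_sd"]))
    })
    if (!is.null(v)) put(v)
  }

  cosinorVals <- function(series, suffix) {
    f <- fitCosinor(series)
    setNames(c(f@mesor, f@amplitude, f@acrophase, f@cq),
             paste0(c("MESOR_", "Amplitude_", "Acrophase_", "CQ_"), suffix))
  }
  if (want(c("MESOR_SC", "Amplitude_SC", "Acrophase_SC", "CQ_SC"))) {
    v <- grab("cosinor_SC", cosinorVals(record@steps, "SC"))
    if (!is.null(v)) put(v)
  }
  if (want(c("MESOR_HR", "Amplitude_HR", "Acrophase_HR", "CQ_HR")) && !is.null(hrRep)) {
    v <- grab("cosinor_HR", cosinorVals(hrRep, "HR"))
    if (!is.null(v)) put(v)
  }

  npVals <- function(series, suffix) {
    np <- nonparametricMarkers(series, binMinutes = binMinutes)
    setNames(np[c("l5", "m10", "ra", "is_", "iv")],
             paste0(c("L5_", "M10_", "RA_", "IS_", "IV_"), suffix))
  }
  if (want(c("L5_SC", "M10_SC", "RA_SC", "IS_SC", "IV_SC"))) {
    v <- grab("nonparametric_SC", npVals(record@steps, "SC"))
    if (!is.null(v)) put(v)
  }
  if (want(c("L5_HR", "M10_HR", "RA_HR", "IS_HR", "IV_HR")) && !is.null(hrRep)) {
    v <- grab("nonparametric_HR", npVals(hrRep, "HR"))
    if (!is.null(v)) put(v)
  }

  if (want("SSA_CARE_SC")) {
    v <- grab("care", c(SSA_CARE_SC = computeCare(record@steps, ssaCfg)))
    if (!is.null(v)) put(v)
  }

  if (want(c("CCE_MF_HR", "CCE_LF_HR", "CCE_Ratio_HR")) && !is.null(hrRep)) {
    v <- grab("cce", {
      cce <- computeCce(cwtEnergyProfile(hrRep, waveletCfg))
      setNames(cce, c("CCE_MF_HR", "CCE_LF_HR", "CCE_Ratio_HR"))
    })
    if (!is.null(v)) put(v)
  }

  attr(out, "reasons") <- reasons
  attr(out, "configHash") <- .configHash(binMinutes, waveletCfg, ssaCfg)
  out
}

#' Build a MarkerCohort from participant records
#'
#' Applies the wear-time filter, computes the requested markers for each
#' eligible participant, and assembles them into a [MarkerCohort-class].
#' Ineligible participants are dropped with a message naming the reason.
#'
#' @param records list of [ParticipantRecord-class] objects.
#' @param markers markers to compute (default all 26).
#' @param checkEligibility apply [checkWearEligibility()] (default TRUE).
#' @param verbose message per exclusion (default TRUE).
#' @inheritParams computeMarkerVector
#' @return a [MarkerCohort-class]; excluded participant ids and reasons are
#'   kept in \code{metadata(x)$excluded}.
#' @export
buildMarkerCohort <- function(records, markers = markerNames(),
                              checkEligibility = TRUE, verbose = TRUE,
                              binMinutes = 60L, waveletCfg = waveletConfig(),
                              ssaCfg = ssaConfig()) {
  excluded <- character()
  if (checkEligibility) {
    keep <- vapply(records, function(r) {
      v <- checkWearEligibility(r)
      if (!v$eligible) {
        excluded[r@participantId] <<- v$reason
        if (verbose) message("excluding ", r@participantId, ": ", v$reason)
      }
      v$eligible
    }, logical(1))
    records <- records[keep]
  }
  if (length(records) == 0) stop("no eligible participants")
  M <- vapply(records, function(r)
    computeMarkerVector(r, markers = markers, binMinutes = binMinutes,
                        waveletCfg = waveletCfg, ssaCfg = ssaCfg),
    numeric(length(markers)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(markers))
  rownames(M) <- markers
  colnames(M) <- vapply(records, participantId, character(1))
  covNames <- unique(unlist(lapply(records, function(r) names(r@covariates))))
  covs <- NULL
  if (length(covNames)) {
    covs <- as.data.frame(lapply(covNames, function(k) {
      sapply(records, function(r) {
        v <- r@covariates[[k]]
        if (is.null(v)) NA else v
      })
    }), col.names = covNames)
  }
  mc <- MarkerCohort(M, group = vapply(records, groupLabel, character(1)),
                     covariates = covs)
  S4Vectors::metadata(mc)$excluded <- excluded
  mc
}

#' Write / read a marker table as CSV
#'
#' One row per participant: id, group, covariates, then the marker columns.
#' The file begins with a provenance header comment (tool version); the
#' reader skips comment lines.
#'
#' @param cohort a [MarkerCohort-class].
#' @param path CSV path.
#' @return \code{writeMarkerTable} returns \code{path} invisibly;
#'   \code{readMarkerTable} returns a [MarkerCohort-class].
#' @export
writeMarkerTable <- function(cohort, path) {
  cd <- as.data.frame(colData(cohort))
  df <- cbind(data.frame(participant_id = colnames(cohort)), cd,
              as.data.frame(t(markerMatrix(cohort))))
  .atomicWrite(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(sprintf("# circamark %s marker table", packageVersion("circamark")), con)
    write.csv(df, con, row.names = FALSE)
  }, path)
  invisible(path)
}

#' @rdname writeMarkerTable
#' @export
readMarkerTable <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  mk <- intersect(markerNames(), names(df))
  covNames <- setdiff(names(df), c("participant_id", "group", mk))
  M <- t(as.matrix(df[, mk, drop = FALSE]))
  colnames(M) <- df$participant_id
  covs <- if (length(covNames)) df[, covNames, drop = FALSE] else NULL
  MarkerCohort(M, group = df$group, covariates = covs)
}
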