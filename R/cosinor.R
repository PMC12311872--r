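# Single-component cosinor fit: Y(t) = M + A cos(2 pi t / tau + phi), fitted
# by least squares through the linear reparameterization
# Y = M + beta cos(w t) + gamma sin(w t),  A = sqrt(beta^2 + gamma^2).

#' CosinorFit: parameters of a least-squares cosinor fit
#'
#' @slot mesor rhythm-adjusted mean (signal units).
#' @slot amplitude half peak-to-trough extent (signal units, >= 0).
#' @slot acrophase clock time of the fitted peak, decimal hours in \[0, 24)
#'   (NA for a constant input where the phase is undefined).
#' @slot period fitted period in minutes.
#' @slot cq circadian quotient, amplitude / MESOR (NA when MESOR <= 0).
#' @slot coefficients named numeric: intercept, beta (cos) and gamma (sin).
#' @slot rss residual sum of squares.
#' @export
setClass("CosinorFit",
  representation(mesor = "numeric", amplitude = "numeric", acrophase = "numeric",
                 period = "numeric", cq = "numeric", coefficients = "numeric",
                 rss = "numeric"))

setValidity("CosinorFit", function(object) {
  msg <- character()
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (!is.na(object@acrophase) && (object@acrophase < 0 || object@acrophase >= 24))
    msg <- c(msg, "acrophase must lie in [0, 24)")
  if (object@period <= 0) msg <- c(msg, "period must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CosinorFit", function(object) {
  cat(sprintf(
    "CosinorFit (period %.0f min): MESOR %.3f, amplitude %.3f, acrophase %s h, CQ %s\n",
    object@period, object@mesor, object@amplitude,
    ifelse(is.na(object@acrophase), "NA", sprintf("%.3f", object@acrophase)),
    ifelse(is.na(object@cq), "NA", sprintf("%.4f", object@cq))))
})

#' Least-squares cosinor fit of a minute series
#'
#' Fits a single cosine of fixed period (default 1440 min, the circadian
#' component) to the pooled multi-day series. The acrophase is reported as the
#' clock time of the fitted peak in decimal hours, anchored to the series'
#' start timestamp.
#'
#' @param series a [MinuteSeries-class] covering at least one full period
#'   (heart rate should be repaired with [interpolateMissingHr()] first).
#' @param periodMinutes fixed period of the fitted cosine (default 1440).
#' @return A [CosinorFit-class] object.
#' @examples
#' t <- 0:7199
#' y <- 70 + 10 * cos(2 * pi * (t - 900) / 1440)
#' fitCosinor(MinuteSeries(y, as.POSIXct("2023-01-02", tz = "UTC")))
#' @export
fitCosinor <- function(series, periodMinutes = 1440) {
  stopifnot(is(series, "MinuteSeries"), periodMinutes > 0)
  y <- series@values
  n <- length(y)
  if (n < periodMinutes) stop("series must cover at least one full period")
  if (var(y) == 0) {
    m <- y[1]
    return(new("CosinorFit", mesor = m, amplitude = 0, acrophase = NA_real_,
               period = periodMinutes, cq = if (m > 0) 0 else NA_real_,
               coefficients = c(mesor = m, beta = 0, gamma = 0), rss = 0))
  }
  t <- seq_len(n) - 1          # minutes since series start
  w <- 2 * pi / periodMinutes
  X <- cbind(1, cos(w * t), sin(w * t))
  fit <- stats::.lm.fit(X, y)
  cf <- fit$coefficients
  m <- cf[1]; beta <- cf[2]; gamma <- cf[3]
  A <- sqrt(beta^2 + gamma^2)
  # y = M + A cos(w t - theta); peak at t = theta / w (minutes from start)
  theta <- atan2(gamma, beta)
  tPeak <- (theta / w) %% periodMinutes
  clockMin <- (.minuteOfDay(series@startTime) + tPeak) %% 1440
  new("CosinorFit", mesor = m, amplitude = A, acrophase = clockMin / 60,
      period = periodMinutes, cq = if (m > 0) A / m else NA_real_,
      coefficients = c(mesor = m, beta = beta, gamma = gamma),
      rss = sum(fit$residuals^2))
}

#' @describeIn fitCosinor evaluate a cosinor model on a vector of minutes
#'   since series start (used by tests as a brute-force probe).
#' @param fit a [CosinorFit-class]
#' @param t minutes since series start
#' @export
predictCosinor <- function(fit, t) {
  cf <- fit@coefficients
  w <- 2 * pi / fit@period
  cf[["mesor"]] + cf[["beta"]] * cos(w * t) + cf[["gamma"]] * sin(w * t)
}
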