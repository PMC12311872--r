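# Nonparametric rhythm markers: L5, M10, RA on the average daily profile
# (wrap-around windows) and IV / IS on hourly-binned multi-day sequences.

#' Average daily profile of a multi-day minute series
#'
#' @param series a [MinuteSeries-class] spanning >= 2 whole days.
#' @return numeric vector of length 1440: element m is the mean across days of
#'   minute-of-day m (relative to the series start, which is midnight for
#'   whole-day records).
#' @export
meanDailyProfile <- function(series) {
  x <- if (is(series, "MinuteSeries")) series@values else as.numeric(series)
  if (length(x) %% 1440 != 0 || length(x) < 2880)
    stop("series must span at least 2 whole days")
  rowMeans(matrix(x, nrow = 1440))
}

# means of all `width`-minute contiguous windows of a circular profile
.wrapWindowMeans <- function(profile, width) {
  n <- length(profile)
  cs <- cumsum(c(profile, profile[seq_len(width - 1)]))
  (cs[width:(n + width - 1)] - c(0, cs[seq_len(n - 1)])) / width
}

#' L5, M10 and relative amplitude from a daily profile
#'
#' L5 is the minimum mean over all 300-min contiguous windows of the (circular)
#' average day, M10 the maximum over all 600-min windows; windows wrap past
#' midnight and ties go to the earliest window start. RA = (M10 - L5) /
#' (M10 + L5), missing when M10 + L5 = 0.
#'
#' @param profile 1440-point non-negative daily profile
#'   (see [meanDailyProfile()]).
#' @return named numeric vector \code{l5}, \code{m10}, \code{ra},
#'   \code{l5_onset}, \code{m10_onset} (window start minutes, kept for
#'   diagnostics).
#' @export
l5m10ra <- function(profile) {
  stopifnot(length(profile) == 1440, all(profile >= 0))
  w5 <- .wrapWindowMeans(profile, 300)
  w10 <- .wrapWindowMeans(profile, 600)
  l5 <- min(w5); m10 <- max(w10)
  ra <- if (m10 + l5 == 0) NA_real_ else (m10 - l5) / (m10 + l5)
  c(l5 = l5, m10 = m10, ra = ra,
    l5_onset = which.min(w5) - 1, m10_onset = which.max(w10) - 1)
}

#' BinnedSeries: bin means of a multi-day minute series
#'
#' @slot values bin means in time order.
#' @slot binMinutes bin width in minutes.
#' @slot binsPerDay number of clock bins per day (1440 / binMinutes).
#' @slot hourlyProfile per-clock-bin means across days.
#' @slot grandMean mean of all bin values.
#' @export
setClass("BinnedSeries",
  representation(values = "numeric", binMinutes = "integer",
                 binsPerDay = "integer", hourlyProfile = "numeric",
                 grandMean = "numeric"))

setValidity("BinnedSeries", function(object) {
  msg <- character()
  if (1440L %% object@binMinutes != 0L)
    msg <- c(msg, "binMinutes must divide 1440")
  if (object@binsPerDay * object@binMinutes != 1440L)
    msg <- c(msg, "binsPerDay must equal 1440 / binMinutes")
  if (length(object@hourlyProfile) != object@binsPerDay)
    msg <- c(msg, "hourlyProfile length must equal binsPerDay")
  if (abs(object@grandMean - mean(object@values)) > 1e-8 * (1 + abs(object@grandMean)))
    msg <- c(msg, "grandMean must equal mean(values)")
  if (length(msg)) msg else TRUE
})

#' Bin a minute series into fixed-width bins
#'
#' @param series a [MinuteSeries-class] spanning whole days (or a numeric
#'   vector whose length is a multiple of 1440).
#' @param binMinutes bin width in minutes; must divide 1440 (default 60,
#'   the conventional actigraphy choice for IV/IS).
#' @return a [BinnedSeries-class].
#' @export
binSeries <- function(series, binMinutes = 60L) {
  x <- if (is(series, "MinuteSeries")) series@values else as.numeric(series)
  binMinutes <- as.integer(binMinutes)
  if (1440L %% binMinutes != 0L) stop("binMinutes must divide 1440")
  if (length(x) %% 1440L != 0L) stop("series must span whole days")
  v <- colMeans(matrix(x, nrow = binMinutes))
  s <- 1440L %/% binMinutes
  new("BinnedSeries", values = v, binMinutes = binMinutes, binsPerDay = s,
      hourlyProfile = rowMeans(matrix(v, nrow = s)), grandMean = mean(v))
}

#' Intradaily variability (IV)
#'
#' IV = N * sum((Y_t - Y_{t-1})^2) / ((N - 1) * sum((Y_t - Ybar)^2)) on the
#' binned multi-day sequence. IV is ~2 for white noise, small for smooth
#' rhythms, up to ~4 for maximal alternation.
#'
#' @param x a [BinnedSeries-class], a [MinuteSeries-class], or a numeric
#'   vector of whole-day minutes (the latter two are binned first).
#' @param binMinutes bin width when binning is needed (default 60).
#' @return IV (dimensionless), or NA for a constant series.
#' @export
intradailyVariability <- function(x, binMinutes = 60L) {
  b <- if (is(x, "BinnedSeries")) x else binSeries(x, binMinutes)
  y <- b@values
  n <- length(y)
  if (n < 3) stop("need at least 3 bins")
  den <- sum((y - mean(y))^2)
  if (den == 0) return(NA_real_)
  n * sum(diff(y)^2) / ((n - 1) * den)
}

#' Interdaily stability (IS)
#'
#' IS = N * sum_h((xbar_h - xbar)^2) / (S * sum_i((x_i - xbar)^2)) on the
#' binned sequence, where xbar_h are the S per-clock-bin means across days.
#' IS is 1 when all days are identical and tends to 0 for arrhythmic data.
#'
#' @inheritParams intradailyVariability
#' @return IS in \[0, 1\], or NA for a constant series.
#' @export
interdailyStability <- function(x, binMinutes = 60L) {
  b <- if (is(x, "BinnedSeries")) x else binSeries(x, binMinutes)
  y <- b@values
  n <- length(y)
  s <- b@binsPerDay
  if (n < 2L * s) stop("need at least 2 whole days")
  den <- s * sum((y - b@grandMean)^2)
  if (den == 0) return(NA_real_)
  n * sum((b@hourlyProfile - b@grandMean)^2) / den
}

#' All nonparametric markers of one series
#'
#' @param series a whole-day [MinuteSeries-class] (heart rate should be
#'   repaired first; steps are used raw since zeros are genuine rest).
#' @param binMinutes bin width for IV/IS (default 60).
#' @param l5m10Mode "profile" (default: L5/M10 on the average daily profile
#'   with wrap-around windows) or "perday" (per-day values averaged).
#' @return named numeric vector \code{l5}, \code{m10}, \code{ra}, \code{is_},
#'   \code{iv}.
#' @export
nonparametricMarkers <- function(series, binMinutes = 60L,
                                 l5m10Mode = c("profile", "perday")) {
  l5m10Mode <- match.arg(l5m10Mode)
  if (l5m10Mode == "profile") {
    lmr <- l5m10ra(meanDailyProfile(series))[c("l5", "m10", "ra")]
  } else {
    x <- series@values
    days <- matrix(x, nrow = 1440)
    per <- apply(days, 2, function(d) l5m10ra(d)[c("l5", "m10", "ra")])
    lmr <- rowMeans(per)
  }
  b <- binSeries(series, binMinutes)
  c(lmr, is_ = interdailyStability(b), iv = intradailyVariability(b))
}
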