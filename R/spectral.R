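# Morlet continuous wavelet transform: spectrogram, per-central-period energy
# profile, CCE band markers and the cohort band scan.
#
# The mother wavelet is psi(t) = pi^(-1/4) exp(i w0 t) exp(-t^2 / 2) (analytic
# Morlet). The transform is computed in the Fourier domain on the circularly
# extended record, so the energy summed over all time shifts obeys the
# Parseval identity
#   sum_b |W(a, b)|^2 = (1/N) sum_k a |xhat_k|^2 |psihat(a w_k)|^2,
# which is how the energy profile is evaluated (no inverse transforms needed).
# Scale and central period are related by the map under which the energy
# response to a sinusoid of that period peaks exactly at its own grid period:
# for the rectified spectrum that is the centre-frequency relation
#   a = w0 * period / (2 pi),
# and for the raw squared magnitude the standard Morlet Fourier-period map
#   a = period * (w0 + sqrt(2 + w0^2)) / (4 pi)
# (whose small offset from the centre-frequency relation compensates the
# scale factor carried by the raw spectrum).
#
# Two energy definitions are offered. "rectified" (default) divides the
# squared magnitude by the scale (the bias-rectified wavelet spectrum), so
# sinusoids of equal amplitude contribute equal total energy regardless of
# period; "squared_magnitude" is the raw |W|^2 of the 1/sqrt(a)-normalized
# transform, under which time-summed energy grows proportionally to the
# period. Band energies are reported as fractions of the grid total either
# way, so the choice affects only the relative weighting across periods.

.cceBands <- list(mid = c(69, 80), low = c(900, 1100))

#' Morlet wavelet analysis configuration
#'
#' @param omega0 dimensionless centre frequency of the Morlet mother
#'   (default 6, the conventional choice balancing time and period
#'   resolution).
#' @param periods central periods in minutes. The default is a geometric grid
#'   on \code{[minPeriod, maxPeriod]} anchored so that it passes exactly
#'   through the canonical periods of interest, 70 min and the circadian 1440
#'   min (ratio \code{(1440/70)^(1/66)}, ~95 points on 20-1500 min, >= 3 grid
#'   periods inside each CCE band).
#' @param nPeriods if supplied, a plain log-spaced grid of this many points is
#'   used instead of the anchored default.
#' @param minPeriod,maxPeriod grid range in minutes when \code{periods} is
#'   NULL (defaults 20-1500).
#' @param normalizeInput z-score the signal before the transform and report
#'   the energy profile as fractions of the grid total (default TRUE, which
#'   makes band energies dimensionless fractions of total energy).
#' @param energyKind "rectified" (default; squared coefficient magnitude
#'   divided by scale — the bias-rectified spectrum, unbiased across periods)
#'   or "squared_magnitude" (raw squared magnitude). Both are additive over
#'   time in the Parseval sense.
#' @return list of class "waveletConfig".
#' @export
waveletConfig <- function(omega0 = 6, periods = NULL, nPeriods = NULL,
                          minPeriod = 20, maxPeriod = 1500,
                          normalizeInput = TRUE,
                          energyKind = c("rectified", "squared_magnitude")) {
  energyKind <- match.arg(energyKind)
  stopifnot(omega0 > 0)
  if (is.null(periods)) {
    if (is.null(nPeriods)) {
      lr <- log(1440 / 70) / 66
      k <- seq(ceiling(log(minPeriod / 1440) / lr),
               floor(log(maxPeriod / 1440) / lr))
      periods <- 1440 * exp(lr * k)
    } else {
      periods <- exp(seq(log(minPeriod), log(maxPeriod), length.out = nPeriods))
    }
  }
  if (is.unsorted(periods, strictly = TRUE))
    stop("period grid must be strictly increasing")
  for (b in names(.cceBands)) {
    k <- sum(periods >= .cceBands[[b]][1] & periods <= .cceBands[[b]][2])
    if (k < 2)
      stop(sprintf("period grid has %d point(s) in the %s-frequency CCE band [%g, %g]; need >= 2",
                   k, b, .cceBands[[b]][1], .cceBands[[b]][2]))
  }
  structure(list(omega0 = omega0, periods = periods,
                 normalizeInput = normalizeInput, energyKind = energyKind),
            class = "waveletConfig")
}

#' @describeIn waveletConfig scale corresponding to a central period, under
#'   the map that makes the chosen energy definition peak at the period of a
#'   pure sinusoid
#' @param period central period in minutes
#' @param omega0 Morlet centre frequency
#' @export
morletScale <- function(period, omega0 = 6, energyKind = "rectified") {
  if (energyKind == "rectified") omega0 * period / (2 * pi)
  else period * (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
}

# |psihat(u)|, u = a * omega; Fourier transform of the analytic Morlet mother
# (positive frequencies only): psihat(u) = pi^(1/4) sqrt(2) exp(-(u - w0)^2 / 2)
.morletFT <- function(u, omega0) {
  ifelse(u > 0, pi^0.25 * sqrt(2) * exp(-(u - omega0)^2 / 2), 0)
}

.prepSignal <- function(series, cfg) {
  x <- if (is(series, "MinuteSeries")) series@values else as.numeric(series)
  n <- length(x)
  if (max(cfg$periods) > n / 2)
    stop("period unresolvable: grid extends beyond half the record length")
  if (cfg$normalizeInput) {
    s <- sd(x)
    if (s == 0) stop("zero variance: constant input cannot be z-scored")
    x <- (x - mean(x)) / s
  }
  x
}

#' Per-central-period CWT energy profile
#'
#' For each central period of the grid, the Morlet spectrogram energy (squared
#' coefficient magnitude) is summed over all time shifts; with the default
#' configuration the input is z-scored first and the profile is normalized to
#' sum to 1 over the grid, so entries are dimensionless energy fractions.
#'
#' @param series a whole-day [MinuteSeries-class] (heart rate repaired first)
#'   or a numeric vector.
#' @param cfg a [waveletConfig()].
#' @return an [EnergyProfile-class].
#' @export
cwtEnergyProfile <- function(series, cfg = waveletConfig()) {
  x <- .prepSignal(series, cfg)
  n <- length(x)
  xhat2 <- Mod(fft(x))^2
  omega <- 2 * pi * (seq_len(n) - 1) / n
  omega[omega > pi] <- 0   # analytic wavelet: positive frequencies only
  e <- vapply(cfg$periods, function(p) {
    a <- morletScale(p, cfg$omega0, cfg$energyKind)
    w <- if (cfg$energyKind == "rectified") 1 else a
    w * sum(xhat2 * .morletFT(a * omega, cfg$omega0)^2) / n
  }, numeric(1))
  tot <- sum(e)
  if (cfg$normalizeInput && tot > 0) e <- e / tot
  new("EnergyProfile", periods = cfg$periods, energy = e, totalEnergy = tot,
      normalized = cfg$normalizeInput && tot > 0,
      kind = if (is(series, "MinuteSeries")) series@kind else "numeric")
}

#' Full Morlet CWT coefficient matrix (spectrogram)
#'
#' Mainly for plotting, dumping and for verifying the Parseval-based energy
#' profile; rows are central periods, columns minutes.
#'
#' @inheritParams cwtEnergyProfile
#' @return complex matrix of CWT coefficients (periods x time).
#' @export
cwtSpectrogram <- function(series, cfg = waveletConfig()) {
  x <- .prepSignal(series, cfg)
  n <- length(x)
  xhat <- fft(x)
  omega <- 2 * pi * (seq_len(n) - 1) / n
  omega[omega > pi] <- 0
  W <- matrix(0i, nrow = length(cfg$periods), ncol = n,
              dimnames = list(sprintf("%.2f", cfg$periods), NULL))
  for (i in seq_along(cfg$periods)) {
    a <- morletScale(cfg$periods[i], cfg$omega0, cfg$energyKind)
    W[i, ] <- fft(xhat * sqrt(a) * .morletFT(a * omega, cfg$omega0),
                  inverse = TRUE) / n
  }
  W
}

#' @describeIn cwtSpectrogram write a spectrogram energy matrix as delimited
#'   text (periods x minutes of |W|^2), atomically.
#' @param path output path for the tab-separated dump.
#' @export
writeSpectrogram <- function(series, path, cfg = waveletConfig()) {
  W <- Mod(cwtSpectrogram(series, cfg))^2
  .atomicWrite(function(tmp) {
    write.table(W, tmp, sep = "\t", quote = FALSE, col.names = FALSE)
  }, path)
}

#' CCE band markers from an energy profile
#'
#' Sums profile energy over grid periods inside the mid-frequency (69-80 min)
#' and low-frequency (900-1100 min) bands (inclusive) and forms their ratio.
#'
#' @param profile an [EnergyProfile-class] covering both bands.
#' @return named numeric vector \code{CCE_MF}, \code{CCE_LF},
#'   \code{CCE_Ratio} (ratio NA when the low-frequency energy is 0).
#' @export
computeCce <- function(profile) {
  stopifnot(is(profile, "EnergyProfile"))
  bandSum <- function(b) {
    inb <- profile@periods >= b[1] & profile@periods <= b[2]
    if (!any(inb)) stop("band not covered by grid: [", b[1], ", ", b[2], "] min")
    sum(profile@energy[inb])
  }
  mid <- bandSum(.cceBands$mid)
  low <- bandSum(.cceBands$low)
  c(CCE_MF = mid, CCE_LF = low,
    CCE_Ratio = if (low == 0) NA_real_ else mid / low)
}

#' Group band scan: per-period two-sample test of CWT energy
#'
#' @param profiles list of [EnergyProfile-class] objects on a common grid, or
#'   a participants-by-periods energy matrix.
#' @param group character vector of "case"/"control" per participant.
#' @param test "t" (Welch) or "wilcoxon".
#' @return data.frame with columns \code{period} and \code{p} (NA where a
#'   group is degenerate at that period).
#' @export
bandScan <- function(profiles, group, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (is.list(profiles)) {
    periods <- profiles[[1]]@periods
    E <- do.call(rbind, lapply(profiles, function(p) {
      if (!isTRUE(all.equal(p@periods, periods)))
        stop("all profiles must share the same period grid")
      p@energy
    }))
  } else {
    E <- profiles
    periods <- as.numeric(colnames(E))
  }
  stopifnot(nrow(E) == length(group))
  ca <- group == "case"
  if (sum(ca) < 2 || sum(!ca) < 2) stop("need >= 2 participants per group")
  p <- vapply(seq_along(periods), function(j) {
    a <- E[ca, j]; b <- E[!ca, j]
    if (sd(a) == 0 && sd(b) == 0) return(NA_real_)
    if (test == "t") t.test(a, b)$p.value
    else suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(period = periods, p = p)
}
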