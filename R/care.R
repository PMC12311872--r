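# Circadian activity rhythm energy (CARE): singular spectrum analysis of the
# step-count series, reporting the fraction of energy carried by subsignals
# whose dominant cycle is shorter than 24 h.
#
# This is a reimplementation from the published description (SSA/SVD, sub-24 h
# subsignal energy), not a reference implementation; all free choices (window
# length, component count, the binning resolution and period estimation by
# periodogram peak) are surfaced in ssaConfig.

#' SSA configuration for CARE
#'
#' @param windowMinutes SSA window length in minutes (default 1440, one day,
#'   so components at and above the circadian period are resolvable).
#' @param nComponents number of leading SVD components retained (default 20).
#' @param periodThresholdMinutes components with dominant period strictly
#'   below this threshold count as sub-circadian (default 1440).
#' @param binMinutes resolution the series is averaged to before SSA
#'   (default 5 min; step counts are bursty at minute resolution and all
#'   periods of interest are >= 10 min).
#' @return list of class "ssaConfig".
#' @export
ssaConfig <- function(windowMinutes = 1440L, nComponents = 20L,
                      periodThresholdMinutes = 1440, binMinutes = 5L) {
  stopifnot(windowMinutes >= 2 * binMinutes, nComponents >= 1,
            windowMinutes %% binMinutes == 0, 1440 %% binMinutes == 0)
  structure(list(windowMinutes = as.integer(windowMinutes),
                 nComponents = as.integer(nComponents),
                 periodThresholdMinutes = periodThresholdMinutes,
                 binMinutes = as.integer(binMinutes)),
            class = "ssaConfig")
}

#' Singular spectrum decomposition of a minute series
#'
#' Builds the Hankel trajectory matrix of the (binned, mean-centred) series,
#' takes its SVD, and reconstructs each elementary component by diagonal
#' averaging. The dominant period of each component is the periodogram peak of
#' its reconstruction.
#'
#' @param series a whole-day [MinuteSeries-class] (or numeric vector of
#'   whole-day minutes).
#' @param cfg an [ssaConfig()].
#' @return list with \code{components} (bins x r matrix of reconstructed
#'   subsignals), \code{energy} (squared singular values), \code{periods}
#'   (dominant period of each component, minutes), \code{mean} (the removed
#'   mean) and \code{binMinutes}.
#' @export
ssaDecompose <- function(series, cfg = ssaConfig()) {
  x0 <- if (is(series, "MinuteSeries")) series@values else as.numeric(series)
  if (length(x0) %% 1440 != 0) stop("series must span whole days")
  x <- colMeans(matrix(x0, nrow = cfg$binMinutes))
  mu <- mean(x)
  x <- x - mu
  n <- length(x)
  L <- cfg$windowMinutes %/% cfg$binMinutes
  if (L > n %/% 2) stop("window length must not exceed half the record")
  K <- n - L + 1L
  X <- matrix(x[outer(seq_len(L), 0:(K - 1L), "+")], nrow = L)
  # SVD via the L x L eigendecomposition (L << K): X = U D V', XX' = U D^2 U'
  ev <- eigen(tcrossprod(X), symmetric = TRUE)
  d2 <- pmax(ev$values, 0)
  r <- min(cfg$nComponents, sum(d2 > max(d2) * 1e-24), L)
  if (r < 1) stop("zero-variance series")
  counts <- convolve(rep(1, L), rep(1, K), type = "open")
  comps <- matrix(0, nrow = n, ncol = r)
  periods <- numeric(r)
  half <- n %/% 2
  for (i in seq_len(r)) {
    u <- ev$vectors[, i]
    dv <- crossprod(X, u)[, 1]            # d_i * v_i
    g <- convolve(u, rev(dv), type = "open") / counts
    comps[, i] <- g
    spec <- Mod(fft(g - mean(g)))^2
    kmax <- which.max(spec[2:(half + 1L)])
    periods[i] <- n * cfg$binMinutes / kmax
  }
  list(components = comps, energy = d2[seq_len(r)], periods = periods,
       mean = mu, binMinutes = cfg$binMinutes)
}

#' Circadian activity rhythm energy (CARE)
#'
#' CARE = energy of SSA components with dominant period strictly below the
#' threshold (24 h by default) divided by the total energy of all retained
#' components. It is scale-invariant and lies in \[0, 1\].
#'
#' @param series the step-count [MinuteSeries-class] (>= 5 whole days
#'   recommended) or a numeric vector of whole-day minutes.
#' @param cfg an [ssaConfig()].
#' @return CARE (dimensionless), or NA for a zero-variance series.
#' @export
computeCare <- function(series, cfg = ssaConfig()) {
  x <- if (is(series, "MinuteSeries")) series@values else as.numeric(series)
  if (var(x) == 0) return(NA_real_)
  d <- ssaDecompose(series, cfg)
  sub <- d$periods < cfg$periodThresholdMinutes
  sum(d$energy[sub]) / sum(d$energy)
}
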