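# Sleep markers: main-sleep selection per night, midsleep time (MST) and
# total sleep time (TST) summaries across nights.

#' Select the main sleep episode of each night
#'
#' A night runs from 18:00 of day d to noon of day d+1. Every episode whose
#' midpoint falls in that window belongs to night d; per night the longest
#' episode is kept and shorter nocturnal episodes and daytime naps are
#' discarded. Nights without any episode are simply absent from the result
#' (their count is reported in the \code{"nightsOmitted"} attribute when a
#' night between the first and last kept night has no episode).
#'
#' @param episodes data.frame with POSIXct \code{onset}/\code{offset}, sorted
#'   by onset (as returned by [readSleepFile()] / [sleepEpisodes()]).
#' @return data.frame of one episode per night with an added \code{night}
#'   column (the Date of the evening the night started).
#' @export
mainSleepPerNight <- function(episodes) {
  if (nrow(episodes) == 0)
    return(cbind(episodes, data.frame(night = as.Date(character()))))
  mid <- episodes$onset + (episodes$offset - episodes$onset) / 2
  mod <- .minuteOfDay(mid)
  night <- .dateOf(mid)
  night[mod < 720] <- night[mod < 720] - 1L   # after-midnight part of the night
  inWindow <- mod >= 1080 | mod < 720         # 18:00 -> noon next day
  keep <- which(inWindow)
  if (length(keep) == 0)
    return(cbind(episodes[0, ], data.frame(night = as.Date(character()))))
  dur <- as.numeric(episodes$offset - episodes$onset, units = "mins")
  best <- vapply(split(keep, as.character(night[keep])), function(ix)
    ix[which.max(dur[ix])], integer(1))
  out <- episodes[sort(best), , drop = FALSE]
  out$night <- night[sort(best)]
  span <- as.integer(max(out$night) - min(out$night)) + 1L
  attr(out, "nightsOmitted") <- span - nrow(out)
  out
}

#' Midsleep-time and total-sleep-time summaries across nights
#'
#' Per night, MST is the clock midpoint of the episode expressed in minutes
#' after midnight and TST is the episode duration in minutes. MST is averaged
#' circularly (23:50 and 00:10 average to 00:00) and its SD is the ordinary
#' SD of the deviations from the circular mean, unwrapped to (-720, 720].
#'
#' @param nightly data.frame of one episode per night (see
#'   [mainSleepPerNight()]).
#' @return named numeric vector: \code{mst_mean}, \code{mst_sd},
#'   \code{tst_mean}, \code{tst_sd} (all minutes; \code{mst_mean} in
#'   \[0, 1440)).
#' @export
computeSleepMarkers <- function(nightly) {
  if (nrow(nightly) < 2) stop("insufficient nights")
  mid <- nightly$onset + (nightly$offset - nightly$onset) / 2
  mst <- .minuteOfDay(mid)
  tst <- as.numeric(nightly$offset - nightly$onset, units = "mins")
  mu <- .circularMeanMinutes(mst)
  dev <- ((mst - mu + 720) %% 1440) - 720
  c(mst_mean = mu, mst_sd = sd(dev), tst_mean = mean(tst), tst_sd = sd(tst))
}
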