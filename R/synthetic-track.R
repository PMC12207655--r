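# Synthetic central-place GPS tracks: smooth out-and-back loops with a
# wandering bearing, guaranteed to start and end at the colony and to reach
# (within 10%) a configured maximum range.

#' Generate a synthetic out-and-back foraging track
#'
#' The track follows a smooth radial profile `r(s) = peak * sin(pi s)^1.3`
#' (s the trip fraction) with a slowly wandering bearing, so it departs the
#' colony, reaches `max_range` (up to a few percent of jitter) mid-trip and
#' homes back.  Fixes are uniformly spaced.
#'
#' @param colony `c(lon, lat)` decimal degrees.
#' @param trip_duration_days trip length in days.
#' @param max_range_km maximum range from the colony in km; tracks that
#'   never leave the 1 km colony exclusion simply yield no trips.
#' @param fix_interval_min fix cadence in minutes (default 60).
#' @param seed integer seed.
#' @param t0 departure time (POSIXct UTC or numeric seconds), default 0.
#' @param pad_h hours of at-colony fixes added before departure and after
#'   return (default 2), so the trip is bracketed and segments as complete.
#' @return data frame: `time`, `lon`, `lat`.
#' @export
gen_track <- function(colony, trip_duration_days, max_range_km,
                      fix_interval_min = 60, seed = 1, t0 = 0, pad_h = 2) {
  if (trip_duration_days <= 0) stop("trip duration must be positive")
  if (max_range_km <= 0) stop("max_range must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  step <- fix_interval_min * 60
  dur_s <- trip_duration_days * 86400
  tt <- seq(0, dur_s, by = step)
  s <- tt / dur_s
  peak <- max_range_km * (1 + runif(1, -0.04, 0.04))
  r <- peak * sin(pi * s)^1.3
  bearing <- runif(1, 0, 360) + smooth_wander(s * 100, 35, 0.02) +
    20 * sin(pi * s)
  pos <- geosphere::destPoint(matrix(colony, ncol = 2,
                                     nrow = length(tt), byrow = TRUE),
                              b = bearing, d = r * 1000)
  trip <- data.frame(time = t0 + tt, lon = pos[, 1], lat = pos[, 2])
  if (pad_h > 0) {
    pre_t <- seq(-pad_h * 3600, -step, by = step)
    post_t <- seq(dur_s + step, dur_s + pad_h * 3600, by = step)
    at_col <- function(times) data.frame(
      time = t0 + times,
      lon = colony[1] + rnorm(length(times), 0, 0.0005),
      lat = colony[2] + rnorm(length(times), 0, 0.0005))
    trip <- rbind(at_col(pre_t), trip, at_col(post_t))
  }
  rownames(trip) <- NULL
  trip
}
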