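# Synthetic 1 Hz depth stream: slow bounded sensor drift, scheduled dive
# excursions, Gaussian noise, quantised to the 0.005 m sensor resolution.

#' Generate a synthetic depth trace with scheduled dives
#'
#' The series is a slowly varying non-negative drift (bounded by
#' `drift_max`, emulating pressure-sensor zero drift), plus one parabolic
#' excursion per scheduled dive, plus Gaussian noise, quantised to the
#' 0.005 m logger resolution.  Scheduled dive maxima are recoverable by the
#' dive pipeline (outlier repair, zero-offset correction, threshold
#' detection).
#'
#' @param dives data frame with columns `start` (seconds from trace start),
#'   `max_depth` (m) and `duration` (s); may have zero rows.
#' @param total_duration total length in seconds.
#' @param drift_max drift bound in metres (default 0.49, the upper end of
#'   zero offsets seen on these loggers).
#' @param noise_sd Gaussian noise SD in metres (default 0.005).
#' @param seed integer seed.
#' @param t0 start time, default 0.
#' @return a [depth_trace()] at 1 Hz.
#' @export
gen_depth <- function(dives = NULL, total_duration, drift_max = 0.49,
                      noise_sd = 0.005, seed = 1, t0 = 0) {
  if (total_duration < 1) stop("total_duration must be positive")
  if (drift_max < 0) stop("drift_max must be non-negative")
  if (is.null(dives)) dives <- data.frame(start = numeric(0),
                                          max_depth = numeric(0),
                                          duration = numeric(0))
  if (nrow(dives) > 0) {
    if (any(dives$start < 0 | dives$start + dives$duration > total_duration))
      stop("scheduled dives must fit within total_duration")
    o <- order(dives$start)
    dives <- dives[o, , drop = FALSE]
    if (nrow(dives) > 1 &&
        any(head(dives$start + dives$duration, -1) > tail(dives$start, -1)))
      stop("scheduled dives overlap")
  }
  n <- round(total_duration)
  t <- seq_len(n) - 1
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # smooth drift rescaled into [0, drift_max]
  drift <- if (drift_max > 0) {
    w <- smooth_wander(t, 1, 1 / (total_duration / 2))
    drift_max * (w - min(w)) / max(diff(range(w)), .Machine$double.eps)
  } else rep(0, n)
  depth <- drift
  if (nrow(dives) > 0) {
    for (i in seq_len(nrow(dives))) {
      sel <- t >= dives$start[i] & t < dives$start[i] + dives$duration[i]
      # parabolic profile peaking at max_depth mid-dive; a one-sample dive
      # sits at its maximum for the full second
      u <- (t[sel] - dives$start[i] + 0.5) / dives$duration[i]
      depth[sel] <- depth[sel] + dives$max_depth[i] * pmin(4 * u * (1 - u) * 1.1, 1)
    }
  }
  if (noise_sd > 0) depth <- depth + rnorm(n, 0, noise_sd)
  depth <- round(depth / 0.005) * 0.005
  depth_trace(time = t0 + t, depth = depth)
}
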