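# Time-depth-recorder processing: outlier repair, zero-offset correction
# (rolling low quantile), dive detection above a fixed depth threshold, depth
# histograms, and per-dive pitch profiles.

#' Construct a 1 Hz depth trace
#'
#' @param time numeric or POSIXct timestamps at 1 Hz.
#' @param depth depth in metres, positive down.
#' @return `data.frame` of class `depth_trace`.
#' @export
depth_trace <- function(time, depth) {
  stopifnot(length(time) == length(depth))
  if (length(time) == 0) stop("empty trace")
  out <- data.frame(time = time, depth = depth)
  class(out) <- c("depth_trace", "data.frame")
  out
}

#' Repair implausible depth spikes
#'
#' Samples deeper than `max_plausible` are treated as pressure-sensor
#' anomalies (isolated spikes would imply impossible vertical speeds) and
#' replaced by linear interpolation between the nearest valid neighbours;
#' leading/trailing outliers take the nearest valid value.
#'
#' @param trace a `depth_trace`.
#' @param max_plausible maximum plausible depth in metres (default 15).
#' @return list: `trace` (repaired) and `n_outliers`.
#' @export
repair_outliers <- function(trace, max_plausible = 15) {
  d <- trace$depth
  bad <- d > max_plausible
  n_bad <- sum(bad)
  if (n_bad == length(d)) stop("all samples exceed the plausibility threshold")
  if (n_bad > 0) {
    t <- as.numeric(trace$time)
    d[bad] <- approx(t[!bad], d[!bad], xout = t[bad], rule = 2)$y
    trace$depth <- d
  }
  list(trace = trace, n_outliers = n_bad)
}

# Rolling quantile over a centered window, truncated at the edges.  Quantiles
# use the default linear interpolation between order statistics (type 7).
rolling_quantile <- function(x, width, prob) {
  zoo::rollapply(x, width = width, FUN = quantile, probs = prob, names = FALSE,
                 partial = TRUE, align = "center")
}

#' Zero-offset correction of a depth trace
#'
#' Pressure sensors drift slowly; the surface reading is recovered as a
#' rolling low quantile of depth (default the 10th percentile over a centered
#' 10-min window), which tracks drift while ignoring brief submergences.  The
#' correction is subtracted and corrected values below 0 m are clamped to 0 m.
#'
#' @param trace a `depth_trace` at 1 Hz.
#' @param window window length in minutes (default 10).
#' @param prob quantile used as the surface estimate (default 0.10).
#' @return list: `trace` (corrected), `zoc` (the offset series, metres).
#' @export
zero_offset_correct <- function(trace, window = 10, prob = 0.10) {
  if (nrow(trace) <= 2) stop("trace too short for zero-offset correction")
  if (prob <= 0 || prob >= 1) stop("quantile must be in (0, 1)")
  width <- round(window * 60) + 1
  zoc <- rolling_quantile(trace$depth, width, prob)
  trace$depth <- pmax(trace$depth - zoc, 0)
  list(trace = trace, zoc = zoc)
}

#' Detect dives in a corrected depth trace
#'
#' A dive is a maximal run of consecutive samples at or deeper than
#' `threshold`.  Duration counts the samples in the run (one sample at 1 Hz
#' is a 1-s dive).
#'
#' @param trace a corrected (non-negative) `depth_trace`.
#' @param threshold dive definition threshold in metres (default 0.5).
#' @return data frame of dive events: `start` (time of first sample),
#'   `duration_s`, `max_depth_m`, `mean_depth_m`; zero rows when no dives.
#' @export
detect_dives <- function(trace, threshold = 0.5) {
  if (threshold < 0) stop("threshold must be non-negative")
  sub <- trace$depth >= threshold
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  dt <- if (nrow(trace) > 1) median(diff(as.numeric(trace$time))) else 1
  out <- data.frame(
    start = trace$time[starts],
    duration_s = (ends - starts + 1) * dt,
    max_depth_m = mapply(function(a, b) max(trace$depth[a:b]), starts, ends),
    mean_depth_m = mapply(function(a, b) mean(trace$depth[a:b]), starts, ends)
  )
  if (nrow(out) == 0)
    out <- data.frame(start = trace$time[0], duration_s = numeric(0),
                      max_depth_m = numeric(0), mean_depth_m = numeric(0))
  out[order(as.numeric(out$start)), , drop = FALSE]
}

#' Histogram of depth readings
#'
#' Half-open bins `[k*bin, (k+1)*bin)`; percentages sum to 100.
#'
#' @param trace a corrected `depth_trace`.
#' @param bin bin width in metres (default 0.1).
#' @return data frame: `bin_lo`, `bin_hi`, `count`, `pct`.
#' @export
depth_histogram <- function(trace, bin = 0.1) {
  if (bin <= 0) stop("bin width must be positive")
  d <- trace$depth
  if (length(d) == 0) stop("empty trace")
  k <- floor(d / bin)
  tab <- table(k)
  kk <- as.integer(names(tab))
  data.frame(bin_lo = kk * bin, bin_hi = (kk + 1) * bin,
             count = as.integer(tab),
             pct = 100 * as.integer(tab) / length(d))
}

#' Pitch excursion profile around a dive
#'
#' Surface-feeding petrel dives show a sigmoidal pitch signature: a rapid
#' drop in body pitch at entry followed by recovery.  This summarises the
#' pitch series over the dive padded by `pad` seconds and flags whether a
#' fall below `-excursion` degrees is bracketed by near-level posture.
#'
#' @param dive one row of the [detect_dives()] output.
#' @param pitch_time,pitch timestamps and pitch series (degrees) covering the
#'   dive plus `pad` on both sides.
#' @param pad padding in seconds (default 5).
#' @param excursion pitch excursion threshold in degrees (default 20).
#' @return list: `min_pitch`, `max_pitch`, `dip_recovered` (logical).
#' @export
dive_pitch_profile <- function(dive, pitch_time, pitch, pad = 5,
                               excursion = 20) {
  t0 <- as.numeric(dive$start) - pad
  t1 <- as.numeric(dive$start) + dive$duration_s + pad
  tt <- as.numeric(pitch_time)
  if (min(tt) > t0 || max(tt) < t1)
    stop("pitch series does not cover the dive plus padding")
  sel <- tt >= t0 & tt <= t1
  p <- pitch[sel]
  dip_idx <- which(p <= -excursion)
  flag <- FALSE
  if (length(dip_idx) > 0) {
    i <- dip_idx[1]; j <- dip_idx[length(dip_idx)]
    before_ok <- i > 1 && any(p[seq_len(i - 1)] > -excursion / 2)
    after_ok <- j < length(p) && any(p[(j + 1):length(p)] > -excursion / 2)
    flag <- before_ok && after_ok
  }
  list(min_pitch = min(p), max_pitch = max(p), dip_recovered = flag)
}

#' Full depth pipeline: repair, correct, detect
#'
#' @param trace a raw `depth_trace`.
#' @param max_plausible outlier threshold in metres.
#' @param window,prob zero-offset correction parameters.
#' @param threshold dive threshold in metres.
#' @return list: `dives`, `trace` (corrected), `zoc`, `n_outliers`.
#' @export
process_depth <- function(trace, max_plausible = 15, window = 10, prob = 0.10,
                          threshold = 0.5) {
  rep <- repair_outliers(trace, max_plausible)
  zoc <- zero_offset_correct(rep$trace, window = window, prob = prob)
  dives <- detect_dives(zoc$trace, threshold = threshold)
  list(dives = dives, trace = zoc$trace, zoc = zoc$zoc,
       n_outliers = rep$n_outliers)
}
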