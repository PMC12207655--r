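# Accelerometer-derived metrics: static/dynamic decomposition, posture angles,
# VeDBA/VeSBA and wingbeat detection, all computed per sample from a raw
# tri-axial trace.

#' Construct an accelerometer trace
#'
#' Bundles time-stamped tri-axial acceleration (and an optional temperature
#' channel) into the data frame layout the metric functions expect.  Axes
#' follow the usual bird-borne logger convention: surge is forward-backward,
#' sway left-right, heave up-down (dorsal), all in units of g.
#'
#' @param time numeric or POSIXct timestamps, strictly increasing, nominally
#'   uniform (25 Hz for the loggers this package targets).
#' @param surge,sway,heave acceleration in g.
#' @param temp optional temperature channel in degrees C.
#' @return a `data.frame` of class `accel_trace`.
#' @export
accel_trace <- function(time, surge, sway, heave, temp = NULL) {
  n <- length(time)
  stopifnot(length(surge) == n, length(sway) == n, length(heave) == n)
  if (n == 0) stop("empty trace")
  tnum <- as.numeric(time)
  if (n > 1 && any(diff(tnum) <= 0)) stop("timestamps must be strictly increasing")
  if (any(abs(c(surge, sway, heave)) >= 16, na.rm = TRUE))
    stop("acceleration outside sensor range (|a| >= 16 g)")
  out <- data.frame(time = time, surge = surge, sway = sway, heave = heave)
  out$temp <- if (is.null(temp)) NA_real_ else temp
  class(out) <- c("accel_trace", "data.frame")
  out
}

#' Sampling rate of a trace in Hz
#' @param trace an `accel_trace`.
#' @return nominal sampling rate (1 / median timestep).
#' @export
trace_rate <- function(trace) {
  if (nrow(trace) < 2) return(NA_real_)
  1 / median(diff(as.numeric(trace$time)))
}

# Centered moving mean with truncated windows at the edges.  O(n) via
# cumulative sums; exact (no FFT/filter edge padding), so the conservation
# identity raw = static + dynamic holds to floating tolerance.
moving_mean <- function(x, half) {
  n <- length(x)
  if (half <= 0) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Split acceleration into static and dynamic components
#'
#' The static (gravitational/postural) component of each axis is a centered
#' moving mean over `window` seconds; the dynamic component is the raw signal
#' minus the static one, so static + dynamic reconstructs the raw axis
#' exactly.  Edge samples use shrunken (truncated) windows, keeping the output
#' the same length as the input.
#'
#' @param trace an `accel_trace`.
#' @param window smoothing window in seconds (default 1 s, the convention for
#'   25 Hz seabird loggers).
#' @return the trace with `static_surge`, `static_sway`, `static_heave`,
#'   `dyn_surge`, `dyn_sway`, `dyn_heave` columns appended.
#' @export
decompose <- function(trace, window = 1) {
  n <- nrow(trace)
  if (n == 0) stop("empty trace")
  rate <- trace_rate(trace)
  # samples per window first, then halve: robust to floating jitter in the
  # estimated rate (a 1-s window at 25 Hz is exactly 25 samples, half = 12)
  half <- if (n == 1 || is.na(rate)) 0L else
    max(0L, round(window * rate) %/% 2L)
  if (n > 1 && 2 * half + 1 > 2 * n) stop("window longer than trace")
  for (ax in c("surge", "sway", "heave")) {
    st <- moving_mean(trace[[ax]], half)
    trace[[paste0("static_", ax)]] <- st
    trace[[paste0("dyn_", ax)]] <- trace[[ax]] - st
  }
  trace
}

#' Body pitch and roll from static acceleration
#'
#' Pitch is the angle of the surge axis against the gravity plane,
#' `atan2(static_surge, sqrt(static_sway^2 + static_heave^2))`; roll is
#' `atan2(static_sway, static_heave)`.  Both are returned in degrees in
#' (-180, 180].  A zero static vector has no defined posture and yields NA
#' rather than an error.
#'
#' @param static_surge,static_sway,static_heave static components in g.
#' @return list with numeric vectors `pitch` and `roll` (degrees).
#' @export
body_angles <- function(static_surge, static_sway, static_heave) {
  deg <- 180 / pi
  zero <- static_surge == 0 & static_sway == 0 & static_heave == 0
  pitch <- atan2(static_surge, sqrt(static_sway^2 + static_heave^2)) * deg
  roll <- atan2(static_sway, static_heave) * deg
  pitch[zero] <- NA_real_
  roll[zero] <- NA_real_
  list(pitch = pitch, roll = roll)
}

#' Vectorial dynamic and static body acceleration
#'
#' VeDBA is the Euclidean norm of the three dynamic components (movement
#' intensity); VeSBA the norm of the three static components (close to 1 g
#' when the bird is stationary or in linear motion, above 1 g in banked
#' turns).
#'
#' @param dx,dy,dz dynamic surge/sway/heave in g.
#' @param sx,sy,sz static surge/sway/heave in g.
#' @return list with vectors `vedba` and `vesba` (g).
#' @export
vedba_vesba <- function(dx, dy, dz, sx, sy, sz) {
  list(vedba = sqrt(dx^2 + dy^2 + dz^2), vesba = sqrt(sx^2 + sy^2 + sz^2))
}

#' Detect wingbeats in the heave channel
#'
#' Candidate wingbeats are local maxima of heave with amplitude above
#' `amp_threshold` (measured against the signal itself, i.e. against the
#' ~1 g gravity baseline).  Successive candidate peaks closer together than
#' `1 / min_rate` seconds chain into a bout; only bouts with at least
#' `min_successive` peaks are retained, and each retained peak flags one
#' wingbeat.
#'
#' @param heave heave acceleration in g.
#' @param rate sampling rate in Hz (must satisfy `rate >= 2 * min_rate`).
#' @param amp_threshold amplitude threshold in g (default 1).
#' @param min_rate minimum within-bout peak rate in Hz (default 4, i.e.
#'   inter-peak interval at most 0.25 s).
#' @param min_successive minimum number of successive peaks per bout
#'   (default 2).
#' @return list: `flags` (logical per sample), `n_wingbeats`, and `bouts`
#'   (data frame of bout start/end sample indices and peak counts).
#' @export
detect_wingbeats <- function(heave, rate, amp_threshold = 1, min_rate = 4,
                             min_successive = 2) {
  if (rate < 2 * min_rate)
    stop("sampling rate below Nyquist for the requested wingbeat rate")
  n <- length(heave)
  flags <- logical(n)
  empty <- data.frame(start = integer(0), end = integer(0), n_peaks = integer(0))
  if (n < 3) return(list(flags = flags, n_wingbeats = 0L, bouts = empty))
  pk <- pracma::findpeaks(heave, minpeakheight = amp_threshold)
  if (is.null(pk) || nrow(pk) == 0)
    return(list(flags = flags, n_wingbeats = 0L, bouts = empty))
  idx <- sort(pk[, 2])
  gap_ok <- diff(idx) / rate <= 1 / min_rate
  grp <- cumsum(c(TRUE, !gap_ok))
  keep <- ave(idx, grp, FUN = length) >= min_successive
  kept <- idx[keep]
  flags[kept] <- TRUE
  if (length(kept) == 0)
    return(list(flags = flags, n_wingbeats = 0L, bouts = empty))
  kg <- grp[keep]
  bouts <- data.frame(
    start = tapply(kept, kg, min),
    end = tapply(kept, kg, max),
    n_peaks = as.integer(tapply(kept, kg, length))
  )
  rownames(bouts) <- NULL
  list(flags = flags, n_wingbeats = sum(flags), bouts = bouts)
}

#' Compute the full per-sample metric series
#'
#' Composes [decompose()], [body_angles()], [vedba_vesba()] and
#' [detect_wingbeats()] into the 12-channel metric series used throughout the
#' package: raw axes, dynamic axes, pitch, roll, VeSBA, VeDBA, wingbeat flags
#' and temperature.  All smoothed quantities use the same `window`.
#'
#' @param trace an `accel_trace`.
#' @param window static-component smoothing window in seconds (default 1).
#' @param wingbeat_args optional list of overrides passed to
#'   [detect_wingbeats()] (`amp_threshold`, `min_rate`, `min_successive`).
#' @param wingbeat_channel channel used for wingbeat peaks: `"heave"` (raw,
#'   the default) or `"dyn_heave"`.
#' @return a `data.frame` of class `metric_series`, one row per input sample.
#' @export
compute_metrics <- function(trace, window = 1, wingbeat_args = list(),
                            wingbeat_channel = c("heave", "dyn_heave")) {
  wingbeat_channel <- match.arg(wingbeat_channel)
  m <- decompose(trace, window = window)
  ang <- body_angles(m$static_surge, m$static_sway, m$static_heave)
  m$pitch <- ang$pitch
  m$roll <- ang$roll
  v <- vedba_vesba(m$dyn_surge, m$dyn_sway, m$dyn_heave,
                   m$static_surge, m$static_sway, m$static_heave)
  m$vedba <- v$vedba
  m$vesba <- v$vesba
  rate <- trace_rate(m)
  if (is.na(rate)) {
    m$wingbeat <- FALSE
  } else {
    wb <- do.call(detect_wingbeats,
                  c(list(heave = m[[wingbeat_channel]], rate = rate),
                    wingbeat_args))
    m$wingbeat <- wb$flags
  }
  class(m) <- c("metric_series", "data.frame")
  m
}
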