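# Synthetic tri-axial accelerometer generator.  Nine behaviour classes in
# three modes (burrow, water, flying), each with a parametric signature tuned
# so that the derived metrics (VeDBA, VeSBA, pitch/roll, wingbeats) reproduce
# the qualitative criteria used to manually classify real petrel data.

#' The nine-class behaviour taxonomy
#'
#' @return data frame with `class` and `mode` columns; the six non-burrow
#'   classes form the "at-sea" set.
#' @export
behaviour_classes <- function() {
  data.frame(
    class = c("burrow-still", "burrow-stirring", "burrow-active",
              "water-inactive", "water-active", "water-intensive",
              "flying-dynamic-soaring", "flying-flap-glide",
              "flying-intensive"),
    mode = c("burrow", "burrow", "burrow",
             "water", "water", "water",
             "flying", "flying", "flying"),
    stringsAsFactors = FALSE
  )
}

#' At-sea behaviour classes
#' @return character vector of the six non-burrow classes.
#' @export
at_sea_classes <- function() {
  bc <- behaviour_classes()
  bc$class[bc$mode != "burrow"]
}

#' Collapse nine behaviour classes to three activity modes
#'
#' Fixed many-to-one mapping burrow/water/flying.
#'
#' @param labels character or factor vector of class labels.
#' @return character vector of modes.
#' @export
collapse_modes <- function(labels) {
  bc <- behaviour_classes()
  labels <- as.character(labels)
  bad <- !labels %in% bc$class
  if (any(bad)) stop("unknown behaviour class: ", labels[bad][1])
  bc$mode[match(labels, bc$class)]
}

# Smooth pseudo-random drift: a sum of three low-frequency sinusoids with
# random phases.  Locally monotone between true crests, so it never injects
# spurious sample-scale local maxima into the heave channel (which would be
# picked up as wingbeats).
smooth_wander <- function(t, amp, base_freq) {
  if (amp <= 0) return(rep(0, length(t)))
  f <- base_freq * c(1, 1 / 1.73, 1 / 3.1)
  a <- amp * c(0.55, 0.3, 0.15)
  ph <- runif(3, 0, 2 * pi)
  a[1] * sin(2 * pi * f[1] * t + ph[1]) +
    a[2] * sin(2 * pi * f[2] * t + ph[2]) +
    a[3] * sin(2 * pi * f[3] * t + ph[3])
}

#' Default class signatures
#'
#' Generative parameters per behaviour class.  The defaults are hand-tuned so
#' that traces passed through [compute_metrics()] satisfy the qualitative
#' movement criteria of each class (e.g. flap-glide flight contains wingbeat
#' bouts with heave peaks above 2 g; burrow-still shows virtually no axis
#' variation and high temperature).  Fields:
#' `pitch0`/`roll0` resting posture (deg); `orient_osc` deterministic posture
#' oscillation (amps in deg, freq in Hz); `wander` smooth posture drift
#' (amp deg, freq Hz); `norm_osc` gravity-norm oscillation driving VeSBA
#' fluctuation (amp g, freq Hz); `heave_osc`/`surge_osc` additive axis
#' oscillations (amp g, freq Hz); `noise_sd` white noise per axis (g;
#' flying classes use none on heave); `wingbeat` bout parameters (freq Hz,
#' amp g, period_s between bout starts, bout_len_s) or NULL; `temp_mean`,
#' `temp_sd` (deg C).
#'
#' @return named list of signature lists, one per behaviour class.
#' @export
default_signatures <- function() {
  sig <- function(pitch0 = 0, roll0 = 0,
                  orient_osc = list(pitch_amp = 0, roll_amp = 0, freq = 0.2),
                  wander = list(amp = 0, freq = 0.1),
                  norm_osc = list(amp = 0, freq = 0.25),
                  heave_osc = list(amp = 0, freq = 0.35),
                  surge_osc = list(amp = 0, freq = 3),
                  noise_sd = c(0.01, 0.01, 0.01),
                  wingbeat = NULL,
                  temp_mean = 18, temp_sd = 0.4) {
    list(pitch0 = pitch0, roll0 = roll0, orient_osc = orient_osc,
         wander = wander, norm_osc = norm_osc, heave_osc = heave_osc,
         surge_osc = surge_osc, noise_sd = noise_sd, wingbeat = wingbeat,
         temp_mean = temp_mean, temp_sd = temp_sd)
  }
  list(
    # resting posture keeps raw heave below the 1 g wingbeat threshold
    "burrow-still" = sig(pitch0 = -12, roll0 = 15,
                         noise_sd = c(0.008, 0.008, 0.008),
                         temp_mean = 28, temp_sd = 0.3),
    "burrow-stirring" = sig(pitch0 = -8, roll0 = 10,
                            orient_osc = list(pitch_amp = 3, roll_amp = 3,
                                              freq = 0.3),
                            noise_sd = c(0.12, 0.12, 0.12),
                            temp_mean = 28, temp_sd = 0.3),
    "burrow-active" = sig(pitch0 = -5, roll0 = 5,
                          orient_osc = list(pitch_amp = 12, roll_amp = 12,
                                            freq = 0.15),
                          wander = list(amp = 6, freq = 0.1),
                          noise_sd = c(0.35, 0.35, 0.35),
                          temp_mean = 28, temp_sd = 0.3),
    "water-inactive" = sig(pitch0 = -5, roll0 = 8,
                           orient_osc = list(pitch_amp = 2, roll_amp = 3,
                                             freq = 0.25),
                           noise_sd = c(0.03, 0.03, 0.03)),
    "water-active" = sig(pitch0 = -3, roll0 = 0,
                         orient_osc = list(pitch_amp = 10, roll_amp = 8,
                                           freq = 0.4),
                         wander = list(amp = 3, freq = 0.1),
                         noise_sd = c(0.18, 0.18, 0.18)),
    "water-intensive" = sig(pitch0 = 0, roll0 = 0,
                            orient_osc = list(pitch_amp = 15, roll_amp = 40,
                                              freq = 0.15),
                            wander = list(amp = 8, freq = 0.12),
                            surge_osc = list(amp = 1.2, freq = 3),
                            noise_sd = c(0.5, 0.5, 0.5)),
    "flying-dynamic-soaring" = sig(pitch0 = 0, roll0 = 0,
                                   orient_osc = list(pitch_amp = 5,
                                                     roll_amp = 25,
                                                     freq = 0.12),
                                   wander = list(amp = 4, freq = 0.08),
                                   norm_osc = list(amp = 0.85, freq = 0.25),
                                   heave_osc = list(amp = 0.6, freq = 0.35),
                                   noise_sd = c(0.25, 0.25, 0)),
    "flying-flap-glide" = sig(pitch0 = 0, roll0 = 0,
                              orient_osc = list(pitch_amp = 4, roll_amp = 15,
                                                freq = 0.15),
                              wander = list(amp = 3, freq = 0.08),
                              norm_osc = list(amp = 0.65, freq = 0.3),
                              heave_osc = list(amp = 0.45, freq = 0.4),
                              wingbeat = list(freq = 6, amp = 1.5,
                                              period_s = 7.5,
                                              bout_len_s = 0.9),
                              noise_sd = c(0.25, 0.25, 0)),
    "flying-intensive" = sig(pitch0 = 0, roll0 = 0,
                             orient_osc = list(pitch_amp = 10, roll_amp = 20,
                                               freq = 0.3),
                             wander = list(amp = 8, freq = 0.15),
                             norm_osc = list(amp = 0.7, freq = 0.3),
                             heave_osc = list(amp = 0.4, freq = 0.4),
                             wingbeat = list(freq = 6.5, amp = 2.2,
                                             period_s = 12,
                                             bout_len_s = 5),
                             noise_sd = c(0.45, 0.45, 0))
  )
}

#' Generate a synthetic accelerometer trace for one behaviour class
#'
#' The signal model is: a gravity vector oriented by slowly varying pitch and
#' roll, scaled by an optional norm oscillation (producing VeSBA
#' fluctuations), plus deterministic axis oscillations, a wingbeat pulse
#' train on heave, and white noise.  Flying-class heave carries no white
#' noise so that wingbeat peaks are the only sample-scale local maxima above
#' the detection threshold.
#'
#' @param class one of [behaviour_classes()]`$class`.
#' @param sig signature list (default from [default_signatures()]).
#' @param duration seconds (>= 1).
#' @param rate sampling rate in Hz (default 25).
#' @param seed integer seed; the trace is fully reproducible.
#' @param t0 start time (numeric seconds or POSIXct), default 0.
#' @return an [accel_trace()].
#' @export
gen_accel <- function(class, sig = NULL, duration, rate = 25, seed = 1,
                      t0 = 0) {
  bc <- behaviour_classes()
  if (!class %in% bc$class) stop("unknown behaviour class: ", class)
  if (duration < 1) stop("duration must be at least 1 s")
  if (rate <= 0) stop("rate must be positive")
  if (is.null(sig)) sig <- default_signatures()[[class]]
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  deg <- pi / 180
  pitch <- sig$pitch0 +
    sig$orient_osc$pitch_amp * sin(2 * pi * sig$orient_osc$freq * t +
                                     runif(1, 0, 2 * pi)) +
    smooth_wander(t, sig$wander$amp, sig$wander$freq)
  roll <- sig$roll0 +
    sig$orient_osc$roll_amp * sin(2 * pi * sig$orient_osc$freq * t +
                                    runif(1, 0, 2 * pi)) +
    smooth_wander(t, sig$wander$amp, sig$wander$freq)
  norm <- 1 + sig$norm_osc$amp *
    sin(2 * pi * sig$norm_osc$freq * t + runif(1, 0, 2 * pi))

  # gravity vector in body frame for the given posture
  surge <- norm * sin(pitch * deg)
  sway <- norm * cos(pitch * deg) * sin(roll * deg)
  heave <- norm * cos(pitch * deg) * cos(roll * deg)

  if (sig$heave_osc$amp > 0)
    heave <- heave + sig$heave_osc$amp *
      sin(2 * pi * sig$heave_osc$freq * t + runif(1, 0, 2 * pi))
  if (sig$surge_osc$amp > 0)
    surge <- surge + sig$surge_osc$amp *
      sin(2 * pi * sig$surge_osc$freq * t + runif(1, 0, 2 * pi))

  if (!is.null(sig$wingbeat)) {
    wb <- sig$wingbeat
    starts <- seq(min(runif(1, 0, wb$period_s / 2), duration / 3),
                  duration, by = wb$period_s)
    lens <- pmax(wb$bout_len_s + rnorm(length(starts), 0, wb$bout_len_s / 8),
                 2.5 / wb$freq)
    in_bout <- rep(FALSE, n)
    for (i in seq_along(starts)) {
      sel <- t >= starts[i] & t < starts[i] + lens[i]
      in_bout[sel] <- TRUE
    }
    pulse <- wb$amp * pmax(sin(2 * pi * wb$freq * t), 0)
    heave <- heave + ifelse(in_bout, pulse, 0)
  }

  surge <- surge + rnorm(n, 0, sig$noise_sd[1])
  sway <- sway + rnorm(n, 0, sig$noise_sd[2])
  if (sig$noise_sd[3] > 0) heave <- heave + rnorm(n, 0, sig$noise_sd[3])

  temp <- sig$temp_mean + smooth_wander(t, sig$temp_sd, 0.05) +
    rnorm(n, 0, sig$temp_sd / 10)

  accel_trace(time = t0 + t, surge = surge, sway = sway, heave = heave,
              temp = temp)
}

# save/restore the RNG state so generators are reproducible without
# clobbering the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Check a metric window against its class's movement criteria
#'
#' Evaluates the quantitative part of the manual-classification criteria for
#' one behaviour class on a (typically 15-s) window of [compute_metrics()]
#' output: VeDBA levels, VeSBA fluctuation, heave peaks, posture excursions,
#' wingbeat bouts and burrow temperature.
#'
#' @param metrics a `metric_series` window.
#' @param class behaviour class name.
#' @param rate sampling rate in Hz (default inferred from the window).
#' @return logical: does the window satisfy the class criteria?
#' @export
class_criteria <- function(metrics, class, rate = NULL) {
  if (is.null(rate)) rate <- trace_rate(metrics)
  wb <- detect_wingbeats(metrics$heave, rate)
  rng <- function(x) diff(range(x))
  warm <- mean(metrics$temp) > 24
  switch(class,
    "burrow-still" = warm && mean(metrics$vedba) < 0.05 &&
      IQR(metrics$surge) < 0.05 && IQR(metrics$sway) < 0.05 &&
      IQR(metrics$heave) < 0.05,
    "burrow-stirring" = warm && max(metrics$vedba) < 1 &&
      mean(metrics$vedba) >= 0.02,
    "burrow-active" = warm && max(metrics$vedba) > 1 &&
      (rng(metrics$pitch) > 10 || rng(metrics$roll) > 10),
    "water-inactive" = !warm && mean(metrics$vedba) < 0.1 &&
      IQR(metrics$vesba) < 0.1,
    "water-active" = !warm && mean(metrics$vedba) > 0.1 &&
      mean(metrics$vedba) < 1 && IQR(metrics$vesba) < 0.15 &&
      (rng(metrics$pitch) > 10 || rng(metrics$roll) > 10),
    "water-intensive" = !warm && mean(metrics$vedba) > 1 &&
      max(metrics$vedba) > 2 && max(metrics$vesba) < 1.5 &&
      (rng(metrics$pitch) > 50 || rng(metrics$roll) > 50),
    "flying-dynamic-soaring" = !warm && max(metrics$vesba) > 1.5 &&
      max(metrics$heave) > 2 && nrow(wb$bouts) == 0,
    "flying-flap-glide" = !warm && max(metrics$vesba) > 1.5 &&
      max(metrics$heave) > 2 && any(wb$bouts$n_peaks >= 3),
    "flying-intensive" = !warm && max(metrics$vesba) > 1.5 &&
      max(metrics$heave) > 3 && wb$n_wingbeats >= 20,
    stop("unknown behaviour class: ", class)
  )
}
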