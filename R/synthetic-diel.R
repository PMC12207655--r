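# Synthetic diel behaviour sequences: hourly class budgets drawn from
# per-class zero-inflated beta generators modulated by sun angle, realised
# as per-second bout sequences.

#' Construct a diel behaviour generator
#'
#' Houses the generating analogues of the fitted diel model: for each of the
#' six at-sea classes, zero-inflation and conditional coefficients on the
#' logit scale with sun angle (radians) as the covariate, plus a common beta
#' precision.  The defaults are the coefficients estimated for incubating
#' Bermuda petrels (flight classes more likely and longer at night, water
#' classes during the day), which reproduce the observed activity budget of
#' roughly 80% of at-sea time in flight, dominated by dynamic soaring.
#'
#' @param coefs data frame with columns `class`, `zi_int`, `zi_slope`,
#'   `cond_int`, `cond_slope`; one row per at-sea class.  Default: the
#'   petrel estimates.
#' @param phi beta precision (> 0), default 10.
#' @param bout_len_s mean within-hour bout length in seconds (default 90).
#' @return object of class `diel_generator`.
#' @export
diel_generator <- function(coefs = NULL, phi = 10, bout_len_s = 90) {
  if (is.null(coefs)) {
    coefs <- data.frame(
      class = c("water-inactive", "water-active", "water-intensive",
                "flying-intensive", "flying-flap-glide",
                "flying-dynamic-soaring"),
      zi_int = c(0.72, -1.3, -1.66, -0.05, -3.7, -2.9),
      zi_slope = c(-1.26, -1.2, -0.81, -0.003, 1.2, 1.0),
      cond_int = c(-1.40, -1.99, -2.84, -4.15, -1.53, 0.003),
      cond_slope = c(0.57, 0.82, 0.14, -0.12, -0.92, -0.39),
      stringsAsFactors = FALSE
    )
  }
  if (!setequal(coefs$class, at_sea_classes()))
    stop("coefs must cover exactly the six at-sea classes")
  if (phi <= 0) stop("precision must be positive")
  structure(list(coefs = coefs, phi = phi, bout_len_s = bout_len_s),
            class = "diel_generator")
}

#' Generate a per-second at-sea behaviour sequence
#'
#' For each clock hour, the generator draws each class's share of the hour
#' from its zero-inflated beta analogue evaluated at the hour-midpoint sun
#' angle, renormalises the shares to sum to 1 (zeros stay zero, so each
#' class's hourly occurrence follows its zero-inflation submodel exactly),
#' and lays the shares out as shuffled bouts of mean length `bout_len_s`.
#' An hour in which every class draws zero is assigned entirely to
#' dynamic-soaring flight.
#'
#' @param gen a [diel_generator()].
#' @param start start time (POSIXct UTC or numeric seconds), aligned to an
#'   hour boundary internally.
#' @param duration_h duration in hours.
#' @param colony `c(lon, lat)` used for sun angle.
#' @param seed integer seed.
#' @return data frame: `time` (per second), `class` (factor over the at-sea
#'   classes).
#' @export
gen_diel_sequence <- function(gen, start, duration_h, colony, seed = 1) {
  stopifnot(inherits(gen, "diel_generator"))
  if (duration_h <= 0) stop("duration must be positive")
  t0 <- floor(as.numeric(start) / 3600) * 3600
  n_hours <- ceiling(duration_h)
  classes <- gen$coefs$class
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  labs <- vector("list", n_hours)
  soar <- match("flying-dynamic-soaring", classes)
  for (h in seq_len(n_hours)) {
    hs <- t0 + (h - 1) * 3600
    x <- sun_angle(colony[2], colony[1], hs + 1800)
    w <- simulate_zib(rep(x, length(classes)),
                      gen$coefs$zi_int, gen$coefs$zi_slope,
                      gen$coefs$cond_int, gen$coefs$cond_slope, gen$phi)
    if (all(w == 0)) w[soar] <- 1
    secs <- round(3600 * w / sum(w))
    # fix rounding so the hour is exactly covered
    delta <- 3600 - sum(secs)
    secs[which.max(secs)] <- secs[which.max(secs)] + delta
    # split each class's allocation into bouts and shuffle the bout order
    bouts_cl <- integer(0); bouts_len <- integer(0)
    for (k in seq_along(classes)) {
      if (secs[k] == 0) next
      nb <- max(1L, round(secs[k] / gen$bout_len_s))
      cuts <- diff(round(seq(0, secs[k], length.out = nb + 1)))
      cuts <- cuts[cuts > 0]
      bouts_cl <- c(bouts_cl, rep(k, length(cuts)))
      bouts_len <- c(bouts_len, cuts)
    }
    ord <- sample.int(length(bouts_cl))
    labs[[h]] <- rep(bouts_cl[ord], bouts_len[ord])
  }
  lab <- unlist(labs)
  lab <- lab[seq_len(min(length(lab), round(duration_h * 3600)))]
  data.frame(time = t0 + seq_along(lab) - 1,
             class = factor(classes[lab], levels = classes))
}
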