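# Independent oracles used to cross-check the package implementations.
# Each is written from first principles (loops, sorting, closed forms) and
# shares no code with the functions it checks.

# Cohen's kappa from an explicit double loop over the confusion matrix.
kappa_oracle <- function(cm) {
  n <- sum(cm)
  po <- 0
  for (i in seq_len(nrow(cm))) po <- po + cm[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(cm))) {
    row_i <- 0; col_i <- 0
    for (j in seq_len(ncol(cm))) {
      row_i <- row_i + cm[i, j]
      col_i <- col_i + cm[j, i]
    }
    pe <- pe + (row_i / n) * (col_i / n)
  }
  (po - pe) / (1 - pe)
}

# One-vs-rest balanced accuracy by counting samples directly.
balanced_acc_oracle <- function(pred, truth, cls) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(pred)) {
    if (truth[i] == cls) {
      if (pred[i] == cls) tp <- tp + 1 else fn <- fn + 1
    } else {
      if (pred[i] == cls) fp <- fp + 1 else tn <- tn + 1
    }
  }
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

# Brute-force wingbeat counter: strict local maxima above a threshold,
# chained when closer than 1/min_rate seconds, bouts of >= min_successive.
wingbeat_oracle <- function(x, rate, thr = 1, min_rate = 4, min_succ = 2) {
  peaks <- integer(0)
  for (i in 2:(length(x) - 1))
    if (x[i] > x[i - 1] && x[i] > x[i + 1] && x[i] > thr)
      peaks <- c(peaks, i)
  if (length(peaks) == 0) return(0L)
  count <- 0L
  run <- 1L
  for (k in seq_along(peaks)[-1]) {
    if ((peaks[k] - peaks[k - 1]) / rate <= 1 / min_rate) {
      run <- run + 1L
    } else {
      if (run >= min_succ) count <- count + run
      run <- 1L
    }
  }
  if (run >= min_succ) count <- count + run
  count
}

# Naive rolling quantile: explicit window extraction per sample.
rolling_quantile_oracle <- function(x, width, prob) {
  n <- length(x)
  half <- (width - 1) %/% 2
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    quantile(w, prob, names = FALSE)
  }, 0)
}

# Sort-based quantile with linear interpolation between order statistics.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Gravity vector in the body frame for a given posture (forward model used
# to check the pitch/roll inversion).
gravity_vec <- function(pitch_deg, roll_deg, norm = 1) {
  p <- pitch_deg * pi / 180; r <- roll_deg * pi / 180
  norm * c(sin(p), cos(p) * sin(r), cos(p) * cos(r))
}

# Astronomical-Almanac (Michalsky-style) solar elevation, independent of the
# package's NOAA-style routine.
solar_oracle <- function(lat, lon, time) {
  t <- as.numeric(time); deg <- pi / 180
  n <- t / 86400 + 2440587.5 - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- L + 1.915 * sin(g * deg) + 0.020 * sin(2 * g * deg)
  eps <- 23.439 - 0.0000004 * n
  decl <- asin(sin(eps * deg) * sin(lam * deg))
  ra <- atan2(cos(eps * deg) * sin(lam * deg), cos(lam * deg)) / deg
  ut <- (t %% 86400) / 3600
  gmst <- (6.697375 + 0.0657098242 * (n - ut / 24) +
             1.00273790935 * ut) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- (lmst * 15 - ra + 180) %% 360 - 180
  asin(sin(lat * deg) * sin(decl) + cos(lat * deg) * cos(decl) *
         cos(ha * deg))
}

# Spherical law of cosines distance (km), alternative to the haversine.
slc_km <- function(a, b) {
  deg <- pi / 180
  6371.0088 * acos(pmin(1, sin(a[2] * deg) * sin(b[2] * deg) +
    cos(a[2] * deg) * cos(b[2] * deg) * cos((b[1] - a[1]) * deg)))
}

# Two-stage zero-inflated-beta fit: Bernoulli GLM for the zero part plus a
# separate beta ML for the positive part; with no shared parameters the
# joint ML log-likelihood must equal the sum.
two_stage_zib_loglik <- function(y, x) {
  z <- as.numeric(y == 0)
  gfit <- glm(z ~ x, family = binomial())
  pos <- y > 0
  nll <- function(par) {
    mu <- plogis(par[1] + par[2] * x[pos])
    phi <- exp(par[3])
    -sum(dbeta(y[pos], mu * phi, (1 - mu) * phi, log = TRUE))
  }
  o <- optim(c(qlogis(mean(y[pos])), 0, log(5)), nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-12))
  as.numeric(logLik(gfit)) - o$value
}
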