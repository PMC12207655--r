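# Full synthetic logger deployments: time-aligned accelerometer, depth and
# GPS streams with per-second truth labels, plus fast generators for
# labelled training segments.

#' Generate labelled training segments
#'
#' Draws balanced 15-s labelled segments across behaviour classes by
#' generating one long trace per class per bird, computing metrics and
#' featurising.  This is the training-set design used for supervised
#' classification (e.g. 400 segments per bird across 11 birds gives 4400).
#'
#' @param n_per_bird segments per bird (default 400), spread as evenly as
#'   possible over `classes`.
#' @param n_birds number of synthetic birds (default 1).
#' @param classes behaviour classes to include (default all nine).
#' @param seed integer seed.
#' @param rate sampling rate in Hz (default 25).
#' @return labelled segment data frame (see [featurize_segments()]).
#' @export
gen_labelled_segments <- function(n_per_bird = 400, n_birds = 1,
                                  classes = behaviour_classes()$class,
                                  seed = 1, rate = 25) {
  out <- vector("list", n_birds * length(classes))
  k <- 0
  for (b in seq_len(n_birds)) {
    counts <- table(factor(rep_len(classes, n_per_bird), levels = classes))
    for (cl in classes) {
      nseg <- counts[[cl]]
      if (nseg == 0) next
      s <- stream_seed(seed + 7 * b, "accel") + match(cl, classes)
      tr <- gen_accel(cl, duration = nseg * 15, rate = rate, seed = s)
      m <- compute_metrics(tr)
      f <- featurize_segments(m, length = 15,
                              bird = sprintf("bird_%02d", b),
                              labels = rep(cl, nrow(m)))
      k <- k + 1
      out[[k]] <- f
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Default deployment configuration
#'
#' @param n_birds number of birds (default 1).
#' @param start deployment start (POSIXct UTC).
#' @param burrow_h hours in the burrow before and after the trip (default 1).
#' @param at_sea_h hours at sea (default 4).
#' @param colony `c(lon, lat)`, default the Bermuda colony.
#' @param max_range_km foraging-trip range (default 300).
#' @param dives data frame of scheduled dives (`start` seconds into the
#'   at-sea phase, `max_depth`, `duration`) or NULL for a small default set.
#' @param drift_max depth-sensor drift bound in metres (default 0.3).
#' @param seed global seed; per-stream sub-seeds derive from it.
#' @return named list.
#' @export
deployment_config <- function(n_birds = 1,
                              start = as.POSIXct("2023-02-01 00:00:00",
                                                 tz = "UTC"),
                              burrow_h = 1, at_sea_h = 4,
                              colony = nonsuch_colony(),
                              max_range_km = 300, dives = NULL,
                              drift_max = 0.3, seed = 7) {
  if (at_sea_h < 0 || burrow_h < 0) stop("inconsistent date ranges")
  if (is.null(dives))
    dives <- data.frame(start = round(at_sea_h * 3600 * c(0.3, 0.55, 0.8)),
                        max_depth = c(0.7, 0.59, 1.2),
                        duration = c(2, 1, 3))
  list(n_birds = n_birds, start = start, burrow_h = burrow_h,
       at_sea_h = at_sea_h, colony = colony, max_range_km = max_range_km,
       dives = dives, drift_max = drift_max, seed = seed)
}

# per-second burrow behaviour sequence: bouts cycling the burrow classes
burrow_sequence <- function(n_sec, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  classes <- c("burrow-still", "burrow-stirring", "burrow-active")
  probs <- c(0.6, 0.25, 0.15)
  lab <- character(0)
  while (length(lab) < n_sec) {
    cl <- sample(classes, 1, prob = probs)
    len <- max(30, round(rgeom(1, 1 / 240)))
    lab <- c(lab, rep(cl, len))
  }
  lab[seq_len(n_sec)]
}

#' Generate a full synthetic logger deployment
#'
#' Builds, for each bird, a time-aligned set of streams: a per-second truth
#' behaviour sequence (burrow phase, at-sea phase from the diel generator,
#' burrow phase), a 25 Hz accelerometer trace generated bout-by-bout from
#' the class signatures, a 1 Hz depth trace with drift and the scheduled
#' dives (during the at-sea phase), and a GPS track looping out from the
#' colony.
#'
#' @param config from [deployment_config()].
#' @return list of class `logger_dataset`: `birds` (per-bird list with
#'   `accel`, `depth`, `gps`, `labels` where `labels` has per-second `time`
#'   and `class`), and `config`.
#' @export
gen_logger_dataset <- function(config = deployment_config()) {
  t0 <- as.numeric(config$start)
  total_h <- 2 * config$burrow_h + config$at_sea_h
  if (nrow(config$dives) > 0 &&
      any(config$dives$start + config$dives$duration >
            config$at_sea_h * 3600))
    stop("scheduled dives fall outside the at-sea phase")
  birds <- list()
  for (b in seq_len(config$n_birds)) {
    seed_b <- config$seed + 1000 * b
    nb <- round(config$burrow_h * 3600)
    ns <- round(config$at_sea_h * 3600)
    lab <- character(nb * 2 + ns)
    lab[seq_len(nb)] <- burrow_sequence(nb, stream_seed(seed_b, "labels"))
    if (ns > 0) {
      sea <- gen_diel_sequence(diel_generator(), start = t0 + nb,
                               duration_h = config$at_sea_h,
                               colony = config$colony,
                               seed = stream_seed(seed_b, "diel"))
      lab[nb + seq_len(ns)] <- as.character(sea$class)
    }
    lab[nb + ns + seq_len(nb)] <- burrow_sequence(
      nb, stream_seed(seed_b, "labels") + 1)
    times <- t0 + seq_along(lab) - 1

    # accelerometer, bout by bout
    r <- rle(lab)
    offs <- c(0, cumsum(r$lengths))
    traces <- vector("list", length(r$values))
    for (i in seq_along(r$values)) {
      traces[[i]] <- gen_accel(r$values[i], duration = r$lengths[i],
                               seed = stream_seed(seed_b, "accel") + i,
                               t0 = t0 + offs[i])
    }
    accel <- do.call(rbind, traces)
    class(accel) <- c("accel_trace", "data.frame")

    depth <- gen_depth(
      dives = transform(config$dives, start = start + nb),
      total_duration = length(lab), drift_max = config$drift_max,
      noise_sd = 0.005, seed = stream_seed(seed_b, "depth"), t0 = t0)

    gps <- if (ns > 0)
      gen_track(config$colony, trip_duration_days = config$at_sea_h / 24,
                max_range_km = config$max_range_km, fix_interval_min = 5,
                seed = stream_seed(seed_b, "gps"), t0 = t0 + nb,
                pad_h = config$burrow_h)
    else data.frame(time = numeric(0), lon = numeric(0), lat = numeric(0))

    birds[[sprintf("bird_%02d", b)]] <-
      list(accel = accel, depth = depth, gps = gps,
           labels = data.frame(time = times, class = lab))
  }
  structure(list(birds = birds, config = config), class = "logger_dataset")
}

# %OS truncates fractional seconds; the half-tick epsilon makes the written
# centisecond exact for the 25 Hz grid
iso_time <- function(t) {
  format(as.POSIXct(as.numeric(t) + 1e-4, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS2Z")
}
parse_time <- function(s)
  as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")

#' Write a logger dataset to the standard CSV layout
#'
#' One directory per bird containing `accel.csv` (timestamp, ax_g, ay_g,
#' az_g, temp_c), `depth.csv` (timestamp, depth_m), `gps.csv` (timestamp,
#' lon, lat) and `labels.csv` (start, end, class; run-length encoded).
#' Timestamps are ISO-8601 UTC; output is deterministic.
#'
#' @param dataset a `logger_dataset`.
#' @param dir output directory.
#' @return invisibly, the per-bird directories written.
#' @export
write_logger_csvs <- function(dataset, dir) {
  dirs <- character(0)
  for (nm in names(dataset$birds)) {
    bd <- file.path(dir, nm)
    dir.create(bd, recursive = TRUE, showWarnings = FALSE)
    b <- dataset$birds[[nm]]
    write.csv(data.frame(timestamp = iso_time(b$accel$time),
                         ax_g = b$accel$surge, ay_g = b$accel$sway,
                         az_g = b$accel$heave, temp_c = b$accel$temp),
              file.path(bd, "accel.csv"), row.names = FALSE, quote = FALSE)
    write.csv(data.frame(timestamp = iso_time(b$depth$time),
                         depth_m = b$depth$depth),
              file.path(bd, "depth.csv"), row.names = FALSE, quote = FALSE)
    write.csv(data.frame(timestamp = iso_time(b$gps$time),
                         lon = b$gps$lon, lat = b$gps$lat),
              file.path(bd, "gps.csv"), row.names = FALSE, quote = FALSE)
    r <- rle(b$labels$class)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    write.csv(data.frame(start = iso_time(b$labels$time[starts]),
                         end = iso_time(b$labels$time[ends] + 1),
                         class = r$values),
              file.path(bd, "labels.csv"), row.names = FALSE, quote = FALSE)
    dirs <- c(dirs, bd)
  }
  invisible(dirs)
}

#' Read logger CSV streams
#'
#' Readers for the standard layouts written by [write_logger_csvs()].
#'
#' @param path CSV file path.
#' @return `read_accel_csv` an [accel_trace()]; `read_depth_csv` a
#'   [depth_trace()]; `read_gps_csv` a track data frame; `read_labels_csv`
#'   a per-second label data frame (`time`, `class`).
#' @export
read_accel_csv <- function(path) {
  d <- read.csv(path, comment.char = "#")
  accel_trace(time = parse_time(d$timestamp), surge = d$ax_g, sway = d$ay_g,
              heave = d$az_g, temp = d$temp_c)
}

#' @rdname read_accel_csv
#' @export
read_depth_csv <- function(path) {
  d <- read.csv(path, comment.char = "#")
  depth_trace(time = parse_time(d$timestamp), depth = d$depth_m)
}

#' @rdname read_accel_csv
#' @export
read_gps_csv <- function(path) {
  d <- read.csv(path, comment.char = "#")
  data.frame(time = parse_time(d$timestamp), lon = d$lon, lat = d$lat)
}

#' @rdname read_accel_csv
#' @export
read_labels_csv <- function(path) {
  d <- read.csv(path, comment.char = "#")
  s <- as.numeric(parse_time(d$start)); e <- as.numeric(parse_time(d$end))
  time <- unlist(mapply(function(a, b) seq(a, b - 1), s, e,
                        SIMPLIFY = FALSE))
  data.frame(time = time, class = rep(d$class, e - s))
}
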