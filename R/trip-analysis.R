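# Central-place foraging trip analysis: great-circle distances, trip
# segmentation around a colony-exclusion radius, long/short classification
# and summary statistics.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km.
#'
#' @param a,b `c(lon, lat)` in decimal degrees, or two-column matrices.
#' @return distance(s) in km.
#' @export
great_circle_km <- function(a, b) {
  chk <- function(p) {
    p <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
    if (any(abs(p[, 1]) > 180) || any(abs(p[, 2]) > 90))
      stop("invalid coordinates")
    p
  }
  geosphere::distHaversine(chk(a), chk(b), r = 6371.0088)
}

#' Segment a GPS track into foraging trips
#'
#' A trip is a maximal run of fixes farther than `exclusion` km from the
#' colony (the exclusion removes on-land positions and near-colony rafting).
#' A trip is complete when it is bracketed by within-exclusion fixes on both
#' sides; duration runs from the first to the last at-sea fix.
#'
#' @param track data frame with `time`, `lon`, `lat` (time-ordered).
#' @param colony `c(lon, lat)`.
#' @param exclusion exclusion radius in km (default 1).
#' @return data frame of trips: `start`, `end`, `duration_days`,
#'   `max_distance_km`, `complete`, `n_fixes`; zero rows when the track never
#'   leaves the exclusion zone.
#' @export
segment_trips <- function(track, colony, exclusion = 1) {
  if (nrow(track) < 2) stop("need at least 2 fixes")
  d <- great_circle_km(cbind(track$lon, track$lat), colony)
  away <- d > exclusion
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0)
    return(data.frame(start = track$time[0], end = track$time[0],
                      duration_days = numeric(0), max_distance_km = numeric(0),
                      complete = logical(0), n_fixes = integer(0)))
  out <- do.call(rbind, lapply(keep, function(i) {
    a <- starts[i]; b <- ends[i]
    data.frame(
      start = track$time[a], end = track$time[b],
      duration_days = (as.numeric(track$time[b]) -
                         as.numeric(track$time[a])) / 86400,
      max_distance_km = max(d[a:b]),
      complete = a > 1 && b < nrow(track),
      n_fixes = b - a + 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Flag long trips
#'
#' @param trips output of [segment_trips()].
#' @param min_duration threshold in days (default 2; separates multi-day
#'   foraging trips from short excursions).
#' @return trips with a logical `long` column appended.
#' @export
classify_long <- function(trips, min_duration = 2) {
  trips$long <- trips$duration_days >= min_duration
  trips
}

#' Summary statistics for complete long trips
#'
#' @param trips trips (typically filtered to complete, long ones).
#' @return list: `n`, `duration_mean_days`, `duration_sd_days`,
#'   `distance_mean_km`, `distance_sd_km`, `sd_defined` (FALSE when fewer
#'   than 2 trips; SDs are then NA, flagged rather than an error).
#' @export
trip_summary <- function(trips) {
  n <- nrow(trips)
  if (n == 0) stop("no trips to summarise")
  list(
    n = n,
    duration_mean_days = mean(trips$duration_days),
    duration_sd_days = if (n >= 2) sd(trips$duration_days) else NA_real_,
    distance_mean_km = mean(trips$max_distance_km),
    distance_sd_km = if (n >= 2) sd(trips$max_distance_km) else NA_real_,
    sd_defined = n >= 2
  )
}

#' Remove fixes near the colony
#'
#' Distribution analyses use only unequivocal foraging positions; this drops
#' every fix within `radius` km of the colony.
#'
#' @param track data frame with `time`, `lon`, `lat`.
#' @param colony `c(lon, lat)`.
#' @param radius exclusion radius in km (default 50).
#' @return list: `track` (filtered), `n_removed`, `n_kept`.
#' @export
exclusion_filter <- function(track, colony, radius = 50) {
  d <- great_circle_km(cbind(track$lon, track$lat), colony)
  keep <- d > radius
  list(track = track[keep, , drop = FALSE], n_removed = sum(!keep),
       n_kept = sum(keep))
}

#' Published incubation foraging-trip metrics
#'
#' Trip-level metrics for Bermuda petrels tracked from Nonsuch Island in the
#' 2023 incubation season, as reported for the deployed GPS and
#' accelerometer loggers: per-trip duration in days, maximum distance from
#' the colony in km (NA for loggers without GPS), and whether the trip was
#' recorded completely.  Shipped as plain CSV under `extdata`.
#'
#' @return data frame with columns `bird`, `tag`, `trip`, `duration_days`,
#'   `max_distance_km`, `complete`.
#' @export
published_trips <- function() {
  path <- system.file("extdata", "incubation_trips_2023.csv",
                      package = "gadflight", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Colony coordinates used throughout the examples
#'
#' Nonsuch Island, Bermuda (32 deg 20 min N, 64 deg 40 min W) as
#' `c(lon, lat)` decimal degrees.
#' @return numeric length-2 vector.
#' @export
nonsuch_colony <- function() c(-64.6667, 32.3333)
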