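# End-to-end orchestration: validated configuration, stage execution with
# timing and warning capture, versioned CSV outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' Validates and assembles every stage parameter with its standard default.
#'
#' @param input_dir directory holding one subdirectory per bird with the
#'   standard CSV streams (see [write_logger_csvs()]).
#' @param output_dir directory for stage outputs (created if needed).
#' @param colony `c(lon, lat)`.
#' @param metric_window static-component window in seconds (default 1).
#' @param segment_length segment length in seconds (default 15).
#' @param zoc_window,zoc_prob zero-offset correction parameters (10 min,
#'   0.10).
#' @param dive_threshold dive definition in metres (default 0.5).
#' @param max_plausible_depth outlier repair threshold in metres (15).
#' @param classifier a [classifier_config()].
#' @param train fit the classifier from the labels streams (default TRUE);
#'   when FALSE a fitted `classifier` object must be supplied via `model`.
#' @param model optional pre-trained `behaviour_classifier`.
#' @param min_coverage hourly-budget at-sea coverage threshold (0.5).
#' @param trip_exclusion_km colony exclusion radius for trips (1).
#' @param long_trip_days long-trip threshold in days (2).
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            colony = nonsuch_colony(),
                            metric_window = 1, segment_length = 15,
                            zoc_window = 10, zoc_prob = 0.10,
                            dive_threshold = 0.5, max_plausible_depth = 15,
                            classifier = classifier_config(),
                            train = TRUE, model = NULL,
                            min_coverage = 0.5, trip_exclusion_km = 1,
                            long_trip_days = 2, seed = 1) {
  if (!dir.exists(input_dir)) stop("missing input directory: ", input_dir)
  stopifnot(metric_window > 0, segment_length > 0, zoc_window > 0,
            zoc_prob > 0, zoc_prob < 1, dive_threshold >= 0)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 colony = colony, metric_window = metric_window,
                 segment_length = segment_length, zoc_window = zoc_window,
                 zoc_prob = zoc_prob, dive_threshold = dive_threshold,
                 max_plausible_depth = max_plausible_depth,
                 classifier = classifier, train = train, model = model,
                 min_coverage = min_coverage,
                 trip_exclusion_km = trip_exclusion_km,
                 long_trip_days = long_trip_days, seed = seed),
            class = "pipeline_config")
}

# hash covers the analysis parameters, not the I/O locations or any
# pre-fitted model object, so reruns on the same data are comparable
config_hash <- function(config) {
  keep <- setdiff(names(config), c("model", "input_dir", "output_dir"))
  raw <- serialize(config[keep], NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% 4294967291)
}

write_output_csv <- function(df, path, version, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gadflight %s config %s", version, hash), con)
  write.csv(df, con, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Reads every bird's streams, computes metrics, segments and features,
#' trains (or applies) the behaviour classifier, detects dives, builds
#' hourly at-sea budgets, fits the diel models, segments foraging trips,
#' writes every stage's CSV output (each carrying the package version and a
#' config hash in its header line) and returns a run manifest.  Degenerate
#' inputs (e.g. burrow-only deployments) produce empty outputs with
#' warnings, not errors.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (also written as `manifest.json`): parameters used,
#'   seeds, package version, per-stage timings, warnings and output files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  version <- as.character(packageVersion("gadflight"))
  hash <- config_hash(config)
  warns <- character(0)
  timings <- list()
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$output_dir, name)
    write_output_csv(df, path, version, hash)
    outputs <<- c(outputs, path)
  }
  note <- function(msg) {
    warns <<- c(warns, msg)
    warning(msg, call. = FALSE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  bird_dirs <- list.dirs(config$input_dir, recursive = FALSE)
  if (length(bird_dirs) == 0) stop("no bird directories in ", config$input_dir)

  segs_all <- list(); dives_all <- list(); labels_sec <- list()
  for (bd in bird_dirs) {
    bird <- basename(bd)
    f_acc <- file.path(bd, "accel.csv")
    if (!file.exists(f_acc)) stop("missing input file: ", f_acc)
    accel <- stage(paste0("read_", bird), read_accel_csv(f_acc))
    metrics <- stage(paste0("metrics_", bird),
                     compute_metrics(accel, window = config$metric_window))
    lab_file <- file.path(bd, "labels.csv")
    lab <- if (file.exists(lab_file)) read_labels_csv(lab_file) else NULL
    persec <- if (!is.null(lab))
      lab$class[match(floor(as.numeric(metrics$time)), lab$time)] else NULL
    segs <- stage(paste0("segment_", bird),
                  featurize_segments(metrics, length = config$segment_length,
                                     bird = bird, labels = persec))
    segs_all[[bird]] <- segs

    f_dep <- file.path(bd, "depth.csv")
    if (file.exists(f_dep)) {
      dp <- stage(paste0("dives_", bird),
                  process_depth(read_depth_csv(f_dep),
                                max_plausible = config$max_plausible_depth,
                                window = config$zoc_window,
                                prob = config$zoc_prob,
                                threshold = config$dive_threshold))
      if (nrow(dp$dives) > 0) {
        dp$dives$bird <- bird
        dives_all[[bird]] <- dp$dives
      }
    }
  }
  segments <- do.call(rbind, segs_all)
  rownames(segments) <- NULL
  emit(transform(segments, start = iso_time(start)), "segments.csv")

  # classifier
  model <- config$model
  have_labels <- any(!is.na(segments$label))
  if (config$train && have_labels &&
      length(unique(segments$label[!is.na(segments$label)])) >= 2) {
    model <- stage("train", train_classifier(segments, config$classifier))
    val <- validate_classifier(model)
    emit(val$class_eval$per_class, "validation_per_class.csv")
  } else if (is.null(model)) {
    note("no labels and no pre-trained model: skipping classification")
  }
  predictions <- segments[, c("bird", "start")]
  predictions$predicted <- if (!is.null(model))
    stage("predict", predict(model, segments)) else NA_character_
  emit(transform(predictions, start = iso_time(start)), "predictions.csv")

  dives <- if (length(dives_all) > 0) do.call(rbind, dives_all) else
    data.frame(start = numeric(0), duration_s = numeric(0),
               max_depth_m = numeric(0), mean_depth_m = numeric(0),
               bird = character(0))
  rownames(dives) <- NULL
  emit(transform(dives, start = iso_time(start)), "dives.csv")

  # hourly budgets from predicted labels over at-sea segments
  budgets <- NULL
  if (!is.null(model)) {
    sec <- do.call(rbind, lapply(seq_len(nrow(predictions)), function(i)
      data.frame(bird = predictions$bird[i],
                 time = predictions$start[i] + 0:(config$segment_length - 1),
                 class = predictions$predicted[i])))
    budgets <- stage("budgets",
                     hourly_budget(sec$time, sec$class, config$colony,
                                   bird = sec$bird,
                                   min_coverage = config$min_coverage))
  }
  if (is.null(budgets) || nrow(budgets) == 0) {
    note("no at-sea hours: diel stage skipped")
    emit(data.frame(), "budgets.csv")
    emit(data.frame(), "diel_fits.csv")
  } else {
    emit(transform(budgets, hour_start = iso_time(hour_start)),
         "budgets.csv")
    fits <- list()
    for (cl in at_sea_classes()) {
      y <- budgets[[make.names(cl)]]
      fit <- tryCatch(fit_zib(y, budgets$sun_angle_rad, bird = budgets$bird),
                      error = function(e) NULL)
      if (is.null(fit)) {
        note(paste0("diel fit skipped for ", cl))
        next
      }
      cf <- fit$coefficients
      cf$class <- cl
      cf$converged <- fit$converged
      fits[[cl]] <- cf
    }
    emit(if (length(fits) > 0) do.call(rbind, fits) else data.frame(),
         "diel_fits.csv")
  }

  # trips
  trips <- list()
  for (bd in bird_dirs) {
    f_gps <- file.path(bd, "gps.csv")
    if (!file.exists(f_gps)) next
    gps <- read_gps_csv(f_gps)
    if (nrow(gps) < 2) next
    tr <- stage(paste0("trips_", basename(bd)),
                classify_long(segment_trips(gps, config$colony,
                                            config$trip_exclusion_km),
                              config$long_trip_days))
    if (nrow(tr) > 0) {
      tr$bird <- basename(bd)
      trips[[basename(bd)]] <- tr
    }
  }
  trips <- if (length(trips) > 0) do.call(rbind, trips) else {
    note("no foraging trips found")
    data.frame(start = numeric(0), end = numeric(0),
               duration_days = numeric(0), max_distance_km = numeric(0),
               complete = logical(0), n_fixes = integer(0),
               long = logical(0), bird = character(0))
  }
  rownames(trips) <- NULL
  emit(transform(trips, start = iso_time(start), end = iso_time(end)),
       "trips.csv")

  manifest <- list(
    package = "gadflight", version = version, config_hash = hash,
    seed = config$seed,
    parameters = config[setdiff(names(config), c("model", "classifier"))],
    classifier = unclass(config$classifier),
    n_birds = length(bird_dirs), n_segments = nrow(segments),
    n_dives = nrow(dives), n_trips = nrow(trips),
    selected_features = if (!is.null(model)) model$features else NULL,
    timings = timings, warnings = warns, outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}
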