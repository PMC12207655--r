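# Synthetic generators: class-signature fidelity, depth and track
# generation, diel sequences, full deployments.

test_that("generated traces satisfy their class criteria in >= 95% of windows", {
  for (cl in behaviour_classes()$class) {
    ok <- vapply(1:20, function(i) {
      m <- compute_metrics(gen_accel(cl, duration = 15, seed = 5000 + i))
      isTRUE(class_criteria(m, cl))
    }, TRUE)
    expect_gte(mean(ok), 0.95, label = paste("fidelity for", cl))
  }
})

test_that("the worked accelerometer examples hold", {
  m <- compute_metrics(gen_accel("burrow-still", duration = 15, seed = 1))
  expect_lt(mean(m$vedba), 0.05)
  expect_lt(IQR(m$heave), 0.05)
  expect_equal(sum(m$wingbeat), 0)

  tr <- gen_accel("flying-flap-glide", duration = 60, seed = 1)
  wb <- detect_wingbeats(tr$heave, 25)
  expect_gte(sum(wb$bouts$n_peaks >= 3), 4)

  m <- compute_metrics(gen_accel("water-inactive", duration = 15, seed = 2))
  expect_lt(mean(m$vedba), 0.1)
  expect_true(all(m$vesba >= 0.9 & m$vesba <= 1.1))
})

test_that("the accelerometer generator validates inputs and is deterministic", {
  expect_error(gen_accel("swimming", duration = 10), "unknown")
  expect_error(gen_accel("water-active", duration = 0.5), "duration")
  a <- gen_accel("water-active", duration = 10, seed = 42)
  b <- gen_accel("water-active", duration = 10, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, gen_accel("water-active", duration = 10,
                                      seed = 43)))
  expect_equal(nrow(gen_accel("water-active", duration = 12, rate = 25,
                              seed = 1)), 300)
})

test_that("depth generation schedules recoverable dives", {
  # no dives: nothing above threshold after correction
  tr <- gen_depth(NULL, 3600, drift_max = 0.3, noise_sd = 0.005, seed = 1)
  expect_equal(nrow(process_depth(tr)$dives), 0)

  tr <- gen_depth(data.frame(start = 1800, max_depth = 1.5, duration = 4),
                  3600, drift_max = 0.3, noise_sd = 0.005, seed = 1)
  ev <- process_depth(tr)$dives
  expect_equal(nrow(ev), 1)
  expect_equal(ev$max_depth_m, 1.5, tolerance = 0.1)
  expect_equal(ev$duration_s, 4, tolerance = 1)

  # the sub-threshold dive disappears
  tr <- gen_depth(data.frame(start = c(1800, 5000),
                             max_depth = c(0.6, 0.4), duration = c(1, 1)),
                  7200, drift_max = 0, noise_sd = 0, seed = 3)
  expect_equal(nrow(detect_dives(tr)), 1)

  expect_error(gen_depth(data.frame(start = c(10, 11), max_depth = c(1, 1),
                                    duration = c(5, 5)), 100), "overlap")
  expect_error(gen_depth(data.frame(start = 90, max_depth = 1,
                                    duration = 20), 100), "fit within")
})

test_that("a null diel generator produces no sun-angle trend", {
  g <- diel_generator(coefs = data.frame(
    class = at_sea_classes(), zi_int = -1, zi_slope = 0,
    cond_int = qlogis(1 / 3), cond_slope = 0), phi = 20)
  sq <- gen_diel_sequence(g, as.POSIXct("2023-02-01", tz = "UTC"), 48,
                          nonsuch_colony(), seed = 4)
  b <- hourly_budget(sq$time, sq$class, nonsuch_colony())
  fit <- lm(b[[make.names("water-active")]] ~ b$sun_angle_rad)
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"]), 2 * est["Std. Error"] + 1e-9)
})

test_that("default diel dynamics favour flight at night", {
  sq <- gen_diel_sequence(diel_generator(),
                          as.POSIXct("2023-02-01", tz = "UTC"), 48,
                          nonsuch_colony(), seed = 6)
  sun <- sun_angle(nonsuch_colony()[2], nonsuch_colony()[1], sq$time)
  flying <- collapse_modes(as.character(sq$class)) == "flying"
  expect_gt(mean(flying[sun < 0]), mean(flying[sun > 0]))
})

test_that("diel sequences are reproducible and partition the timeline", {
  g <- diel_generator()
  a <- gen_diel_sequence(g, 0, 6, nonsuch_colony(), seed = 9)
  b <- gen_diel_sequence(g, 0, 6, nonsuch_colony(), seed = 9)
  expect_identical(a, b)
  expect_equal(diff(a$time), rep(1, nrow(a) - 1))
  expect_equal(nrow(a), 6 * 3600)
  expect_error(diel_generator(coefs = data.frame(class = "x", zi_int = 0,
                                                 zi_slope = 0, cond_int = 0,
                                                 cond_slope = 0)),
               "six at-sea")
})

test_that("occurrence modulation in the generator is recovered by the model", {
  # focal-class occurrence slope is preserved exactly by renormalisation
  g <- diel_generator(coefs = data.frame(
    class = at_sea_classes(),
    zi_int = c(0.4, -1, -1.5, -0.5, -3, -3),
    zi_slope = c(-0.8, 0, 0, 0, 0, 0),   # water-inactive is focal
    cond_int = c(-1.5, -2, -2.8, -4, -1.5, 0),
    cond_slope = 0), phi = 10)
  budgets <- do.call(rbind, lapply(1:8, function(b) {
    sq <- gen_diel_sequence(g, as.POSIXct("2023-01-20", tz = "UTC"),
                            14 * 24, nonsuch_colony(), seed = 100 + b)
    hourly_budget(sq$time, sq$class, nonsuch_colony(),
                  bird = paste0("b", b))
  }))
  fit <- fit_zib(budgets[[make.names("water-inactive")]],
                 budgets$sun_angle_rad)
  sl <- fit$coefficients[fit$coefficients$term == "zi_sun_angle", ]
  expect_true(fit$converged)
  expect_lt(abs(sl$estimate - (-0.8)), 3 * sl$se)
})

test_that("generated tracks segment into the configured trip", {
  tk <- gen_track(nonsuch_colony(), 10, 1200, 60, seed = 1)
  tp <- segment_trips(tk, nonsuch_colony())
  expect_equal(nrow(tp), 1)
  expect_true(tp$complete)
  expect_equal(tp$max_distance_km, 1200, tolerance = 0.1 * 1200)
  d_end <- great_circle_km(c(tail(tk$lon, 1), tail(tk$lat, 1)),
                           nonsuch_colony())
  expect_lt(d_end, 1)

  # never leaves the exclusion radius: no trips
  tk0 <- gen_track(nonsuch_colony(), 0.5, 0.5, 60, seed = 1)
  expect_equal(nrow(segment_trips(tk0, nonsuch_colony())), 0)

  # truncated before return: one incomplete trip
  tk_cut <- tk[seq_len(nrow(tk) - 60), ]
  tp_cut <- segment_trips(tk_cut, nonsuch_colony())
  expect_equal(nrow(tp_cut), 1)
  expect_false(tp_cut$complete)

  expect_error(gen_track(nonsuch_colony(), -1, 100), "positive")
})

test_that("full deployments round-trip through the CSV layout byte-identically", {
  cfg <- deployment_config(at_sea_h = 0.5, burrow_h = 0.25, seed = 7,
                           dives = data.frame(start = 600, max_depth = 1,
                                              duration = 2))
  ds <- gen_logger_dataset(cfg)
  b <- ds$birds[[1]]
  # truth labels cover every accelerometer sample with no gaps
  expect_true(all(floor(as.numeric(b$accel$time)) %in% b$labels$time))
  expect_equal(diff(b$labels$time), rep(1, nrow(b$labels) - 1))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_logger_csvs(ds, d1)
  write_logger_csvs(gen_logger_dataset(cfg), d2)
  for (f in c("accel.csv", "depth.csv", "gps.csv", "labels.csv"))
    expect_identical(readLines(file.path(d1, "bird_01", f)),
                     readLines(file.path(d2, "bird_01", f)))

  ac <- read_accel_csv(file.path(d1, "bird_01", "accel.csv"))
  expect_equal(as.numeric(ac$time), as.numeric(b$accel$time))
  expect_equal(ac$surge, b$accel$surge, tolerance = 1e-12)
  lb <- read_labels_csv(file.path(d1, "bird_01", "labels.csv"))
  expect_identical(lb$class, b$labels$class)
  dp <- read_depth_csv(file.path(d1, "bird_01", "depth.csv"))
  expect_equal(dp$depth, b$depth$depth, tolerance = 1e-12)
})

test_that("the labelled training-set design yields 400 segments per bird", {
  segs <- gen_labelled_segments(n_per_bird = 400, n_birds = 11, seed = 17)
  expect_equal(nrow(segs), 4400)
  expect_equal(as.vector(table(segs$bird)), rep(400L, 11))
  # balanced to within one segment per class within each bird
  tab <- table(segs$bird, segs$label)
  expect_true(all(tab >= 44 & tab <= 45))
  feats <- setdiff(names(segs), c("bird", "start", "label"))
  expect_true(all(is.finite(as.matrix(segs[, feats]))))
})
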