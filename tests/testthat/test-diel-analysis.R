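# Solar elevation, hourly budgets and the zero-inflated beta model.

colony <- nonsuch_colony()

test_that("solar elevation matches an independent almanac oracle", {
  # equator at equinox, solar noon
  el <- sun_angle(0, 0, as.POSIXct("2023-03-20 12:07:00", tz = "UTC"))
  expect_lt(abs(el - pi / 2), 0.03)

  t1 <- as.POSIXct("2023-02-01 00:00:00", tz = "UTC")
  expect_lt(abs(sun_angle(colony[2], colony[1], t1) -
                  solar_oracle(colony[2], colony[1], t1)), 0.005)

  tt <- as.POSIXct("2023-01-01", tz = "UTC") + seq(0, 364 * 86400,
                                                   by = 3 * 3600)
  expect_lt(max(abs(sun_angle(colony[2], colony[1], tt) -
                      solar_oracle(colony[2], colony[1], tt))), 0.005)
  expect_error(sun_angle(95, 0, t1), "latitude")
})

test_that("sun angle varies little across the foraging range at sunrise", {
  # ~ sunrise at the colony in February
  t <- as.POSIXct("2023-02-01 11:10:00", tz = "UTC")
  d3 <- abs(sun_angle(colony[2], colony[1], t) -
              sun_angle(colony[2], colony[1] + 3, t))
  d1 <- abs(sun_angle(colony[2], colony[1], t) -
              sun_angle(colony[2], colony[1] + 1, t))
  expect_lt(d3, 0.06)
  expect_lt(d1, d3)
})

test_that("elevation is nearly periodic over one solar day", {
  tt <- as.POSIXct("2023-06-10 00:00:00", tz = "UTC") + (0:23) * 3600
  expect_lt(max(abs(sun_angle(colony[2], colony[1], tt) -
                      sun_angle(colony[2], colony[1], tt + 86400))), 0.01)
})

test_that("hourly budgets partition at-sea time", {
  base <- as.numeric(as.POSIXct("2023-02-01 00:00:00", tz = "UTC"))
  tsec <- base + 0:7199
  lab <- c(rep("flying-dynamic-soaring", 3600),
           rep(c("flying-flap-glide", "water-inactive"), each = 1800))
  b <- hourly_budget(tsec, lab, colony)
  expect_equal(nrow(b), 2)
  expect_equal(b[[make.names("flying-dynamic-soaring")]][1], 1)
  expect_equal(b[[make.names("flying-flap-glide")]][2], 0.5)
  expect_equal(b[[make.names("water-inactive")]][2], 0.5)
  cols <- make.names(at_sea_classes())
  expect_equal(rowSums(b[, cols]), c(1, 1), ignore_attr = TRUE)

  # an hour mostly in the burrow is excluded at 50% coverage
  lab2 <- c(rep("burrow-still", 3000), rep("water-active", 600),
            rep("water-active", 3600))
  b2 <- hourly_budget(tsec, lab2, colony)
  expect_equal(nrow(b2), 1)
  expect_error(hourly_budget(numeric(0), character(0), colony), "empty")
})

test_that("the zero-inflated beta fit recovers generating parameters", {
  set.seed(41)
  x <- runif(2000, -0.5, 0.9)
  y <- simulate_zib(x, zi_int = 0.5, zi_slope = -1.2,
                    cond_int = -1.99, cond_slope = 0.82, phi = 10)
  fit <- fit_zib(y, x)
  expect_true(fit$converged)
  zi <- fit$coefficients[fit$coefficients$term == "zi_sun_angle", ]
  co <- fit$coefficients[fit$coefficients$term == "cond_sun_angle", ]
  expect_lt(abs(zi$estimate - (-1.2)), 3 * zi$se)
  expect_lt(abs(co$estimate - 0.82), 3 * co$se)
  expect_gt(fit$phi, 0)
  expect_error(fit_zib(c(y, 2), c(x, 0)), "outside")
  expect_error(fit_zib(y[1:10], x[1:10]), "30 records")
})

test_that("all-positive data push the zero-inflation mass to zero", {
  set.seed(42)
  x <- runif(500, -0.5, 0.9)
  y <- rbeta(500, 0.4 * 12, 0.6 * 12)
  fit <- fit_zib(y, x)
  zi0 <- fit$coefficients[fit$coefficients$term == "zi_(Intercept)", ]
  co <- fit$coefficients[fit$coefficients$term == "cond_sun_angle", ]
  expect_lt(plogis(zi0$estimate), 0.01)
  expect_lt(abs(co$estimate), 3 * co$se)
  expect_true(fit$degenerate)
})

test_that("joint likelihood equals the two-part fit when nothing is shared", {
  set.seed(43)
  x <- runif(800, -0.5, 0.9)
  y <- simulate_zib(x, 0.2, -1, -1.5, 0.6, 8)
  fit <- fit_zib(y, x)
  expect_equal(fit$loglik, two_stage_zib_loglik(y, x), tolerance = 1e-6)
})

test_that("estimates agree with an established mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(44)
  x <- runif(1500, -0.5, 0.9)
  y <- simulate_zib(x, 0.5, -1.2, -1.99, 0.82, 10)
  ours <- fit_zib(y, x)
  ref <- glmmTMB::glmmTMB(y ~ x, ziformula = ~x,
                          family = glmmTMB::beta_family(),
                          data = data.frame(y = y, x = x))
  rf <- glmmTMB::fixef(ref)
  expect_equal(
    ours$coefficients$estimate[ours$coefficients$term == "cond_(Intercept)"],
    unname(rf$cond[1]), tolerance = 1e-3)
  expect_equal(
    ours$coefficients$estimate[ours$coefficients$term == "cond_sun_angle"],
    unname(rf$cond[2]), tolerance = 1e-3)
  expect_equal(
    ours$coefficients$estimate[ours$coefficients$term == "zi_sun_angle"],
    unname(rf$zi[2]), tolerance = 1e-3)
})

test_that("slope uncertainty shrinks as records accumulate", {
  ses <- vapply(c(200, 2000, 20000), function(n) {
    set.seed(n)
    x <- runif(n, -0.5, 0.9)
    y <- simulate_zib(x, 0.5, -1.2, -1.99, 0.82, 10)
    fit <- fit_zib(y, x)
    co <- fit$coefficients[fit$coefficients$term == "cond_sun_angle", ]
    expect_lt(abs(co$estimate - 0.82), 3 * co$se)
    co$se
  }, 0)
  expect_true(all(diff(ses) < 0))
})

test_that("prediction curves respect the model structure", {
  set.seed(45)
  x <- runif(600, -0.5, 0.9)
  y <- simulate_zib(x, 0.3, 0, -1.2, 0, 10)
  fit <- fit_zib(y, x)
  grid <- seq(-0.5, 0.9, length.out = 20)
  cv <- predict_curves(fit, grid)
  expect_lt(diff(range(cv$occurrence)), 0.08)
  expect_lt(diff(range(cv$conditional)), 0.08)
  expect_equal(cv$product, cv$occurrence * cv$conditional)
  expect_true(all(cv$occurrence_lo <= cv$occurrence &
                    cv$occurrence <= cv$occurrence_hi))

  y2 <- simulate_zib(x, 0.3, -1.5, -1.2, 0, 10)
  cv2 <- predict_curves(fit_zib(y2, x), grid)
  expect_true(all(diff(cv2$occurrence) > 0))
})

test_that("leave-one-bird-out flags an adversarial bird", {
  set.seed(46)
  n_per <- 150
  birds <- rep(paste0("b", 1:5), each = n_per)
  x <- runif(5 * n_per, -0.5, 0.9)
  y <- simulate_zib(x, 0.5, -1.0, -1.8, 0.7, 10)
  # bird 3 gets an inverted relationship
  sel <- birds == "b3"
  y[sel] <- simulate_zib(x[sel], -1.5, 2.5, -0.3, -2.5, 10)
  out <- leave_one_bird_out(y, x, birds)
  expect_equal(nrow(out$deviations), 5)
  worst <- out$deviations$excluded[
    which.max(abs(out$deviations[["cond_sun_angle"]]))]
  expect_equal(worst, "b3")

  # homogeneous birds: small deviations
  y0 <- simulate_zib(x, 0.5, -1.0, -1.8, 0.7, 10)
  out0 <- leave_one_bird_out(y0, x, birds)
  expect_lt(out0$max_abs_deviation, 0.5)
  expect_error(leave_one_bird_out(y0[1:300], x[1:300], birds[1:300]),
               "3 birds")
})
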