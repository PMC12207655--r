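# Segmentation, the 36-feature map, evaluation metrics, mode collapse and
# the training workflow mechanics.

test_that("segmentation drops partial windows and never straddles gaps", {
  t <- (0:(150 * 25 - 1)) / 25
  m <- data.frame(time = t)
  expect_length(segment_windows(m), 10)
  m2 <- data.frame(time = (0:(155 * 25 - 1)) / 25)
  expect_length(segment_windows(m2), 10)
  # two 20-s blocks separated by a 100-s gap: one window each, none across
  tg <- c((0:499) / 25, 200 + (0:499) / 25)
  idx <- segment_windows(data.frame(time = tg))
  expect_length(idx, 2)
  for (i in idx) expect_lt(diff(range(tg[i])), 15.01)
})

test_that("featurisation yields 36 named features with exact statistics", {
  tr <- gen_accel("water-active", duration = 15, seed = 1)
  m <- compute_metrics(tr)
  f <- featurize(m)
  expect_length(f, 36)
  expect_true(all(c("vedba_mean", "vedba_q90", "dyn_sway_mean",
                    "dyn_heave_mean", "heave_iqr", "temp_mean",
                    "wingbeat_sum") %in% names(f)))
  # constant channels: zero IQR, mean equals the constant
  const <- m
  for (ch in c("dyn_surge", "dyn_sway", "dyn_heave", "heave", "pitch",
               "roll", "vedba", "vesba"))
    const[[ch]] <- 0.7
  fc <- featurize(const)
  expect_equal(unname(fc["heave_iqr"]), 0)
  expect_equal(unname(fc["vedba_mean"]), 0.7)
  # wingbeat sum counts flags
  wbm <- m
  wbm$wingbeat <- FALSE
  wbm$wingbeat[1:12] <- TRUE
  expect_equal(unname(featurize(wbm)["wingbeat_sum"]), 12)
  # quantiles match a sort-based oracle
  expect_equal(unname(f["vedba_q10"]), quantile_oracle(m$vedba, 0.1),
               tolerance = 1e-9)
  expect_equal(unname(f["vedba_q90"]), quantile_oracle(m$vedba, 0.9),
               tolerance = 1e-9)
  expect_error(featurize(m[, setdiff(names(m), "vedba")]), "missing")
})

test_that("evaluation reproduces hand-computed accuracy and kappa", {
  p <- c(rep("a", 50), rep("b", 50))
  t <- c(rep("a", 45), rep("b", 5), rep("a", 15), rep("b", 35))
  ev <- evaluate_classification(p, t)
  expect_equal(ev$accuracy, 0.80)
  expect_equal(ev$kappa, 0.60, tolerance = 1e-12)

  perf <- evaluate_classification(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$kappa, 1)
  expect_true(all(perf$per_class$balanced_accuracy == 1))

  # all-one-class predictions on balanced truth: chance agreement
  ev0 <- evaluate_classification(rep("a", 100),
                                 rep(c("a", "b"), 50), classes = c("a", "b"))
  expect_equal(ev0$accuracy, 0.5)
  expect_equal(ev0$kappa, 0)
  expect_error(evaluate_classification("q", "a", classes = c("a", "b")),
               "taxonomy")
})

test_that("kappa and balanced accuracy match brute-force oracles", {
  set.seed(31)
  classes <- letters[1:4]
  for (i in 1:50) {
    n <- 120
    p <- sample(classes, n, replace = TRUE)
    t <- ifelse(runif(n) < 0.6, p, sample(classes, n, replace = TRUE))
    ev <- evaluate_classification(p, t, classes = classes)
    expect_equal(ev$kappa, kappa_oracle(ev$confusion), tolerance = 1e-12)
    for (cl in classes)
      expect_equal(
        ev$per_class$balanced_accuracy[ev$per_class$class == cl],
        balanced_acc_oracle(p, t, cl), tolerance = 1e-12)
  }
})

test_that("evaluation agrees with an established reference implementation", {
  skip_if_not_installed("caret")
  set.seed(12)
  classes <- c("u", "v", "w")
  p <- factor(sample(classes, 300, replace = TRUE), levels = classes)
  t <- factor(ifelse(runif(300) < 0.5, as.character(p),
                     sample(classes, 300, replace = TRUE)), levels = classes)
  ev <- evaluate_classification(as.character(p), as.character(t),
                                classes = classes)
  cm <- caret::confusionMatrix(p, t)
  expect_equal(ev$accuracy, unname(cm$overall["Accuracy"]))
  expect_equal(ev$kappa, unname(cm$overall["Kappa"]), tolerance = 1e-10)
  expect_equal(ev$per_class$balanced_accuracy,
               unname(cm$byClass[, "Balanced Accuracy"]), tolerance = 1e-10)
})

test_that("mode collapse maps classes correctly and never lowers accuracy", {
  expect_equal(collapse_modes("flying-flap-glide"), "flying")
  expect_equal(collapse_modes(c("burrow-still", "water-intensive")),
               c("burrow", "water"))
  expect_error(collapse_modes("unknown-thing"), "unknown")
  set.seed(7)
  cls <- behaviour_classes()$class
  for (i in 1:20) {
    t <- sample(cls, 200, replace = TRUE)
    p <- ifelse(runif(200) < 0.7, t, sample(cls, 200, replace = TRUE))
    acc_c <- evaluate_classification(p, t, classes = cls)$accuracy
    acc_m <- evaluate_classification(collapse_modes(p),
                                     collapse_modes(t))$accuracy
    expect_gte(acc_m, acc_c)
  }
})

test_that("training is deterministic and leak-free", {
  segs <- gen_labelled_segments(n_per_bird = 36,
                                classes = c("burrow-still", "water-active",
                                            "flying-flap-glide",
                                            "flying-dynamic-soaring"),
                                n_birds = 2, seed = 55)
  a <- train_classifier(segs, small_config(seed = 5))
  b <- train_classifier(segs, small_config(seed = 5))
  expect_identical(a$features, b$features)
  expect_identical(predict(a, segs), predict(b, segs))
  # the validation half never appears in training
  expect_length(intersect(a$train_idx,
                          which(!seq_len(nrow(segs)) %in% a$train_idx)), 0)
  expect_equal(sort(c(a$train_idx,
                      as.integer(rownames(a$validation)))),
               seq_len(nrow(segs)))
})

test_that("prediction is invariant to feature column order", {
  segs <- gen_labelled_segments(n_per_bird = 24,
                                classes = c("burrow-still", "water-active",
                                            "flying-flap-glide"),
                                seed = 66)
  clf <- train_classifier(segs, small_config(seed = 3))
  shuffled <- segs[, c("label", sample(setdiff(names(segs), "label")))]
  expect_identical(predict(clf, segs), predict(clf, shuffled))
})

test_that("indistinguishable classes give near-zero kappa, not an error", {
  set.seed(19)
  n <- 60
  feats <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, paste0("f", 1:6)))
  segs <- data.frame(bird = "b1", start = seq_len(n), feats,
                     label = rep(c("p", "q"), each = n / 2))
  clf <- train_classifier(segs, classifier_config(cv_folds = 3,
                                                  cv_repeats = 1,
                                                  grid_size = 3,
                                                  rfe_sizes = c(3, 6),
                                                  tune_trees = 50,
                                                  num_trees = 100, seed = 8))
  ev <- evaluate_classification(predict(clf, clf$validation),
                                clf$validation$label, classes = c("p", "q"))
  expect_lt(abs(ev$kappa), 0.5)
  expect_error(train_classifier(segs[segs$label == "p", ], small_config()),
               "2 classes")
})

test_that("variable importance finds the informative feature", {
  set.seed(23)
  n <- 120
  label <- rep(c("p", "q"), each = n / 2)
  feats <- matrix(rnorm(n * 8), n, 8,
                  dimnames = list(NULL, paste0("f", 1:8)))
  feats[, 3] <- ifelse(label == "p", 0, 3) + rnorm(n, 0, 0.2)
  segs <- data.frame(bird = "b1", start = seq_len(n), feats, label = label)
  cfg <- classifier_config(cv_folds = 3, cv_repeats = 1, grid_size = 3,
                           rfe_sizes = c(4, 8), tune_trees = 50,
                           num_trees = 200, seed = 2)
  clf <- train_classifier(segs, cfg)
  vi <- variable_importance(clf)
  expect_equal(vi$feature[1], "f3")
  expect_equal(vi$importance[1], 100)
  expect_true(all(vi$importance >= 0))

  # a duplicated informative feature shares the signal without crashing
  feats2 <- cbind(feats, f3b = feats[, 3] + rnorm(n, 0, 0.05))
  segs2 <- data.frame(bird = "b1", start = seq_len(n), feats2, label = label)
  clf2 <- train_classifier(segs2, cfg)
  vi2 <- variable_importance(clf2)
  expect_true(all(c("f3", "f3b") %in%
                    vi2$feature[seq_len(min(4, nrow(vi2)))]))
})
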