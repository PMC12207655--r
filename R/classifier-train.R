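# Random-forest training workflow: stratified 50/50 split, within-fold
# up-sampling, repeated-CV random grid search over (min.node.size, mtry,
# splitrule), recursive feature elimination with a 1% kappa rule, and a
# final refit.

#' Classifier training configuration
#'
#' @param split_fraction training share of the labelled data (default 0.5).
#' @param cv_folds,cv_repeats repeated k-fold CV design (default 10 folds,
#'   5 repeats).
#' @param grid_size number of randomly sampled hyperparameter combinations
#'   (default 18) over `min.node.size` 1-20, `mtry` 2-p, splitrule gini or
#'   extratrees.
#' @param rfe_sizes candidate feature-subset sizes for recursive feature
#'   elimination.
#' @param rfe_tolerance relative kappa tolerance for picking the smallest
#'   subset (default 0.01: simplest model within 1% of the best kappa).
#' @param upsample resample minority classes with replacement inside each
#'   training fold so class sizes are even (default TRUE).
#' @param tune_trees,num_trees forest sizes used during tuning/RFE and for
#'   the final refit.
#' @param seed integer seed controlling the split, folds, sampled grid and
#'   forests.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(split_fraction = 0.5, cv_folds = 10,
                              cv_repeats = 5, grid_size = 18,
                              rfe_sizes = c(4, 8, 12, 14, 18, 24, 30, 36),
                              rfe_tolerance = 0.01, upsample = TRUE,
                              tune_trees = 100, num_trees = 500, seed = 1) {
  stopifnot(split_fraction > 0, split_fraction < 1, cv_folds >= 2)
  structure(list(split_fraction = split_fraction, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, grid_size = grid_size,
                 rfe_sizes = rfe_sizes, rfe_tolerance = rfe_tolerance,
                 upsample = upsample, tune_trees = tune_trees,
                 num_trees = num_trees, seed = seed),
            class = "classifier_config")
}

feature_cols <- function(segments)
  setdiff(names(segments), c("bird", "start", "label"))

# even class sizes by resampling with replacement up to the largest class
upsample_idx <- function(labels) {
  tab <- table(labels)
  target <- max(tab)
  unlist(lapply(names(tab), function(cl) {
    i <- which(labels == cl)
    c(i, sample(i, target - length(i), replace = TRUE))
  }), use.names = FALSE)
}

# stratified fold assignment
make_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- sample(which(labels == cl))
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

fit_ranger <- function(x, y, mtry, min_node, splitrule, trees, seed) {
  ranger::ranger(x = x, y = factor(y), num.trees = trees,
                 mtry = min(mtry, ncol(x)), min.node.size = min_node,
                 splitrule = splitrule, respect.unordered.factors = TRUE,
                 num.threads = 1, seed = seed)
}

cv_kappa <- function(x, y, combo, folds_list, upsample, trees, seed) {
  ks <- vapply(folds_list, function(fold) {
    kf <- vapply(sort(unique(fold)), function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      if (upsample) tr <- tr[upsample_idx(y[tr])]
      m <- fit_ranger(x[tr, , drop = FALSE], y[tr], combo$mtry,
                      combo$min_node, combo$splitrule, trees, seed)
      pred <- predict(m, data = x[te, , drop = FALSE])$predictions
      evaluate_classification(as.character(pred), y[te],
                              classes = sort(unique(y)))$kappa
    }, 0)
    mean(kf)
  }, 0)
  mean(ks)
}

#' Train a behaviour classifier
#'
#' Implements the full supervised workflow on labelled 15-s segments:
#' stratified 50/50 train/validation split; random grid search over
#' `grid_size` hyperparameter combinations scored by repeated cross-validated
#' kappa with up-sampling applied inside each training fold only; recursive
#' feature elimination ranking features by permutation importance and
#' keeping the smallest subset whose cross-validated kappa is within
#' `rfe_tolerance` of the best; and a final forest refit on the selected
#' features.  Everything is deterministic given the config seed.
#'
#' @param segments labelled segment data frame from [featurize_segments()]
#'   (non-NA `label`).
#' @param config a [classifier_config()].
#' @return object of class `behaviour_classifier`: `model` (ranger),
#'   `features` (selected), `best_combo`, `tuning` (grid results), `rfe`
#'   (subset-size results), `validation` (held-out segments), `config`.
#' @export
train_classifier <- function(segments, config = classifier_config()) {
  segments <- segments[!is.na(segments$label), , drop = FALSE]
  y_all <- as.character(segments$label)
  classes <- sort(unique(y_all))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(y_all) < 2)) stop("every class needs at least 2 instances")
  feats <- feature_cols(segments)
  x_all <- as.matrix(segments[, feats, drop = FALSE])
  if (any(!is.finite(x_all))) stop("non-finite feature values")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  # stratified split (by class and bird where cell sizes allow)
  strat <- if (length(unique(segments$bird)) > 1 &&
               all(table(y_all, segments$bird) >= 2))
    paste(y_all, segments$bird) else y_all
  tr_idx <- unlist(lapply(unique(strat), function(s) {
    i <- sample(which(strat == s))
    head(i, round(length(i) * config$split_fraction))
  }), use.names = FALSE)
  tr_idx <- sort(tr_idx)
  x <- x_all[tr_idx, , drop = FALSE]; y <- y_all[tr_idx]

  # random hyperparameter grid
  grid <- data.frame(
    min_node = sample(1:20, config$grid_size, replace = TRUE),
    mtry = sample(2:length(feats), config$grid_size, replace = TRUE),
    splitrule = sample(c("gini", "extratrees"), config$grid_size,
                       replace = TRUE)
  )
  grid <- grid[!duplicated(grid), , drop = FALSE]

  folds_list <- lapply(seq_len(config$cv_repeats), function(r)
    make_folds(y, config$cv_folds))
  grid$kappa <- vapply(seq_len(nrow(grid)), function(i)
    cv_kappa(x, y, grid[i, ], folds_list, config$upsample,
             config$tune_trees, config$seed + i), 0)
  best <- grid[which.max(grid$kappa), , drop = FALSE]

  # RFE: rank by permutation importance per fold, refit at each subset size
  sizes <- sort(unique(pmin(config$rfe_sizes, length(feats))))
  rfe_fold <- make_folds(y, config$cv_folds)
  rfe_k <- matrix(NA_real_, nrow = config$cv_folds, ncol = length(sizes))
  for (f in seq_len(config$cv_folds)) {
    tr <- which(rfe_fold != f); te <- which(rfe_fold == f)
    tru <- if (config$upsample) tr[upsample_idx(y[tr])] else tr
    full <- ranger::ranger(x = x[tru, , drop = FALSE], y = factor(y[tru]),
                           num.trees = config$tune_trees,
                           mtry = min(best$mtry, length(feats)),
                           min.node.size = best$min_node,
                           splitrule = best$splitrule,
                           importance = "permutation", num.threads = 1,
                           seed = config$seed + 100 + f)
    rank <- names(sort(full$variable.importance, decreasing = TRUE))
    for (j in seq_along(sizes)) {
      sub <- rank[seq_len(sizes[j])]
      m <- fit_ranger(x[tru, sub, drop = FALSE], y[tru], best$mtry,
                      best$min_node, best$splitrule, config$tune_trees,
                      config$seed + 200 + f)
      pred <- predict(m, data = x[te, sub, drop = FALSE])$predictions
      rfe_k[f, j] <- evaluate_classification(as.character(pred), y[te],
                                             classes = classes)$kappa
    }
  }
  rfe <- data.frame(size = sizes, kappa = colMeans(rfe_k))
  best_k <- max(rfe$kappa)
  chosen_size <- min(rfe$size[rfe$kappa >= best_k * (1 - config$rfe_tolerance)])

  # final importance ranking on the whole training half
  tru <- if (config$upsample) upsample_idx(y) else seq_along(y)
  ranker <- ranger::ranger(x = x[tru, , drop = FALSE], y = factor(y[tru]),
                           num.trees = config$num_trees,
                           mtry = min(best$mtry, length(feats)),
                           min.node.size = best$min_node,
                           splitrule = best$splitrule,
                           importance = "permutation", num.threads = 1,
                           seed = config$seed + 300)
  features <- names(sort(ranker$variable.importance,
                         decreasing = TRUE))[seq_len(chosen_size)]
  final <- ranger::ranger(x = x[tru, features, drop = FALSE],
                          y = factor(y[tru]), num.trees = config$num_trees,
                          mtry = min(best$mtry, chosen_size),
                          min.node.size = best$min_node,
                          splitrule = best$splitrule,
                          importance = "permutation", num.threads = 1,
                          seed = config$seed + 400)
  structure(list(model = final, features = features, best_combo = best,
                 tuning = grid, rfe = rfe,
                 train_idx = tr_idx,
                 validation = segments[-tr_idx, , drop = FALSE],
                 classes = classes, config = config),
            class = "behaviour_classifier")
}

#' Predict behaviour classes for new segments
#'
#' @param object a `behaviour_classifier`.
#' @param newdata segment data frame containing the selected feature columns
#'   (any column order).
#' @param ... unused.
#' @return character vector of predicted classes.
#' @export
predict.behaviour_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  as.character(predict(object$model, data = x)$predictions)
}

#' Validate a classifier on its held-out segments
#'
#' @param clf a `behaviour_classifier`.
#' @param collapse also report the three-mode (burrow/water/flying)
#'   evaluation (default TRUE).
#' @return list: `class_eval` (`eval_report`), and `mode_eval` when
#'   `collapse` is TRUE.
#' @export
validate_classifier <- function(clf, collapse = TRUE) {
  val <- clf$validation
  pred <- predict(clf, val)
  out <- list(class_eval = evaluate_classification(pred, val$label,
                                                   classes = clf$classes))
  if (collapse)
    out$mode_eval <- evaluate_classification(collapse_modes(pred),
                                             collapse_modes(val$label))
  out
}

#' Permutation variable importance, max-scaled to 100
#'
#' @param clf a trained `behaviour_classifier`.
#' @return data frame `feature`, `importance` (descending, max = 100).
#' @export
variable_importance <- function(clf) {
  imp <- clf$model$variable.importance
  if (is.null(imp)) stop("model carries no importance scores")
  imp <- pmax(imp, 0)
  imp <- sort(100 * imp / max(imp), decreasing = TRUE)
  data.frame(feature = names(imp), importance = as.numeric(imp),
             row.names = NULL)
}
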