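# Behaviour classification: 15-s segmentation of the metric series, the
# 36-feature summary map, evaluation metrics (accuracy, Cohen's kappa,
# balanced accuracy), and mode collapse.

#' Split a metric series into fixed-length segments
#'
#' Consecutive non-overlapping windows of `length` seconds within each
#' contiguous block of samples; a trailing partial window is dropped and
#' windows never straddle gaps.
#'
#' @param metrics a `metric_series` (or any data frame with a `time` column
#'   at a uniform rate).
#' @param length segment length in seconds (default 15).
#' @param gap_tol factor of the nominal timestep above which a step counts
#'   as a gap (default 1.5).
#' @return list of row-index vectors, one per segment.
#' @export
segment_windows <- function(metrics, length = 15, gap_tol = 1.5) {
  t <- as.numeric(metrics$time)
  if (base::length(t) < 2) stop("metric series shorter than one window")
  dt <- median(diff(t))
  per <- round(length / dt)
  blocks <- cumsum(c(TRUE, diff(t) > gap_tol * dt))
  out <- list()
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    k <- floor(base::length(idx) / per)
    if (k == 0) next
    for (j in seq_len(k)) out[[base::length(out) + 1]] <-
        idx[((j - 1) * per + 1):(j * per)]
  }
  out
}

#' Summarise one segment into the 36-feature vector
#'
#' Four statistics (mean, IQR, 10th and 90th quantile, linear-interpolation
#' quantiles) of eight per-sample metrics (dynamic surge/sway/heave, raw
#' heave, pitch, roll, VeDBA, VeSBA) give 32 features; mean raw surge, mean
#' raw sway, mean temperature and the wingbeat count complete the 36.  This
#' map contains the predictors that dominate classification in practice
#' (mean and upper-quantile VeDBA, mean dynamic sway/heave, IQR heave).
#'
#' @param seg a `metric_series` slice spanning one segment.
#' @return named numeric vector of 36 features.
#' @export
featurize <- function(seg) {
  need <- c("surge", "sway", "heave", "dyn_surge", "dyn_sway", "dyn_heave",
            "pitch", "roll", "vedba", "vesba", "wingbeat", "temp")
  miss <- setdiff(need, names(seg))
  if (length(miss) > 0) stop("missing channels: ", paste(miss, collapse = ", "))
  chans <- c("dyn_surge", "dyn_sway", "dyn_heave", "heave", "pitch", "roll",
             "vedba", "vesba")
  out <- numeric(0)
  for (ch in chans) {
    x <- seg[[ch]]
    q <- quantile(x, c(0.1, 0.9), names = FALSE)
    v <- c(mean(x), IQR(x), q[1], q[2])
    names(v) <- paste0(ch, c("_mean", "_iqr", "_q10", "_q90"))
    out <- c(out, v)
  }
  c(out,
    surge_mean = mean(seg$surge),
    sway_mean = mean(seg$sway),
    temp_mean = mean(seg$temp),
    wingbeat_sum = sum(seg$wingbeat))
}

#' Segment and featurise a metric series
#'
#' @param metrics a `metric_series`.
#' @param length segment length in seconds (default 15).
#' @param bird bird identifier attached to every segment.
#' @param labels optional per-sample truth labels; a segment is labelled by
#'   its modal label.
#' @return data frame: `bird`, `start`, 36 feature columns, and `label`
#'   (NA when unlabelled).
#' @export
featurize_segments <- function(metrics, length = 15, bird = "bird1",
                               labels = NULL) {
  idx <- segment_windows(metrics, length = length)
  if (base::length(idx) == 0) stop("no complete segments")
  feats <- t(vapply(idx, function(i) featurize(metrics[i, , drop = FALSE]),
                    numeric(36)))
  lab <- if (is.null(labels)) NA_character_ else
    vapply(idx, function(i) names(which.max(table(labels[i]))), "")
  out <- data.frame(bird = bird,
                    start = vapply(idx, function(i) as.numeric(metrics$time[i[1]]), 0),
                    feats, check.names = FALSE)
  out$label <- lab
  out
}

#' Evaluate predicted against true labels
#'
#' Overall accuracy with an exact (Clopper-Pearson) binomial confidence
#' interval, Cohen's kappa computed from the confusion-matrix marginals, and
#' one-vs-rest precision, recall and balanced accuracy per class.
#'
#' @param predicted,truth equal-length label vectors.
#' @param classes optional class universe (default: union of observed).
#' @return object of class `eval_report`: `confusion` (predicted x truth),
#'   `accuracy`, `accuracy_ci`, `kappa`, `per_class` data frame.
#' @export
evaluate_classification <- function(predicted, truth, classes = NULL) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  if (is.null(classes)) classes <- sort(union(predicted, truth))
  if (!all(c(predicted, truth) %in% classes)) stop("label outside taxonomy")
  p <- factor(predicted, levels = classes)
  t <- factor(truth, levels = classes)
  cm <- table(predicted = p, truth = t)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  ci <- as.numeric(binom.test(sum(diag(cm)), n)$conf.int)
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[cl, ]) - tp
    fn <- sum(cm[, cl]) - tp
    tn <- n - tp - fp - fn
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    data.frame(class = cl,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = sens,
               balanced_accuracy = (sens + spec) / 2)
  }))
  rownames(per) <- NULL
  structure(list(confusion = cm, accuracy = acc, accuracy_ci = ci,
                 kappa = kappa, per_class = per, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Accuracy %.3f (95%% CI %.3f-%.3f), kappa %.3f, n = %d\n",
              x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2], x$kappa, x$n))
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}
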