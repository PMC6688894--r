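#' Confusion counts for binary artefact detection
#'
#' The artefact class is the positive class.
#'
#' @param y_true,y_pred Binary vectors (0 = good, 1 = artefact), or logical.
#' @return An object of class `confusion_counts` with integer fields `TP`,
#'   `FP`, `FN`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_invariant("`y_true` and `y_pred` lengths differ (%d vs %d)",
                   length(y_true), length(y_pred))
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1)) {
    stop_invariant("labels must be binary (0/1)")
  }
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L),
                 TN = sum(y_true == 0L & y_pred == 0L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and balanced accuracy. Recall is the standard
#' `TP/(TP+FN)` (proportion of artefact images correctly identified). The
#' default balanced accuracy is the `(precision + recall)/2` variant used in
#' this field's quality-assessment tables; `variant = "standard"` gives the
#' usual `(sensitivity + specificity)/2`. Metrics with an empty denominator
#' are reported as `NA` (undefined), never silently 0.
#'
#' @param counts A [confusion()] result.
#' @param variant `"paper"` for (precision+recall)/2, `"standard"` for
#'   (sensitivity+specificity)/2.
#' @return Named numeric vector: `accuracy`, `precision`, `recall`,
#'   `balanced_accuracy`.
#' @export
metrics <- function(counts, variant = c("paper", "standard")) {
  variant <- match.arg(variant)
  if (!inherits(counts, "confusion_counts")) {
    stop_invariant("`counts` must be `confusion_counts`")
  }
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  acc <- safe_div(tp + tn, tp + fp + fn + tn)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  ba <- if (variant == "paper") {
    (prec + rec) / 2
  } else {
    spec <- safe_div(tn, tn + fp)
    (rec + spec) / 2
  }
  c(accuracy = acc, precision = prec, recall = rec, balanced_accuracy = ba)
}

#' ROC curve and area under the curve
#'
#' Sweeps thresholds over the unique scores (predicting positive when
#' `score >= t`), yielding a curve from (0,0) to (1,1); the AUC is the
#' trapezoidal area, which equals the probability that a random positive
#' outscores a random negative plus half the tie probability.
#'
#' @param y_true Binary labels (1 = artefact = positive).
#' @param scores Numeric classifier scores (higher = more artefact-like).
#' @return A list with `curve` (data frame: threshold, TPR, FPR, descending
#'   thresholds) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop_invariant("length mismatch")
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_invariant("ROC needs both classes present (got %d positive, %d negative)",
                   n_pos, n_neg)
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores >= t & y_true == 1L) / n_pos, 0)
  fpr <- vapply(th, function(t) sum(scores >= t & y_true == 0L) / n_neg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = th, TPR = tpr, FPR = fpr), auc = auc)
}

#' Stratified k-fold assignment (optionally repeated)
#'
#' Each repeat partitions the samples into `k` folds with per-fold class
#' counts within one sample of proportional. Deterministic given the seed.
#'
#' @param labels Class labels (any type with well-defined equality).
#' @param k Number of folds.
#' @param repeats Number of independent repetitions.
#' @param seed RNG seed.
#' @return A data frame with columns `index`, `fold`, `rep`.
#' @export
stratified_kfold <- function(labels, k = 10L, repeats = 1L, seed = 1L) {
  if (!is_count(k, 2L)) stop_invariant("`k` must be an integer >= 2")
  k <- as.integer(k)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop_invariant("class '%s' has fewer members (%d) than k = %d",
                   small[1], counts[[small[1]]], k)
  }
  with_seed(seed, {
    out <- lapply(seq_len(repeats), function(r) {
      fold <- integer(length(labels))
      for (cl in names(counts)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- (seq_along(idx) - 1L) %% k + 1L
      }
      data.frame(index = seq_along(labels), fold = fold, rep = r)
    })
    do.call(rbind, out)
  })
}

#' Variance-of-Laplacian blur score
#'
#' Per frame, the variance of the 4-neighbour discrete Laplacian response
#' (computed on the interior, away from borders); the sequence score is the
#' mean over frames. Lower scores indicate blurrier sequences.
#'
#' @param seq A [cine_sequence()].
#' @return A non-negative scalar.
#' @export
variance_of_laplacian <- function(seq) {
  assert_cine(seq)
  d <- dim(seq$frames)
  if (d[1] < 3L || d[2] < 3L) stop_invariant("frames too small for a Laplacian")
  per_frame <- vapply(seq_len(d[3]), function(t) {
    x <- seq$frames[, , t]
    h <- d[1]; w <- d[2]
    lap <- x[1:(h - 2), 2:(w - 1)] + x[3:h, 2:(w - 1)] +
      x[2:(h - 1), 1:(w - 2)] + x[2:(h - 1), 3:w] -
      4 * x[2:(h - 1), 2:(w - 1)]
    mean((lap - mean(lap))^2)
  }, 0)
  mean(per_frame)
}

#' Per-class balanced accuracy for 3-class artefact detection
#'
#' One-vs-rest confusion per artefact class (every class except `"good"`),
#' reporting the (precision+recall)/2 balanced accuracy. A class absent from
#' `y_true` is reported as `NA`.
#'
#' @param y_true,y_pred Character (or factor) labels in
#'   {good, breathing, mistriggering}.
#' @param variant Passed to [metrics()].
#' @return Named numeric vector of per-artefact-class balanced accuracies.
#' @export
evaluate_multiclass <- function(y_true, y_pred, variant = "paper") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop_invariant("length mismatch")
  classes <- setdiff(sort(unique(c(y_true, y_pred))), "good")
  vapply(classes, function(cl) {
    if (!any(y_true == cl)) return(NA_real_)
    m <- metrics(confusion(as.integer(y_true == cl), as.integer(y_pred == cl)),
                 variant = variant)
    m[["balanced_accuracy"]]
  }, 0)
}
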