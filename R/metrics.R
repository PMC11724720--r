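# Evaluation protocol: ROC-AUC as the Mann-Whitney concordance probability,
# confusion-matrix metrics at a cutoff, and exhaustive best-balanced-accuracy
# cutoff selection.

check_labels_scores <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    abort("labels and scores must have the same length")
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- label_to_binary(as_activity_factor(labels))
  }
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1 or active/inactive")
  if (anyNA(scores) || !is.numeric(scores)) {
    abort("scores must be numeric without missing values")
  }
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) {
    abort("both classes must be present")
  }
  list(labels = as.integer(labels), scores = as.numeric(scores))
}

#' ROC-AUC (Mann-Whitney concordance probability)
#'
#' The probability that a randomly drawn active outranks a randomly drawn
#' inactive, with ties counting one half — computed exactly via mid-ranks.
#'
#' @param labels 0/1 vector or `"active"`/`"inactive"` labels (active = 1).
#' @param scores Numeric scores, higher meaning more likely active.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  x <- check_labels_scores(labels, scores)
  n_pos <- sum(x$labels == 1)
  n_neg <- sum(x$labels == 0)
  r <- rank(x$scores, ties.method = "average")
  (sum(r[x$labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics at a score cutoff
#'
#' A prediction is positive when `score > cutoff` (strict, matching the
#' tri-level call rule). Ratios with an empty denominator are reported as 0
#' and flagged in the `degenerate` column.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision cutoff; the shipped thresholds are 0.5 (normal)
#'   and 0.7 (strict).
#' @return A one-row tibble: `roc_auc`, `accuracy`, `precision`, `recall`,
#'   `f1`, `fpr`, `cutoff_used`, `n_pos`, `n_neg`, `degenerate`.
#' @export
classification_metrics <- function(labels, scores, cutoff = 0.5) {
  check_number(cutoff, "cutoff")
  x <- check_labels_scores(labels, scores)
  pred <- as.integer(x$scores > cutoff)
  tp <- sum(pred == 1 & x$labels == 1)
  fp <- sum(pred == 1 & x$labels == 0)
  fn <- sum(pred == 0 & x$labels == 1)
  tn <- sum(pred == 0 & x$labels == 0)
  degenerate <- (tp + fp) == 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble(
    roc_auc = roc_auc(x$labels, x$scores),
    accuracy = (tp + tn) / length(x$labels),
    precision = precision, recall = recall, f1 = f1,
    fpr = fp / (fp + tn),
    cutoff_used = cutoff,
    n_pos = tp + fn, n_neg = fp + tn,
    degenerate = degenerate
  )
}

#' Best balanced-accuracy cutoff
#'
#' Maximizes balanced accuracy, `(TPR + TNR) / 2`, over the exhaustive set
#' of candidate cutoffs (midpoints between consecutive distinct scores, plus
#' 0 and 1). Ties are broken toward the smallest qualifying cutoff.
#'
#' @inheritParams roc_auc
#' @return A list with `cutoff` and `balanced_accuracy`.
#' @export
best_ba_cutoff <- function(labels, scores) {
  x <- check_labels_scores(labels, scores)
  s <- sort(unique(x$scores))
  candidates <- sort(unique(c(0, 1, if (length(s) > 1)
    (s[-1] + s[-length(s)]) / 2)))
  n_pos <- sum(x$labels == 1)
  n_neg <- sum(x$labels == 0)
  ba <- vapply(candidates, function(cut) {
    pred <- x$scores > cut
    tpr <- sum(pred & x$labels == 1) / n_pos
    tnr <- sum(!pred & x$labels == 0) / n_neg
    (tpr + tnr) / 2
  }, numeric(1))
  best <- which.max(ba)  # which.max returns the first (smallest) maximizer
  list(cutoff = candidates[best], balanced_accuracy = ba[best])
}

#' Evaluate a fitted model on labeled examples
#'
#' Computes the full metric report on a labeled example set: ROC-AUC,
#' confusion metrics at the model's normal (0.5) and strict (0.7) cutoffs
#' and at the best-balanced-accuracy cutoff.
#'
#' @param model A fitted `pcm_model`.
#' @param examples Labeled assembled examples.
#' @return A tibble with one row per evaluated cutoff (`cutoff_type` of
#'   `"normal"`, `"strict"`, `"best_ba"`).
#' @export
evaluate_model <- function(model, examples) {
  scores <- predict(model, examples)$score
  labels <- label_to_binary(as_activity_factor(examples$label))
  ba <- best_ba_cutoff(labels, scores)
  dplyr::bind_rows(
    dplyr::mutate(classification_metrics(labels, scores,
                                         model$thresholds[["medium"]]),
                  cutoff_type = "normal"),
    dplyr::mutate(classification_metrics(labels, scores,
                                         model$thresholds[["high"]]),
                  cutoff_type = "strict"),
    dplyr::mutate(classification_metrics(labels, scores, ba$cutoff),
                  cutoff_type = "best_ba",
                  balanced_accuracy = ba$balanced_accuracy)
  )
}
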