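#' Classification metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and accuracy
#' `(TP+TN)/total` for binary predictions, with the positive class coded
#' 1.  A ratio with a zero denominator is reported as `NA` and named in
#' the `flags` column rather than silently coerced to 0.
#'
#' @param preds predicted 0/1 labels.
#' @param labels reference 0/1 labels of the same length.
#' @return a one-row tibble: `precision`, `recall`, `accuracy`, the
#'   confusion counts `tp`, `fp`, `fn`, `tn`, and `flags`.
#' @export
classification_metrics <- function(preds, labels) {
  if (length(preds) == 0) stop("empty input", call. = FALSE)
  if (length(preds) != length(labels)) {
    stop("preds and labels must have equal length", call. = FALSE)
  }
  preds <- as.integer(preds); labels <- as.integer(labels)
  stopifnot(all(preds %in% 0:1), all(labels %in% 0:1))
  tp <- sum(preds == 1 & labels == 1)
  fp <- sum(preds == 1 & labels == 0)
  fn <- sum(preds == 0 & labels == 1)
  tn <- sum(preds == 0 & labels == 0)
  flags <- character()
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    flags <- c(flags, "precision_undefined"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    flags <- c(flags, "recall_undefined"); NA_real_
  }
  tibble(precision = precision, recall = recall,
         accuracy = (tp + tn) / length(preds),
         tp = tp, fp = fp, fn = fn, tn = tn,
         flags = paste(flags, collapse = ";"))
}

#' ROC curve points
#'
#' True-positive rate against false-positive rate at every distinct score
#' threshold (descending), bracketed by (0,0) and (1,1): the monotone
#' staircase of the classifier.
#'
#' @param scores predicted positive-class scores in `[0, 1]`.
#' @param labels reference 0/1 labels.
#' @return tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(scores >= 0 & scores <= 1))
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) {
    if (np == 0) 0 else sum(scores >= t & labels == 1) / np
  }, numeric(1))
  fpr <- vapply(thr, function(t) {
    if (nn == 0) 0 else sum(scores >= t & labels == 0) / nn
  }, numeric(1))
  out <- tibble(threshold = thr, fpr = fpr, tpr = tpr)
  if (out$fpr[nrow(out)] < 1 || out$tpr[nrow(out)] < 1) {
    out <- dplyr::bind_rows(out, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the [roc_points()] staircase.
#'
#' @inheritParams roc_points
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}
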