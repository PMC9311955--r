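#' Confusion matrix of age-range predictions
#'
#' `counts[i, j]` is the number of samples with actual label `i - 1`
#' predicted as label `j - 1`: rows are actual labels (each row sums to
#' the number of actual samples of that label), columns are predictions.
#'
#' @param true,pred equal-length integer vectors of labels in
#'   `0 .. n_classes - 1`.
#' @param n_classes number of classes (default 5).
#' @return an `n_classes x n_classes` integer matrix with dimnames
#'   `actual` / `predicted`.
#' @export
confusion <- function(true, pred, n_classes = 5L) {
  if (length(true) != length(pred)) {
    stopf("true (%d) and pred (%d) differ in length", length(true), length(pred))
  }
  true <- as.integer(true); pred <- as.integer(pred)
  if (any(c(true, pred) < 0) || any(c(true, pred) >= n_classes)) {
    stopf("labels must lie in 0..%d", n_classes - 1L)
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(actual = 0:(n_classes - 1L),
                               predicted = 0:(n_classes - 1L)))
  for (i in seq_along(true)) cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Harmonic mean of precision and recall
#'
#' `F1 = 2 P R / (P + R)`; 0 when both are 0.
#'
#' @param precision,recall numeric vectors in `[0, 1]`.
#' @return numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' For each class X: `TP` is the diagonal entry, `FP` the rest of its
#' column, `FN` the rest of its row, `TN` the remainder;
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1` their harmonic mean.
#' A 0/0 ratio is reported as 0 with the `undefined_*` flag set.
#'
#' @param cm a confusion matrix from [confusion()].
#' @return a data.frame with one row per class: `label`, `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`, `undefined_precision`,
#'   `undefined_recall`.
#' @export
class_metrics <- function(cm) {
  k <- nrow(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  up <- tp + fp == 0
  ur <- tp + fn == 0
  p <- ifelse(up, 0, tp / (tp + fp))
  r <- ifelse(ur, 0, tp / (tp + fn))
  data.frame(label = 0:(k - 1L), tp = tp, fp = fp, fn = fn, tn = tn,
             precision = p, recall = r, f1 = f1_score(p, r),
             undefined_precision = up, undefined_recall = ur,
             row.names = NULL)
}

#' Overall accuracy of a confusion matrix
#'
#' The proportion of correctly identified samples among all samples
#' (`trace / total`, the default `form = "proportion"`). The alternative
#' `form = "per_class_sum"` reports the sum over classes of the per-class
#' one-vs-rest accuracies `(TP_X + TN_X) / N` without dividing by the
#' number of classes; it is provided because that summation form circulates
#' as an accuracy formula even though it exceeds 1 whenever more than one
#' class is present -- the proportion form is the meaningful one.
#'
#' @param cm a confusion matrix from [confusion()].
#' @param form `"proportion"` or `"per_class_sum"`.
#' @return a single number.
#' @export
accuracy <- function(cm, form = c("proportion", "per_class_sum")) {
  form <- match.arg(form)
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  if (form == "proportion") return(sum(diag(cm)) / total)
  m <- class_metrics(cm)
  sum((m$tp + m$tn) / total)
}

## Midrank (Mann-Whitney) AUC of scores for positives vs negatives.
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest ROC AUC per class
#'
#' For each class c, the area under the ROC curve of the class-c
#' probability for class-c samples versus all others, computed as the
#' rank-based Mann-Whitney statistic with midranks for ties, plus the
#' arithmetic mean over classes. A class absent from the truth has
#' undefined AUC; it is excluded from the average with a warning.
#'
#' @param scores N x K matrix of class probabilities (rows sum to 1).
#' @param true integer labels 0..K-1, length N.
#' @return a list with `auc` (length-K named vector, `NA` when undefined)
#'   and `average` (mean of the defined AUCs).
#' @export
roc_auc <- function(scores, true) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  true <- as.integer(true)
  if (length(true) != nrow(scores)) stopf("scores and true differ in length")
  if (any(abs(rowSums(scores) - 1) > 1e-6)) {
    stopf("score rows must sum to 1 (class probabilities)")
  }
  auc <- vapply(seq_len(k), function(c) auc_rank(scores[, c], true == c - 1L),
                numeric(1))
  names(auc) <- 0:(k - 1L)
  if (anyNA(auc)) {
    warnf("classes absent from truth excluded from the average AUC: %s",
          paste(names(auc)[is.na(auc)], collapse = ", "))
  }
  list(auc = auc, average = mean(auc, na.rm = TRUE))
}

## Empirical ROC curve points (FPR, TPR) for one class, threshold sweep.
roc_curve <- function(scores, positive) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(positive); n0 <- sum(!positive)
  tpr <- vapply(ths, function(t) sum(scores >= t & positive) / n1, numeric(1))
  fpr <- vapply(ths, function(t) sum(scores >= t & !positive) / n0, numeric(1))
  data.frame(threshold = ths, fpr = fpr, tpr = tpr)
}

#' Full evaluation report
#'
#' Confusion matrix, per-class precision/recall/F1 and one-vs-rest AUC,
#' overall accuracy and average AUC for a batch of predictions: the
#' standard report layout for the five-range age classifier.
#'
#' @param true integer labels 0..K-1.
#' @param pred integer predicted labels (defaults to the argmax of
#'   `scores`).
#' @param scores optional N x K probability matrix (needed for AUC).
#' @param n_classes number of classes.
#' @return an object of class `mps_metrics`: `confusion`, `per_class`
#'   (data.frame with the metrics and AUC), `accuracy`,
#'   `per_class_acc_sum`, `average_auc`, `n`.
#' @export
metrics_report <- function(true, pred = NULL, scores = NULL, n_classes = 5L) {
  if (is.null(pred)) {
    if (is.null(scores)) stopf("need pred or scores")
    pred <- max.col(as.matrix(scores), ties.method = "first") - 1L
  }
  cm <- confusion(true, pred, n_classes)
  per <- class_metrics(cm)
  if (!is.null(scores)) {
    ra <- roc_auc(scores, true)
    per$auc <- unname(ra$auc)
    avg_auc <- ra$average
  } else {
    per$auc <- NA_real_
    avg_auc <- NA_real_
  }
  structure(list(confusion = cm, per_class = per,
                 accuracy = accuracy(cm),
                 per_class_acc_sum = accuracy(cm, "per_class_sum"),
                 average_auc = avg_auc, n = sum(cm)),
            class = "mps_metrics")
}

#' @export
print.mps_metrics <- function(x, ...) {
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(x$confusion)
  cat("\nPer-class metrics:\n")
  tab <- x$per_class[, c("label", "auc", "precision", "recall", "f1")]
  tab$n_test <- rowSums(x$confusion)
  print(format(tab, digits = 4), row.names = FALSE)
  cat(sprintf("\nTotal samples: %d\nAccuracy: %.4f\nAverage AUC: %s\n",
              x$n, x$accuracy,
              ifelse(is.na(x$average_auc), "-", sprintf("%.4f", x$average_auc))))
  invisible(x)
}

#' @export
as.data.frame.mps_metrics <- function(x, ...) {
  tab <- x$per_class[, c("label", "auc", "precision", "recall", "f1")]
  tab$n_test <- rowSums(x$confusion)
  tab
}

#' Write a metrics report as JSON plus a per-class CSV
#'
#' @param report an `mps_metrics` object.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(confusion = report$confusion,
                              per_class = report$per_class,
                              accuracy = report$accuracy,
                              per_class_acc_sum = report$per_class_acc_sum,
                              average_auc = report$average_auc, n = report$n),
                         json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  invisible(report)
}
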