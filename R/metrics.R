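#' Confusion counts for semantic segmentation
#'
#' Tallies per-class true positives, false positives and false negatives for
#' equal-length label sequences over a fixed class set, plus the per-class
#' support (number of true points of each class).
#'
#' @param true_labels,pred_labels integer vectors of equal length.
#' @param classes class id vector (default the three organ classes 0, 1, 2).
#' @return object of class `confusion_counts`: list with `classes`, `tp`,
#'   `fp`, `fn`, `tn`, `support`, `n`.
#' @export
confusion <- function(true_labels, pred_labels, classes = 0:2) {
  if (length(true_labels) != length(pred_labels))
    stop("label sequences must have equal length")
  if (!all(true_labels %in% classes) || !all(pred_labels %in% classes))
    stop("labels outside the declared class set")
  n <- length(true_labels)
  tp <- fp <- fn <- tn <- support <- numeric(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp[i] <- sum(true_labels == k & pred_labels == k)
    fp[i] <- sum(true_labels != k & pred_labels == k)
    fn[i] <- sum(true_labels == k & pred_labels != k)
    tn[i] <- n - tp[i] - fp[i] - fn[i]
    support[i] <- sum(true_labels == k)
  }
  structure(list(classes = classes, tp = tp, fp = fp, fn = fn, tn = tn,
                 support = support, n = n),
            class = "confusion_counts")
}

#' Per-class segmentation metrics
#'
#' From confusion counts: precision TP/(TP+FP), recall TP/(TP+FN),
#' F1 = 2PR/(P+R), IoU = TP/(TP+FP+FN), and a per-class accuracy
#' (TP+TN)/N (the one-vs-rest reading of per-label accuracy). Any 0/0 is
#' reported as 0 and flagged in the `degenerate` column.
#'
#' @param counts a [confusion()] result.
#' @return `data.frame` with one row per class: `class`, `support`,
#'   `accuracy`, `precision`, `recall`, `f1`, `iou`, `degenerate`.
#' @export
per_class_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe(counts$tp, counts$tp + counts$fp)
  recall <- safe(counts$tp, counts$tp + counts$fn)
  f1 <- safe(2 * precision * recall, precision + recall)
  iou <- safe(counts$tp, counts$tp + counts$fp + counts$fn)
  accuracy <- safe(counts$tp + counts$tn, counts$n)
  degenerate <- (counts$tp + counts$fp) == 0 | (counts$tp + counts$fn) == 0
  if (any(degenerate))
    warning("0/0 metric(s) reported as 0 for class(es): ",
            paste(counts$classes[degenerate], collapse = ", "))
  data.frame(class = counts$classes, support = counts$support,
             accuracy = accuracy, precision = precision, recall = recall,
             f1 = f1, iou = iou, degenerate = degenerate)
}

#' Support-weighted aggregate metrics
#'
#' Weights each class by its share of true points, w_k = N_k / sum_j N_j, and
#' aggregates every per-class metric as sum_k w_k * metric_k. The overall
#' accuracy sum_k TP_k / N is reported alongside.
#'
#' @param counts a [confusion()] result.
#' @param per_class optional precomputed [per_class_metrics()] table.
#' @return object of class `metrics_report`: list with `per_class`,
#'   `weights`, `weighted` (named numeric: accuracy, precision, recall, f1,
#'   iou) and `overall_accuracy`.
#' @export
weighted_metrics <- function(counts, per_class = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (sum(counts$support) == 0) stop("all-zero supports")
  if (is.null(per_class))
    per_class <- suppressWarnings(per_class_metrics(counts))
  w <- counts$support / sum(counts$support)
  weighted <- vapply(c("accuracy", "precision", "recall", "f1", "iou"),
                     function(mt) sum(w * per_class[[mt]]), numeric(1L))
  structure(list(per_class = per_class, weights = w, weighted = weighted,
                 overall_accuracy = sum(counts$tp) / counts$n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("overall accuracy: %.4f\n", x$overall_accuracy))
  cat("support-weighted:",
      paste(sprintf("%s %.4f", names(x$weighted), x$weighted),
            collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a predicted labeling against ground truth
#'
#' Convenience wrapper: confusion counts then per-class and support-weighted
#' metrics over the three semantic organ classes.
#'
#' @param true_labels,pred_labels equal-length integer label vectors.
#' @param classes class id vector.
#' @return a `metrics_report`.
#' @export
evaluate_segmentation <- function(true_labels, pred_labels, classes = 0:2) {
  weighted_metrics(confusion(true_labels, pred_labels, classes))
}
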