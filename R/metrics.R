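#' Confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns). For a
#' two-class problem with class 0 as the positive class the cells map to
#' `(TP, FN; FP, TN)`.
#'
#' @param y_true,y_pred Vectors of class codes, equal length.
#' @param classes Ordered vector of all class codes; defaults to the sorted
#'   union of observed values.
#' @return A `confusion_matrix`: C x C integer matrix with class dimnames.
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(y_true %in% classes)) stop("y_true contains a label not in `classes`")
  if (!all(y_pred %in% classes)) stop("y_pred contains a label not in `classes`")
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  cm <- unclass(table(ft, fp, dnn = NULL))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (rows = true, columns = predicted):\n")
  print(matrix(as.vector(x), nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}

ratio0 <- function(num, den) if (den > 0) num / den else 0

#' Binary classification metrics from a 2x2 confusion matrix
#'
#' Precision, recall (TPR), TNR, F-measure, G-mean and accuracy, with class
#' 0 (first row) as positive. Ratios with zero denominators are reported as
#' 0 and listed in the `undefined` flag rather than returned as NaN, so
#' aggregates over degenerate folds stay computable.
#'
#' @param cm A 2x2 `confusion_matrix`.
#' @return List: `precision`, `recall`, `tnr`, `f_measure`, `g_mean`,
#'   `accuracy`, `undefined` (character vector of flagged ratios).
#' @export
binary_metrics <- function(cm) {
  if (!all(dim(cm) == c(2, 2))) stop("binary_metrics requires a 2x2 confusion matrix")
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  undefined <- character(0)
  if (tp + fp == 0) undefined <- c(undefined, "precision")
  if (tp + fn == 0) undefined <- c(undefined, "recall")
  if (tn + fp == 0) undefined <- c(undefined, "tnr")
  precision <- ratio0(tp, tp + fp)
  recall <- ratio0(tp, tp + fn)
  tnr <- ratio0(tn, tn + fp)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(
    precision = precision,
    recall = recall,
    tnr = tnr,
    f_measure = f,
    g_mean = sqrt(recall * tnr),
    accuracy = ratio0(tp + tn, tp + tn + fp + fn),
    undefined = undefined
  )
}

per_class_recall <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    stop(sprintf("class '%s' has no true samples; per-class accuracy undefined",
                 rownames(cm)[which(rs == 0)[1]]))
  }
  diag(cm) / rs
}

#' Multiclass G-mean
#'
#' Geometric mean of the per-class accuracies, where class i's accuracy is
#' its recall (diagonal over row sum) — the reading under which the
#' multiclass form reduces exactly to `sqrt(TPR * TNR)` on two classes.
#' Any class fully missed drives the G-mean to 0, which is the metric's
#' point: a classifier cannot hide a sacrificed minority class.
#'
#' @param cm A `confusion_matrix` with at least one true sample per class.
#' @return G-mean in `[0, 1]`.
#' @export
multiclass_g_mean <- function(cm) {
  acc <- per_class_recall(cm)
  prod(acc)^(1 / length(acc))
}

#' Multiclass (macro) F-score
#'
#' Unweighted mean over classes of the per-class F-measure, with class i's
#' precision = `cm[i,i] / colsum_i` and recall = `cm[i,i] / rowsum_i`.
#' Degenerate ratios (class never predicted) contribute 0.
#'
#' @param cm A `confusion_matrix`.
#' @return Macro F-score in `[0, 1]`.
#' @export
multiclass_f_score <- function(cm) {
  cs <- colSums(cm)
  rs <- rowSums(cm)
  f <- vapply(seq_len(nrow(cm)), function(i) {
    p <- ratio0(cm[i, i], cs[i])
    r <- ratio0(cm[i, i], rs[i])
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  mean(f)
}

#' Prevalence-weighted multiclass accuracy
#'
#' Per-class accuracies (recalls) weighted by class prevalence
#' `P_i = rowsum_i / total`. With the recall reading of per-class accuracy
#' this is identically `trace(cm) / total`, i.e. the overall accuracy.
#'
#' @param cm A `confusion_matrix`.
#' @return Accuracy in `[0, 1]`.
#' @export
weighted_accuracy <- function(cm) {
  acc <- per_class_recall(cm)
  p <- rowSums(cm) / sum(cm)
  sum(acc * p)
}
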