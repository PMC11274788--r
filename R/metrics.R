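#' Confusion-matrix evaluation of hard-label predictions
#'
#' Computes accuracy, sensitivity (true-positive rate), specificity
#' (true-negative rate) and the F1 score for a designated positive class,
#' plus the raw confusion counts. Metrics are returned as percentages on
#' 0–100. A ratio with a zero denominator (e.g. sensitivity with no
#' positive-class truth instances) is reported as `NA` ("undefined"),
#' never silently as 0.
#'
#' @param y_true true class labels.
#' @param y_pred predicted class labels, same length.
#' @param positive the positive class label; defaults to `"1"` (the usual
#'   malignant encoding in binary histopathology tasks, where 0 = benign
#'   and 1 = malignant).
#' @return a list with `accuracy`, `sensitivity`, `specificity`, `f1`
#'   (percentages, `NA` when undefined) and `counts` (list with `tp`,
#'   `fp`, `tn`, `fn`).
#' @details Binary definitions: accuracy = (TP+TN)/N, sensitivity =
#'   TP/(TP+FN), specificity = TN/(TN+FP), F1 = 2TP/(2TP+FP+FN). With more
#'   than two classes the evaluation is one-vs-rest for the designated
#'   positive class; [evaluate_multiclass()] reports every class in turn.
#'   Swapping which class is designated positive swaps sensitivity and
#'   specificity.
#' @export
evaluate_classification <- function(y_true, y_pred, positive = "1") {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ: ", length(y_true), " vs ",
         length(y_pred))
  }
  positive <- as.character(positive)
  if (!positive %in% c(y_true, y_pred)) {
    stop("positive class '", positive, "' absent from labels")
  }
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  n <- tp + fn + tn + fp
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(
    accuracy = ratio(tp + tn, n),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    f1 = ratio(2 * tp, 2 * tp + fp + fn),
    counts = list(tp = tp, fp = fp, tn = tn, fn = fn)
  )
}

#' One-vs-rest evaluation for every class
#'
#' @inheritParams evaluate_classification
#' @return a data frame with one row per class: `class`, `accuracy`
#'   (overall, identical in every row), `sensitivity`, `specificity`,
#'   `f1`, and the one-vs-rest counts.
#' @export
evaluate_multiclass <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  acc <- 100 * mean(y_true == y_pred)
  rows <- lapply(classes, function(cl) {
    m <- evaluate_classification(y_true, y_pred, positive = cl)
    data.frame(class = cl, accuracy = acc, sensitivity = m$sensitivity,
               specificity = m$specificity, f1 = m$f1,
               tp = m$counts$tp, fp = m$counts$fp,
               tn = m$counts$tn, fn = m$counts$fn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format an evaluation as a plain-text metric table
#'
#' @param eval result of [evaluate_classification()].
#' @param name row label for the table (e.g. the model or run name).
#' @return a character vector of lines: a header
#'   `Accuracy % / Sensitivity % / Specificity % / F1 Score %` and one
#'   value row; undefined metrics print as `NA`.
#' @export
format_metric_table <- function(eval, name = "FCA") {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  c(sprintf("%-16s %10s %14s %14s %12s", "Classifier", "Accuracy %",
            "Sensitivity %", "Specificity %", "F1 Score %"),
    sprintf("%-16s %10s %14s %14s %12s", name, fmt(eval$accuracy),
            fmt(eval$sensitivity), fmt(eval$specificity), fmt(eval$f1)))
}
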