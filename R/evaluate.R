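#' Overall accuracy (percent)
#'
#' `100 * #correct / #total` over paired label vectors.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' overall_accuracy(c("a", "a", "b", "b"), c("a", "b", "b", "b"))  # 75
overall_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  if (length(truth) == 0L) abort("Empty label vectors.")
  100 * sum(as.character(truth) == as.character(predicted)) / length(truth)
}

per_class_prf <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- classes %||% sort(union(truth, predicted))
  purrr::map_dfr(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble(class = cl, support = tp + fn, precision = precision,
           recall = recall, f1 = f1)
  })
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 scores over the classes present in the
#' truth or the prediction. A class predicted never and absent from the
#' truth is excluded; a class with zero precision and recall contributes 0.
#'
#' @inheritParams overall_accuracy
#' @return Score in `[0, 1]`.
#' @export
macro_f1 <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  if (length(truth) == 0L) abort("Empty label vectors.")
  mean(per_class_prf(truth, predicted)$f1)
}

#' Full classification metric report
#'
#' Bundles overall accuracy, macro F1, the per-class precision/recall/F1
#' table and the confusion matrix for one evaluation level (pixel or field).
#'
#' @inheritParams overall_accuracy
#' @param level `"pixel"` or `"field"`, recorded in the report.
#' @param classes Optional class order for the confusion matrix.
#' @return Object of class `metric_report`: a list with
#'   `overall_accuracy`, `macro_f1`, `per_class` (tibble), `confusion`
#'   (contingency table, rows = truth) and `level`.
#' @export
metric_report <- function(truth, predicted, level = c("field", "pixel"),
                          classes = NULL) {
  level <- match.arg(level)
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- classes %||% sort(union(truth, predicted))
  confusion <- table(truth = factor(truth, classes),
                     predicted = factor(predicted, classes))
  structure(
    list(overall_accuracy = overall_accuracy(truth, predicted),
         macro_f1 = macro_f1(truth, predicted),
         per_class = per_class_prf(truth, predicted, classes),
         confusion = confusion,
         level = level,
         n = length(truth)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> level = %s, n = %d\n", x$level, x$n))
  cat(sprintf("  overall accuracy: %.2f%%\n  macro F1: %.4f\n",
              x$overall_accuracy, x$macro_f1))
  invisible(x)
}

#' @rdname metric_report
#' @param x A `metric_report`.
#' @param ... Unused.
#' @export
tidy.metric_report <- function(x, ...) x$per_class

#' @rdname metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble(level = x$level, overall_accuracy = x$overall_accuracy,
         macro_f1 = x$macro_f1, n = x$n)
}
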