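#' Two-class confusion matrix
#'
#' Counts under an explicit positive-class convention. Throughout the
#' package tumor is the positive class: sensitivity is the true-positive
#' rate among tumors and specificity the true-negative rate among normals.
#'
#' @param y_true,y_pred Equal-length label vectors drawn from at most two
#'   classes.
#' @param positive_class The class counted as positive (default `"tumor"`).
#' @return An object of class `confusion_matrix` with integer counts `tp`,
#'   `fp`, `tn`, `fn` and the `positive_class`.
#' @export
#' @examples
#' cm <- confusion(rep(c("tumor", "normal"), c(35, 35)),
#'                 rep(c("tumor", "normal", "tumor"), c(35, 28, 7)))
#' performance(cm)
confusion <- function(y_true, y_pred, positive_class = "tumor") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    of_stop("invalid_spec", "y_true and y_pred lengths differ")
  if (length(y_true) == 0)
    of_stop("invalid_spec", "empty label vectors")
  classes <- sort(unique(c(y_true, y_pred)))
  if (length(classes) > 2)
    of_stop("invalid_spec", "confusion() handles binary labels; got %d classes",
            length(classes))
  if (!positive_class %in% classes && length(classes) == 2)
    of_stop("invalid_spec", "positive_class '%s' absent from labels",
            positive_class)
  pos <- y_true == positive_class
  pred_pos <- y_pred == positive_class
  structure(
    list(tp = sum(pos & pred_pos), fp = sum(!pos & pred_pos),
         tn = sum(!pos & !pred_pos), fn = sum(pos & !pred_pos),
         positive_class = positive_class),
    class = "confusion_matrix"
  )
}

#' Assemble a confusion matrix from counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts (total > 0).
#' @param positive_class Positive-class label.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn, positive_class = "tumor") {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) == 0)
    of_stop("invalid_spec",
            "counts must be non-negative integers with a positive total")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 positive_class = positive_class),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive = %s\n", x$positive_class))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(true = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(t(m))
  invisible(x)
}

#' Performance metrics of a confusion matrix
#'
#' All metrics in percent: accuracy `(tp + tn) / total`, sensitivity
#' `tp / (tp + fn)`, specificity `tn / (tn + fp)` and error rate
#' `100 - accuracy`.
#'
#' @param cm A `confusion_matrix`.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`,
#'   `error_rate` (percent, unrounded).
#' @export
performance <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0) of_stop("undefined_metric", "accuracy undefined: no samples")
  if (cm$tp + cm$fn == 0)
    of_stop("undefined_metric", "sensitivity undefined: no positive samples")
  if (cm$tn + cm$fp == 0)
    of_stop("undefined_metric", "specificity undefined: no negative samples")
  acc <- 100 * (cm$tp + cm$tn) / total
  list(accuracy = acc,
       sensitivity = 100 * cm$tp / (cm$tp + cm$fn),
       specificity = 100 * cm$tn / (cm$tn + cm$fp),
       error_rate = 100 - acc)
}
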