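#' Confusion counts for one class (one-vs-rest)
#'
#' Tallies true/false positives and negatives of a single target class
#' against all remaining classes.
#'
#' @param y_true,y_pred vectors of observed and predicted class labels.
#' @param positive the class treated as "positive".
#' @return A list with integer fields `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop_input("y_true and y_pred lengths differ (%d vs %d)",
               length(y_true), length(y_pred))
  pos_t <- y_true == positive; pos_p <- y_pred == positive
  list(TP = sum(pos_t & pos_p), FN = sum(pos_t & !pos_p),
       TN = sum(!pos_t & !pos_p), FP = sum(!pos_t & pos_p))
}

#' Sensitivity (true positive rate)
#'
#' `TP / (TP + FN)`.
#'
#' @param counts a list with fields `TP` and `FN` (see [confusion_counts()]).
#' @return Fraction in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  denom <- counts$TP + counts$FN
  if (denom == 0) stop_input("sensitivity undefined: no positive samples (TP + FN = 0)")
  counts$TP / denom
}

#' Specificity (true negative rate)
#'
#' `TN / (TN + FP)`. In a two-class problem the specificity of one class
#' equals the sensitivity of the other.
#'
#' @param counts a list with fields `TN` and `FP`.
#' @return Fraction in `[0, 1]`.
#' @export
specificity <- function(counts) {
  denom <- counts$TN + counts$FP
  if (denom == 0) stop_input("specificity undefined: no negative samples (TN + FP = 0)")
  counts$TN / denom
}

#' Class error in percent
#'
#' `CE = (1 - (sensitivity + specificity) / 2) * 100`, the average of the
#' false positive and false negative rates expressed in percent. Values are
#' kept unrounded internally; round only for display.
#'
#' @param sens,spec sensitivity and specificity as fractions.
#' @return Class error in percent.
#' @export
class_error <- function(sens, spec) {
  stopifnot(is.finite(sens), is.finite(spec))
  (1 - (sens + spec) / 2) * 100
}

#' Overall accuracy from per-class errors
#'
#' `100 - max(class_errors)`: the reported accuracy is limited by the worst
#' class error across classes and across the cross-validation and prediction
#' phases ("whichever is higher").
#'
#' @param class_errors numeric vector of class errors in percent.
#' @return Overall accuracy in percent.
#' @export
overall_accuracy <- function(class_errors) {
  class_errors <- unlist(class_errors, use.names = FALSE)
  if (length(class_errors) == 0) stop_input("overall_accuracy: empty class-error list")
  100 - max(class_errors)
}

#' Per-class metrics report
#'
#' Expands a multi-class prediction into one-vs-rest confusion counts per
#' class and computes sensitivity, specificity and class error for each.
#'
#' @param y_true,y_pred observed and predicted labels.
#' @param classes class levels; defaults to the sorted union of `y_true`.
#' @return A data.frame with columns `class`, `sensitivity`, `specificity`,
#'   `class_error` (percent), `n`.
#' @export
per_class_report <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true)
  if (is.null(classes)) classes <- sort(unique(y_true))
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(y_true, y_pred, cl)
    se <- sensitivity(cc); sp <- specificity(cc)
    data.frame(class = cl, sensitivity = se, specificity = sp,
               class_error = class_error(se, sp),
               n = cc$TP + cc$FN, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Display rounding, half away from zero, to `digits` decimals (matches how
## percentages are conventionally printed in chemometric model tables).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
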