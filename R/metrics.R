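#' Confusion counts for binary classification
#'
#' Counts true/false positives and negatives under the label coding
#' used throughout the package: 1 = AFP (positive), 2 = non-AFP
#' (negative). TP/TN are correctly predicted positive/negative samples;
#' FN/FP are incorrectly predicted positive/negative samples.
#'
#' @param y_true,y_pred equal-length vectors with values in `{1, 2}`.
#' @return A list of class `ConfusionCounts` with integer fields `TP`,
#'   `FP`, `FN`, `TN` summing to `length(y_true)`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(1L, 2L))) {
    stop("labels must be 1 (positive) or 2 (negative)", call. = FALSE)
  }
  structure(
    list(TP = sum(y_true == 1L & y_pred == 1L),
         FP = sum(y_true == 2L & y_pred == 1L),
         FN = sum(y_true == 1L & y_pred == 2L),
         TN = sum(y_true == 2L & y_pred == 2L)),
    class = "ConfusionCounts"
  )
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Evaluates the four standard measures:
#' SN = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/(TP+TN+FP+FN), and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' SN is the accuracy on positive samples and SP on negative samples;
#' MCC is a balanced summary in [-1, 1] that remains informative under
#' heavy class imbalance and is the model-selection measure used by
#' [ifs_search()]. Any measure whose denominator is 0 is defined as 0
#' and flagged via the `degenerate` field.
#'
#' @param counts a `ConfusionCounts` from [confusion_counts()], or a
#'   list with fields `TP`, `FP`, `FN`, `TN`.
#' @return A list of class `MetricSet` with numeric fields `SN`, `SP`,
#'   `ACC`, `MCC`, logical `degenerate`, and the input `counts`.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  fn <- as.numeric(counts$FN); tn <- as.numeric(counts$TN)
  if (any(c(tp, fp, fn, tn) < 0) || tp + fp + fn + tn < 1) {
    stop("counts must be nonnegative with total >= 1", call. = FALSE)
  }
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  acc <- (tp + tn) / (tp + fp + fn + tn)
  mcc <- safe_div(tp * tn - fp * fn,
                  sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  structure(list(SN = sn, SP = sp, ACC = acc, MCC = mcc,
                 degenerate = degenerate, counts = counts),
            class = "MetricSet")
}

#' @export
print.MetricSet <- function(x, ...) {
  cat(sprintf("SN = %.4f  SP = %.4f  ACC = %.4f  MCC = %.4f%s\n",
              x$SN, x$SP, x$ACC, x$MCC,
              if (isTRUE(x$degenerate)) "  [degenerate denominator -> 0]" else ""))
  invisible(x)
}
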