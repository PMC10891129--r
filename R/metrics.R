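# Decision rule, confusion matrix and the five evaluation metrics.
# Convention throughout: the positive class is "healthy"; TP counts healthy
# images predicted healthy, TN counts T2D images predicted T2D.

#' Map healthy-class scores to class labels
#'
#' Scores strictly greater than 0.5 map to `"healthy"`; everything else
#' (including exactly 0.5) maps to `"T2D"`.
#'
#' @param healthy_score Numeric vector of scores in `[0, 1]`.
#' @return Character vector of `"healthy"` / `"T2D"` labels.
#' @export
predict_label <- function(healthy_score) {
  stopifnot(is.numeric(healthy_score))
  if (any(healthy_score < 0 | healthy_score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  ifelse(healthy_score > 0.5, "healthy", "T2D")
}

#' Confusion matrix with healthy as the positive class
#'
#' @param y_true,y_pred Character vectors of `"healthy"` / `"T2D"` labels,
#'   equal length.
#' @return An object of class `confusion_matrix`: list with integer
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  lv <- c("healthy", "T2D")
  if (!all(y_true %in% lv) || !all(y_pred %in% lv)) {
    stop("labels must be 'healthy' or 'T2D'", call. = FALSE)
  }
  structure(
    list(tp = sum(y_true == "healthy" & y_pred == "healthy"),
         fp = sum(y_true == "T2D" & y_pred == "healthy"),
         tn = sum(y_true == "T2D" & y_pred == "T2D"),
         fn = sum(y_true == "healthy" & y_pred == "T2D")),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Balanced accuracy, accuracy, precision, recall and F1
#'
#' Computed from the confusion counts:
#' `BAC = (TP/(TP+FN) + TN/(TN+FP)) / 2`,
#' `ACC = (TP+TN)/total`, `PRE = TP/(TP+FP)`, `REC = TP/(TP+FN)`,
#' `F1 = 2*PRE*REC/(PRE+REC)`. A metric whose denominator is zero is
#' reported as `NA` (the explicit "undefined" marker), never silently 0.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metrics_report`: list with `bac`, `acc`,
#'   `pre`, `rec`, `f1`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(cm$tp, cm$tp + cm$fn)
  spec <- safe_div(cm$tn, cm$tn + cm$fp)
  bac <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  acc <- safe_div(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  pre <- safe_div(cm$tp, cm$tp + cm$fp)
  rec <- sens
  f1 <- if (is.na(pre) || is.na(rec) || (pre + rec) == 0) NA_real_ else {
    2 * pre * rec / (pre + rec)
  }
  structure(list(bac = bac, acc = acc, pre = pre, rec = rec, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> BAC=%.4f ACC=%.4f PRE=%.4f REC=%.4f F1=%.4f\n",
              x$bac, x$acc, x$pre, x$rec, x$f1))
  invisible(x)
}
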