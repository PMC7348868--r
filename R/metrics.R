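#' Confusion matrix under the depression-positive convention
#'
#' Class 1 = depression = positive, class 0 = dementia = negative.
#'
#' @param labels true labels, 0/1 vector.
#' @param predictions predicted labels, 0/1 vector of the same length.
#' @return list of class `confusion` with integer counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop("labels and predictions must be 0/1")
  confusion_counts(tp = sum(labels == 1 & predictions == 1),
                   fp = sum(labels == 0 & predictions == 1),
                   tn = sum(labels == 0 & predictions == 0),
                   fn = sum(labels == 1 & predictions == 0))
}

#' Construct a confusion matrix from counts
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @return list of class `confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  structure(lapply(as.list(counts), as.integer), class = "confusion")
}

#' Reconstruct integer confusion counts from class sizes and rates
#'
#' Given the positive/negative class sizes and the printed TPR/TNR
#' percentages of a published confusion summary, recovers the integer
#' counts by nearest-integer rounding (TP = round(TPR/100 * P), etc.).
#'
#' @param n_pos,n_neg class sizes (positives = depression).
#' @param tpr_pct,tnr_pct true positive / true negative rates in percent.
#' @return list of class `confusion`.
#' @export
reconstruct_confusion <- function(n_pos, n_neg, tpr_pct, tnr_pct) {
  tp <- round(tpr_pct / 100 * n_pos)
  tn <- round(tnr_pct / 100 * n_neg)
  confusion_counts(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' The eight confusion-matrix evaluation metrics
#'
#' Accuracy, TPR (sensitivity), TNR (specificity), PPV (precision), NPV,
#' F1, Cohen's kappa via the expected-agreement form
#' EXP = ((TP+FP)(TP+FN) + (TN+FN)(TN+FP)) / total^2, and Matthews
#' correlation with the four-factor denominator. Ratios with a zero
#' denominator are NA (undefined), except MCC which is defined as 0 when
#' its denominator vanishes (flagged via the `mcc_degenerate` attribute).
#' All values are proportions on \code{[0, 1]} (kappa/MCC on
#' \code{[-1, 1]}); multiply by 100 for the percent reporting scale.
#'
#' @param cm a `confusion` object.
#' @return named numeric vector: acc, tpr, tnr, ppv, npv, f1, kappa, mcc.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- (tp + tn) / total
  tpr <- sdiv(tp, tp + fn)
  tnr <- sdiv(tn, tn + fp)
  ppv <- sdiv(tp, tp + fp)
  npv <- sdiv(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(tpr) || (ppv + tpr) == 0) NA_real_
        else 2 * ppv * tpr / (ppv + tpr)
  expagree <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / total^2
  kappa <- if (expagree == 1) NA_real_ else (acc - expagree) / (1 - expagree)
  mden <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  degenerate <- mden == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / mden
  out <- c(acc = acc, tpr = tpr, tnr = tnr, ppv = ppv, npv = npv,
           f1 = f1, kappa = kappa, mcc = mcc)
  attr(out, "mcc_degenerate") <- degenerate
  out
}

#' Format a metric set on the percent reporting scale
#' @param metrics vector from [compute_metrics()].
#' @param digits decimals (default 1, the tables' precision).
#' @return named numeric vector in percent.
#' @export
metrics_percent <- function(metrics, digits = 1) {
  round(100 * metrics, digits)
}
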