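# Binary classification evaluation: confusion counts, ACC/PR/RE/F1/MCC
# and rank-based AUC.

#' Confusion counts
#'
#' @param truth,pred Equal-length binary vectors (logical or 0/1); `pred`
#'   positive means predicted positive.
#' @return Named list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  truth <- as.logical(truth); pred <- as.logical(pred)
  list(tp = sum(truth & pred), tn = sum(!truth & !pred),
       fp = sum(!truth & pred), fn = sum(truth & !pred))
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator in ", what, "; returning 0")
    return(0)
  }
  num / den
}

#' Classification scores
#'
#' Accuracy, precision, recall, F1 and Matthews correlation coefficient
#' from confusion counts.  Any score with a zero denominator is defined
#' as 0 (with a warning).
#'
#' @param counts List from [confusion_counts()].
#' @return One-row tibble with columns `acc`, `pr`, `re`, `f1`, `mcc`.
#' @export
classification_scores <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  acc <- .safe_ratio(tp + tn, n, "ACC")
  pr <- .safe_ratio(tp, tp + fp, "PR")
  re <- .safe_ratio(tp, tp + fn, "RE")
  f1 <- .safe_ratio(2 * tp, 2 * tp + fp + fn, "F1")
  mcc_den <- sqrt(as.double(tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  mcc <- .safe_ratio(as.double(tp) * tn - as.double(fn) * fp, mcc_den, "MCC")
  tibble::tibble(acc = acc, pr = pr, re = re, f1 = f1, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param truth Binary vector, `TRUE`/1 = positive.
#' @param prob Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(truth, prob) {
  truth <- as.logical(truth)
  if (length(truth) != length(prob)) stop("length mismatch")
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) stop("both classes must be present for AUC")
  r <- rank(prob)
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate predicted probabilities against binary truth
#'
#' @param truth Binary vector.
#' @param prob Predicted probabilities.
#' @param threshold Decision threshold; positive iff `prob > threshold`.
#' @return One-row tibble `acc`, `pr`, `re`, `f1`, `mcc`, `auc`.
#' @export
evaluate_predictions <- function(truth, prob, threshold = 0.5) {
  sc <- classification_scores(confusion_counts(truth, prob > threshold))
  sc$auc <- auc_score(truth, prob)
  sc
}
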