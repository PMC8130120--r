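# Binary-classifier evaluation: confusion-matrix scalars (sensitivity,
# specificity, precision, F1, accuracy, Matthews correlation) and ROC/AUC.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts; their sum must be >= 1.
#' @return A named list of class `hs_confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn >= 1)
  structure(list(TP = as.integer(tp), FP = as.integer(fp),
                 TN = as.integer(tn), FN = as.integer(fn)),
            class = "hs_confusion")
}

#' Scalar classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, `F1 = 2*SEN*PRE/(SEN+PRE)`, accuracy, and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric with a zero denominator is `NA`; MCC is 0 by convention when any
#' marginal total is 0.
#'
#' @param counts An `hs_confusion` from [confusion_counts()].
#' @return Named numeric vector `SEN`, `SPE`, `PRE`, `F1`, `ACC`, `MCC`.
#' @export
scalar_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sen <- div(tp, tp + fn)
  spe <- div(tn, tn + fp)
  pre <- div(tp, tp + fp)
  f1 <- if (is.na(sen) || is.na(pre) || (sen + pre) == 0) NA_real_ else
    2 * sen * pre / (sen + pre)
  acc <- div(tp + tn, tp + tn + fp + fn)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(marg))
  c(SEN = sen, SPE = spe, PRE = pre, F1 = f1, ACC = acc, MCC = mcc)
}

#' Infer confusion counts from printed rates and class sizes
#'
#' Given a reported sensitivity and specificity (rounded to some number of
#' decimals) together with the exact class composition, recovers the integer
#' confusion matrix: TP is the integer in `0..n_pos` whose ratio is closest
#' to the printed sensitivity, likewise TN for specificity.
#'
#' @param sen,spe Printed sensitivity and specificity.
#' @param n_pos,n_neg Number of positives / negatives.
#' @return An `hs_confusion`.
#' @export
confusion_from_rates <- function(sen, spe, n_pos, n_neg) {
  tp <- which.min(abs((0:n_pos) / n_pos - sen)) - 1L
  tn <- which.min(abs((0:n_neg) / n_neg - spe)) - 1L
  confusion_counts(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' ROC curve and area under it
#'
#' AUC is the Mann-Whitney concordance probability (ties between a positive
#' and a negative score credited 0.5), computed from midranks; the ROC curve
#' is the threshold sweep over unique scores, and its trapezoidal area equals
#' the rank-based AUC.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1, logical or factor; positive = 1).
#' @return List of class `hs_roc`: `points` (data frame `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- ifelse(to_pm1(labels) > 0, 1, 0)
  if (length(unique(y)) < 2) stop("ROC needs both classes present")
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n_neg, numeric(1))
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))

  structure(list(points = points, auc = auc), class = "hs_roc")
}

# trapezoidal area under the ROC polygon; cross-check for the rank AUC
trapezoid_auc <- function(roc) {
  p <- roc$points
  p <- rbind(p, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  sum(diff(p$fpr) * (head(p$tpr, -1) + p$tpr[-1]) / 2)
}

#' Full evaluation report for scored predictions
#'
#' @param scores Prediction scores in `[0, 1]` (or any monotone score).
#' @param labels Binary reference labels.
#' @param threshold Classification threshold on `scores` (default 0.5).
#' @return List of class `hs_eval`: `counts`, `metrics` (3-decimal
#'   presentation in `$table`, raw in `$metrics`), `roc`, `auc`.
#' @export
eval_report <- function(scores, labels, threshold = 0.5) {
  y <- ifelse(to_pm1(labels) > 0, 1, 0)
  pred <- as.integer(scores >= threshold)
  counts <- confusion_counts(tp = sum(pred == 1 & y == 1),
                             fp = sum(pred == 1 & y == 0),
                             tn = sum(pred == 0 & y == 0),
                             fn = sum(pred == 0 & y == 1))
  metrics <- scalar_metrics(counts)
  roc <- roc_auc(scores, labels)
  structure(list(counts = counts, metrics = metrics,
                 table = round_half_up(c(metrics, AUC = roc$auc), 3),
                 roc = roc, auc = roc$auc),
            class = "hs_eval")
}

#' @export
print.hs_eval <- function(x, ...) {
  cat("<hs_eval> TP", x$counts$TP, "FP", x$counts$FP,
      "TN", x$counts$TN, "FN", x$counts$FN, "\n")
  print(x$table)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `hs_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    counts = report$counts[c("TP", "FP", "TN", "FN")],
    metrics = as.list(report$metrics),
    auc = report$auc,
    roc = report$roc$points
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
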