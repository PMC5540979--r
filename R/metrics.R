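#' Confusion counts for a two-class problem
#'
#' The positive class is `+1` (normal): TP = correctly identified normal
#' units, TN = correctly identified fatigue units, FP = fatigue units
#' called normal, FN = normal units called fatigue.
#'
#' @param y_true,y_pred label vectors in `{-1, +1}`, equal length.
#' @return A list of class `eb_confusion` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch between y_true and y_pred", call. = FALSE)
  }
  y_true <- check_labels(y_true)
  y_pred <- check_labels(y_pred)
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == -1 & y_pred == -1),
                 FP = sum(y_true == -1 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == -1)),
            class = "eb_confusion")
}

#' Scalar classification metrics from confusion counts
#'
#' `ERR = (FP + FN) / total`, `Precision = TP / (TP + FP)`,
#' `Recall = TP / (TP + FN)`, `F1` the harmonic mean of precision and
#' recall, and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Degenerate denominators (e.g. no predicted positives) return 0 and the
#' affected metrics are listed in `attr(, "degenerate")`.
#'
#' @param counts an `eb_confusion` or a list with `TP`, `TN`, `FP`, `FN`.
#' @return One-row tibble with `err`, `precision`, `recall`, `f1`, `mcc`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  stopifnot(total > 0)
  flagged <- character(0)
  safe_div <- function(num, den, what) {
    if (den <= 0) {
      flagged <<- c(flagged, what)
      0
    } else num / den
  }
  err <- (FP + FN) / total
  precision <- safe_div(TP, TP + FP, "precision")
  recall <- safe_div(TP, TP + FN, "recall")
  f1 <- if (precision + recall <= 0) {
    flagged <- c(flagged, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- safe_div(TP * TN - FP * FN, mcc_den, "mcc")
  mcc <- min(max(mcc, -1), 1)  # guard rounding at exact +/-1 corners
  out <- tibble(err = err, precision = precision, recall = recall,
                f1 = f1, mcc = mcc)
  attr(out, "degenerate") <- unique(flagged)
  out
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique score values (descending;
#' tied scores collapse into a single step), producing an ROC that starts
#' at (0, 0) and ends at (1, 1), with AUC by the trapezoidal rule. Equals
#' the Mann-Whitney pair-ordering probability with ties counted 1/2.
#'
#' @param y_true labels in `{-1, +1}` (+1 = normal = positive); both
#'   classes must be present.
#' @param scores continuous classifier scores (larger = more positive).
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- check_labels(y_true)
  stopifnot(length(y_true) == length(scores))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == -1)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present for an ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  # group tied scores into single steps
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == -1)[last]
  roc <- tibble(threshold = c(Inf, s[last]),
                fpr = c(0, fp / n_neg),
                tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

#' Paired t-test between two runs of a metric
#'
#' Classic paired t-test with `n - 1` degrees of freedom (two-sided),
#' via [stats::t.test()]. All-equal inputs give `t = 0, p = 1`; a nonzero
#' mean difference with zero variance is reported as `p = 0` with a
#' `degenerate` attribute.
#'
#' @param a,b equal-length numeric vectors (one entry per run).
#' @return One-row tibble with `statistic`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2L) stop("need at least two paired runs", call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    return(tibble(statistic = 0, df = length(d) - 1L, p_value = 1,
                  mean_diff = 0))
  }
  if (sd(d) == 0) {
    out <- tibble(statistic = Inf * sign(mean(d)), df = length(d) - 1L,
                  p_value = 0, mean_diff = mean(d))
    attr(out, "degenerate") <- "zero-variance differences"
    return(out)
  }
  ht <- t.test(a, b, paired = TRUE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_diff = unname(ht$estimate))
}
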