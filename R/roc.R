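# ROC curve and AUC with exact tie handling: the trapezoidal area over
# the tie-grouped curve equals the Mann-Whitney pair-counting statistic.

#' ROC curve and area under it
#'
#' Thresholds sweep the distinct score values from high to low; tied
#' scores move along the curve's diagonal segment, so the trapezoidal area
#' equals `(#{pos-neg pairs with score_pos > score_neg} + ties / 2) /
#' (n1 * n0)` exactly.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return Object of class `roc_result`: list with `fpr`, `tpr` (curve
#'   points from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # collapse tied scores into single curve vertices
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(1 - l)[last_of_tie]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC with", length(x$fpr), "points, AUC =", format(x$auc), "\n")
  invisible(x)
}
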