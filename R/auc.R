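#' Area under the ROC curve by the rank statistic
#'
#' Computes the AUC as the Mann-Whitney U statistic rescaled to `[0, 1]`:
#' the probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half. Identical to trapezoidal
#' integration of the ROC curve.
#'
#' @param scores Numeric prediction scores (higher means more likely
#'   positive).
#' @param labels Binary labels (0/1 or logical), same length as `scores`.
#' @return The AUC, a number in `[0, 1]`.
#' @export
#' @examples
#' auc_rank(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1: perfect separation
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stopf("`scores` and `labels` must have the same length",
          class = "depnet_argument_error")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stopf("`labels` must be binary (0/1)", class = "depnet_argument_error")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stopf("AUC needs at least one positive and one negative",
          class = "depnet_argument_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Returns the (false positive rate, true positive rate) points of the ROC
#' curve swept over every distinct score threshold, suitable for plotting or
#' trapezoidal integration.
#'
#' @inheritParams auc_rank
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, ordered from the
#'   (0, 0) corner to (1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  labels <- labels[ord]
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  tp <- cumsum(labels)
  fp <- cumsum(1L - labels)
  last <- !duplicated(scores, fromLast = TRUE)  # one point per threshold
  tibble(
    threshold = c(Inf, scores[last]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1)
  )
}

# Trapezoidal integral of a ROC polyline; used in tests as the independent
# cross-check of auc_rank.
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}
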