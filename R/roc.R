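#' ROC curve and AUC for a continuous marker
#'
#' Empirical ROC analysis of a score against a binary label, with the AUC
#' computed by the Mann-Whitney construction (ties between a positive and a
#' negative score count 1/2), so `auc` is exactly the probability that a
#' random positive outscores a random negative. The operating threshold is
#' chosen by Youden's J (sensitivity + specificity - 1); exact J ties are
#' broken toward the higher-specificity point. A subject is called positive
#' when `score >= threshold`.
#'
#' @param scores numeric vector, finite.
#' @param labels binary vector (0/1, logical, or two-level factor); 1/TRUE is
#'   the positive class.
#' @return object of class `pme_roc`: list with `auc`, `threshold`,
#'   `sensitivity`, `specificity` (at the threshold), and `curve`, a
#'   data.frame of (`threshold`, `fpr`, `tpr`) beginning at (0,0) and ending
#'   at (1,1).
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1: perfect separation
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("degenerate labels: both classes required")

  r <- rank(scores)  # midranks
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ## curve over descending unique cutoffs; positive call: score >= cutoff
  cuts <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(cuts, function(t) sum(scores >= t & labels == 1), 0)
  fp <- vapply(cuts, function(t) sum(scores >= t & labels == 0), 0)
  curve <- data.frame(threshold = c(Inf, cuts),
                      fpr = c(0, fp / n0),
                      tpr = c(0, tp / n1))

  j <- curve$tpr - curve$fpr
  best <- which(j == max(j))
  best <- best[which.min(curve$fpr[best])]  # ties -> higher specificity
  structure(list(auc = auc,
                 threshold = curve$threshold[best],
                 sensitivity = curve$tpr[best],
                 specificity = 1 - curve$fpr[best],
                 curve = curve),
            class = "pme_roc")
}

#' @export
print.pme_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f; Youden threshold = %.4g (sens %.3f, spec %.3f)\n",
              x$auc, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) > 2) stop("labels must be binary")
    labels <- as.integer(labels == levels(droplevels(labels))[2])
  } else if (is.logical(labels)) {
    labels <- as.integer(labels)
  }
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  labels
}
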