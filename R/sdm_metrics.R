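#' Area under the ROC curve
#'
#' Probability that a randomly chosen presence scores above a randomly
#' chosen absence, ties counting one half — computed with the average-rank
#' (Mann-Whitney) identity, which is exactly the pairwise-concordance
#' definition.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (1 = presence).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)                       # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stop("undefined metric: both classes must be present")
  invisible(TRUE)
}

#' True skill statistic at a fixed threshold
#'
#' TSS = sensitivity + specificity - 1 of the classifier that calls a
#' record a presence when its score is `>= threshold`.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (`>=` rule).
#' @return TSS in `[-1, 1]`.
#' @export
tss_at_threshold <- function(scores, labels, threshold) {
  check_two_classes(labels)
  pred <- as.integer(scores >= threshold)
  sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
  spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

#' TSS-optimal decision threshold
#'
#' Scans the candidate thresholds where the confusion matrix can change:
#' the smallest distinct score (everything positive) and the midpoints
#' between consecutive distinct sorted scores. Ties in maximal TSS break
#' toward the smallest threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return List with `threshold` and the `tss` it attains.
#' @export
optimize_threshold <- function(scores, labels) {
  check_two_classes(labels)
  ds <- sort(unique(scores))
  cand <- if (length(ds) == 1) ds else c(ds[1], (ds[-1] + ds[-length(ds)]) / 2)
  tss <- vapply(cand, function(th) tss_at_threshold(scores, labels, th),
                numeric(1))
  best <- which.max(tss)                  # which.max takes the first maximum
  list(threshold = cand[best], tss = tss[best])
}
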