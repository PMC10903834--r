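# True skill statistic (TSS) evaluation and threshold optimisation.

#' True skill statistic of thresholded predictions
#'
#' TSS = sensitivity + specificity - 1 of the confusion matrix obtained by
#' classifying `predictions >= threshold` as presence.  Ranges over
#' `[-1, 1]`; 0 means no skill.
#'
#' @param predictions numeric scores.
#' @param labels binary labels (1 = presence, 0 = background/absence).
#' @param threshold classification cutoff.
#' @return TSS value.
#' @export
compute_tss <- function(predictions, labels, threshold) {
  stopifnot(length(predictions) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2) {
    stop("TSS is undefined when only one class is present")
  }
  pred_pos <- predictions >= threshold
  tp <- sum(pred_pos & labels == 1L)
  fn <- sum(!pred_pos & labels == 1L)
  tn <- sum(!pred_pos & labels == 0L)
  fp <- sum(pred_pos & labels == 0L)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' TSS-maximising classification threshold
#'
#' Scans the midpoints between consecutive sorted unique prediction values
#' (so for separable scores the threshold lies mid-gap) and returns the
#' threshold with maximal TSS; ties are broken by the smallest threshold.
#'
#' @inheritParams compute_tss
#' @return list with `threshold` and `tss`.
#' @export
find_optimal_threshold <- function(predictions, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("TSS is undefined when only one class is present")
  }
  u <- sort(unique(predictions))
  if (length(u) == 1) {
    return(list(threshold = u, tss = 0))
  }
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  # counts of each class at each unique score, cumulated left to right
  pos_at <- vapply(split(labels, match(predictions, u)), sum, 0)
  cnt_at <- vapply(split(labels, match(predictions, u)), length, 0)
  idx <- as.integer(names(pos_at))
  pos_le <- neg_le <- numeric(length(u))
  pos_le[idx] <- pos_at
  neg_le[idx] <- cnt_at - pos_at
  pos_le <- cumsum(pos_le)
  neg_le <- cumsum(neg_le)
  k <- seq_len(length(u) - 1)
  tss <- neg_le[k] / nneg - pos_le[k] / npos
  best <- which.max(tss)  # first max = smallest threshold
  list(threshold = (u[best] + u[best + 1]) / 2, tss = tss[best])
}
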