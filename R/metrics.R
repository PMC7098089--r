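#' Average precision (area under the precision-recall curve)
#'
#' Computes AP as the sum over threshold steps of precision times the recall
#' increment. Tied scores share one threshold block (all tied items enter
#' together), so a constant scorer has AP exactly equal to the positive
#' prevalence and, without ties, AP is the mean over positives of the
#' precision at each positive's rank.
#'
#' @param labels 0/1 vector (or logical); at least one positive required.
#' @param scores numeric scores, higher means more positive.
#' @return scalar AP in `[0, 1]`.
#' @export
average_precision <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  P <- sum(labels)
  if (P == 0) stop("average precision is undefined without positive labels")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  # block boundaries: last index of each run of tied scores
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[last]
  n_at <- last
  rec <- tp / P
  prec <- tp / n_at
  sum(diff(c(0, rec)) * prec)
}

#' Score threshold with equal precision and recall
#'
#' Scans all observed scores as candidate thresholds (prediction is positive
#' when `score >= threshold`) and returns the one minimizing
#' `|precision - recall|`; ties are broken toward higher recall (the lower
#' threshold).
#'
#' @param labels 0/1 vector with at least one positive.
#' @param scores numeric scores.
#' @return scalar threshold.
#' @export
equal_pr_threshold <- function(labels, scores) {
  labels <- as.numeric(labels)
  P <- sum(labels)
  if (P == 0) stop("equal_pr_threshold requires at least one positive")
  cand <- sort(unique(scores), decreasing = TRUE)
  best <- cand[1]
  best_gap <- Inf
  best_rec <- -1
  for (t in cand) {
    pos <- scores >= t
    tp <- sum(labels[pos])
    prec <- tp / sum(pos)
    rec <- tp / P
    gap <- abs(prec - rec)
    if (gap < best_gap - 1e-12 ||
        (abs(gap - best_gap) <= 1e-12 && rec > best_rec)) {
      best_gap <- gap
      best <- t
      best_rec <- rec
    }
  }
  best
}

#' Linear-interpolation percentile
#'
#' Thin wrapper over the standard linear-interpolation convention
#' (`stats::quantile` type 7), pinned here so every percentile in the
#' package (span caps, disruption cutoffs) uses the same rule.
#'
#' @param x numeric vector.
#' @param p probability in `[0, 1]`.
#' @return scalar percentile.
#' @export
percentile <- function(x, p) {
  if (length(x) == 0L) stop("percentile of an empty vector")
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}
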