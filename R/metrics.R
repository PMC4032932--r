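#' Area under the ROC curve of a realized ranking
#'
#' Computed by the rank-sum formulation: the fraction of (positive,
#' negative) pairs in which the positive precedes the negative. Equals the
#' probability that a uniformly random positive outranks a uniformly random
#' negative. Ties in scores are resolved upstream by the deterministic
#' ordering of [rank_candidates()], so the metric is evaluated on the
#' realized order. A perfect ranking scores 1; a random one 0.5 in
#' expectation.
#'
#' @param ranking Character vector of items in rank order (best first).
#' @param positives Character vector (or set) of positive items.
#' @return AUROC in `[0, 1]`, or `NA` when there are no positives or no
#'   negatives in the ranking.
#' @export
auroc <- function(ranking, positives) {
  pos_rank <- which(ranking %in% positives)
  P <- length(pos_rank)
  N <- length(ranking) - P
  if (P == 0L || N == 0L) return(NA_real_)
  concordant <- sum(N - (pos_rank - seq_len(P)))
  concordant / (P * N)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the mean, over positives taken in rank
#' order, of the precision at each positive's rank. No interpolation is
#' applied. A random ranking scores close to P/(P+N) in expectation.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`, or `NA` when there are no positives or no
#'   negatives.
#' @export
aupr <- function(ranking, positives) {
  pos_rank <- which(ranking %in% positives)
  P <- length(pos_rank)
  if (P == 0L || length(ranking) == P) return(NA_real_)
  mean(seq_len(P) / pos_rank)
}

#' Precision at a fixed recall level
#'
#' Precision at the smallest rank cutoff whose recall reaches at least `r`.
#' With ten or fewer positives and the default `r = 0.10` this is the
#' precision at the first retrieved positive. The cutoff always exists
#' because recall reaches 1 at the full list.
#'
#' @inheritParams auroc
#' @param r Recall fraction to reach (default 0.10).
#' @return Precision in `[0, 1]`, or `NA` when there are no positives or no
#'   negatives.
#' @export
precision_at_recall <- function(ranking, positives, r = 0.10) {
  pos_rank <- which(ranking %in% positives)
  P <- length(pos_rank)
  if (P == 0L || length(ranking) == P) return(NA_real_)
  k <- max(1L, ceiling(r * P))
  k / pos_rank[k]
}

#' All three ranking metrics of one fold
#'
#' @inheritParams auroc
#' @return Named numeric vector `auroc`, `aupr`, `p10r` (each `NA` when
#'   undefined, i.e. no positives or no negatives in the ranking).
#' @export
fold_metrics <- function(ranking, positives) {
  c(auroc = auroc(ranking, positives),
    aupr = aupr(ranking, positives),
    p10r = precision_at_recall(ranking, positives, 0.10))
}
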