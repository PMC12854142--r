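#' Ranks of true breeding values induced by the predicted ordering
#'
#' Orders candidates by decreasing GEBV and reports, for the first k of
#' them, the rank (1 = largest) each holds in the true breeding values.
#' A perfectly informative prediction yields (1, 2, ..., k). Ties in
#' either vector are broken by ascending candidate index; simulated
#' values are continuous so real ties have measure zero.
#'
#' @param tbv,gebv numeric vectors of equal length nc.
#' @param k evaluation depth (1 <= k <= nc).
#' @return Integer vector pi of length k with distinct entries in 1..nc.
#' @export
tbv_rank_permutation <- function(tbv, gebv, k) {
  nc <- length(tbv)
  stopifnot(length(gebv) == nc, k >= 1L)
  if (k > nc) stop("k must not exceed the number of candidates")
  tbv_rank <- integer(nc)
  tbv_rank[order(-tbv, seq_len(nc))] <- seq_len(nc)
  top_by_gebv <- order(-gebv, seq_len(nc))[seq_len(k)]
  tbv_rank[top_by_gebv]
}

#' Normalized discounted cumulative gain at depth k
#'
#' Ratio of the discounted cumulative gain of the predicted ordering to
#' that of the ideal ordering, both truncated at k, with linear gain
#' f(v) = v and discount d(i) = 1 / log2(i + 1). With positive gains the
#' score lies in [0, 1] and equals 1 exactly when the predicted top-k
#' ordering matches the true one; negative gains void the range claim and
#' trigger a warning.
#'
#' @inheritParams tbv_rank_permutation
#' @return Scalar NDCG value.
#' @export
ndcg_at_k <- function(tbv, gebv, k) {
  pi <- tbv_rank_permutation(tbv, gebv, k)
  v_sorted <- tbv[order(-tbv, seq_along(tbv))]
  disc <- 1 / log2(seq_len(k) + 1)
  if (any(v_sorted[pi] < 0) || any(v_sorted[seq_len(k)] < 0))
    warning("negative gains among the top-k; NDCG may fall outside [0, 1]")
  ideal <- sum(v_sorted[seq_len(k)] * disc)
  if (ideal == 0) stop("ideal DCG is zero (all-zero gains)")
  sum(v_sorted[pi] * disc) / ideal
}

#' Spearman rank correlation of the top-k predicted ordering
#'
#' Pearson correlation of the pairs (i, pi_i) for i = 1..k, where pi is
#' the true-rank permutation of the top-k candidates by GEBV: +1 when the
#' predicted order of the selected k preserves their true order, -1 when
#' it reverses it.
#'
#' @inheritParams tbv_rank_permutation
#' @param k evaluation depth (>= 2).
#' @return Scalar in [-1, 1].
#' @export
src_at_k <- function(tbv, gebv, k) {
  stopifnot(k >= 2L)
  pi <- tbv_rank_permutation(tbv, gebv, k)
  if (stats::sd(pi) == 0) stop("zero variance in rank permutation")
  stats::cor(seq_len(k), pi)
}

#' Rank-sum ratio at depth k
#'
#' Ratio of the ideal rank sum 1 + 2 + ... + k to the realized sum of
#' true ranks of the top-k candidates by GEBV. Equals 1 exactly when the
#' predicted top-k set coincides with the true top-k set (in any order)
#' and decreases toward 0 as the prediction picks truly worse candidates.
#'
#' @inheritParams tbv_rank_permutation
#' @return Scalar in (0, 1].
#' @export
rs_ratio_at_k <- function(tbv, gebv, k) {
  pi <- tbv_rank_permutation(tbv, gebv, k)
  sum(seq_len(k)) / sum(pi)
}

#' Relative improvement percentage over the random baseline
#'
#' @param mean_method mean metric value of a construction method.
#' @param mean_random mean metric value of the random-sampling baseline
#'   (non-zero).
#' @return 100 * (mean_method - mean_random) / mean_random.
#' @export
rip <- function(mean_method, mean_random) {
  if (any(mean_random == 0)) stop("random baseline mean is zero")
  100 * (mean_method - mean_random) / mean_random
}
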