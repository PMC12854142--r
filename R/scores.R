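#' Code marker calls into raw additive and dominance scores
#'
#' The additive score counts major alleles symmetrically around the
#' heterozygote: AA is 1, AB is 0, BB is -1. The dominance score indicates
#' the heterozygote: AB is 1, the homozygotes are 0. These are the
#' classical codings used for additive + dominance genomic relationship
#' matrices in hybrid populations.
#'
#' @param g a [genotype_table()].
#' @return List with integer matrices \code{WA} and \code{WD}, both
#'   hybrids x markers.
#' @examples
#' g <- genotype_table(matrix(c("AA", "AB", "BB", "AB"), 2, 2))
#' code_markers(g)$WA
#' @export
code_markers <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  calls <- g$calls
  WA <- matrix(0L, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  WA[calls == "AA"] <- 1L
  WA[calls == "BB"] <- -1L
  WD <- matrix(0L, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  WD[calls == "AB"] <- 1L
  list(WA = WA, WD = WD)
}

#' Standardize raw marker scores column-wise
#'
#' Each retained column is centered by its sample mean and divided by its
#' sample standard deviation (n - 1 denominator). Columns with zero
#' variance carry no information for the corresponding effect (for the
#' dominance score this happens whenever no sampled cross segregates at
#' the locus) and are dropped and reported.
#'
#' @param W numeric matrix of raw scores, hybrids in rows.
#' @return List with \code{X} (standardized matrix over retained columns),
#'   \code{retained} and \code{dropped} (column indices of \code{W}).
#' @export
standardize_scores <- function(W) {
  stopifnot(is.matrix(W), nrow(W) >= 2L)
  W <- W * 1.0
  s <- apply(W, 2L, stats::sd)
  keep <- s > 0
  if (!any(keep)) stop("all columns have zero variance; no usable markers")
  X <- scale(W[, keep, drop = FALSE], center = TRUE, scale = TRUE)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, retained = unname(which(keep)), dropped = unname(which(!keep)))
}

#' Build the standardized additive and dominance score pair
#'
#' Convenience wrapper: codes the genotype table and standardizes each
#' score matrix separately, keeping per-matrix bookkeeping of dropped
#' (zero-variance) markers.
#'
#' @param g a [genotype_table()].
#' @return An object of class \code{score_pair}: list with \code{XA},
#'   \code{XD}, \code{retained_A}, \code{retained_D}, \code{dropped_A},
#'   \code{dropped_D}.
#' @export
marker_scores <- function(g) {
  w <- code_markers(g)
  a <- standardize_scores(w$WA)
  d <- standardize_scores(w$WD)
  structure(list(XA = a$X, XD = d$X,
                 retained_A = a$retained, retained_D = d$retained,
                 dropped_A = a$dropped, dropped_D = d$dropped),
            class = "score_pair")
}

#' @export
print.score_pair <- function(x, ...) {
  cat(sprintf(
    "score_pair: %d hybrids; %d additive / %d dominance markers retained (%d / %d dropped)\n",
    nrow(x$XA), ncol(x$XA), ncol(x$XD),
    length(x$dropped_A), length(x$dropped_D)))
  invisible(x)
}

#' Genomic relationship matrix from standardized scores
#'
#' K = X X' / p with p the number of retained columns of X. With
#' standardized columns this gives trace(K) = n - 1 and zero row sums.
#'
#' @param X standardized score matrix (hybrids x markers).
#' @param p_used number of retained columns; defaults to \code{ncol(X)}.
#' @return Symmetric n x n matrix.
#' @export
kinship <- function(X, p_used = ncol(X)) {
  stopifnot(is.matrix(X))
  if (p_used == 0L) stop("p_used must be positive: no markers retained")
  tcrossprod(X) / p_used
}

#' Additive and dominance kinship pair for a candidate population
#'
#' @param scores a [marker_scores()] result (or a genotype_table, which is
#'   scored first).
#' @return Object of class \code{kinship_pair}: list with \code{KA} and
#'   \code{KD}.
#' @export
kinship_pair <- function(scores) {
  if (inherits(scores, "genotype_table")) scores <- marker_scores(scores)
  stopifnot(inherits(scores, "score_pair"))
  structure(list(KA = kinship(scores$XA), KD = kinship(scores$XD)),
            class = "kinship_pair")
}

#' @export
print.kinship_pair <- function(x, ...) {
  cat(sprintf("kinship_pair: %d x %d (trace KA = %.4f, trace KD = %.4f)\n",
              nrow(x$KA), ncol(x$KA),
              sum(diag(x$KA)), sum(diag(x$KD))))
  invisible(x)
}

#' Principal-component reduction of the merged score matrix
#'
#' Replaces the merged additive + dominance score matrix [XA, XD] by the
#' scores on its leading principal directions, keeping the smallest number
#' of components whose cumulative explained variance exceeds the
#' threshold. The basis is computed once from the full candidate
#' population; training-set rows used by subset criteria are row subsets
#' of the returned score matrix, so the criterion stays comparable across
#' candidate subsets.
#'
#' @param XA,XD standardized score matrices with matching row counts.
#' @param threshold cumulative explained-variance target in (0, 1];
#'   default 0.99.
#' @return Object of class \code{pc_scores}: list with \code{Z}
#'   (candidates x m component scores), \code{m}, and
#'   \code{explained_cumvar}.
#' @export
pc_reduce <- function(XA, XD, threshold = 0.99) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must be a single value in (0, 1]")
  X <- cbind(XA, XD)
  X <- sweep(X, 2L, colMeans(X))   # already centered for standardized input
  sv <- svd(X)
  ev <- sv$d^2
  cum <- cumsum(ev) / sum(ev)
  m <- which(cum > threshold - 1e-12)[1L]
  if (is.na(m)) m <- length(ev)
  Z <- sv$u[, seq_len(m), drop = FALSE] %*%
    diag(sv$d[seq_len(m)], m, m)
  rownames(Z) <- rownames(XA)
  structure(list(Z = Z, m = m, explained_cumvar = cum[m]),
            class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  cat(sprintf("pc_scores: %d x %d (cumulative explained variance %.4f)\n",
              nrow(x$Z), x$m, x$explained_cumvar))
  invisible(x)
}

#' Per-genotype dominance variance profile
#'
#' The genomic variance attributable to dominance for genotype i is
#' sigmaD2 * KD[i, i]; its distribution over a population indicates how
#' strongly dominance is expressed (the quantity histogrammed when
#' comparing crops).
#'
#' @param KD dominance kinship matrix.
#' @param sigmaD2 dominance variance component (>= 0).
#' @return Numeric vector of length \code{nrow(KD)}.
#' @export
dominance_variance_profile <- function(KD, sigmaD2) {
  stopifnot(is.matrix(KD), sigmaD2 >= 0)
  unname(sigmaD2 * diag(KD))
}
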