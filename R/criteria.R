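#' Training set container
#'
#' A training set is a sorted set of distinct candidate indices plus
#' provenance: the construction method, the criterion value it achieved
#' (if any), and the RNG seed used (if any).
#'
#' @param indices integer vector of candidate indices (1-based).
#' @param nc candidate population size.
#' @param method character tag.
#' @param criterion_value optional scalar.
#' @param seed optional integer.
#' @return Object of class \code{training_set}.
#' @export
training_set <- function(indices, nc, method = "manual",
                         criterion_value = NULL, seed = NULL) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 1L || any(indices < 1L) || any(indices > nc))
    stop("training set indices must be distinct values in 1..nc")
  structure(list(indices = indices, nt = length(indices), nc = nc,
                 method = method, criterion_value = criterion_value,
                 seed = seed),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set (%s): nt = %d of nc = %d", x$method, x$nt, x$nc))
  if (!is.null(x$criterion_value))
    cat(sprintf(", criterion = %.6g", x$criterion_value))
  cat("\n")
  invisible(x)
}

as_indices <- function(train) {
  if (inherits(train, "training_set")) train$indices else as.integer(train)
}

#' Ridge-regression MSPE criterion for a candidate training set
#'
#' Evaluates the simplified mean squared prediction error of a ridge
#' predictor of all candidate scores from the training subset:
#' \deqn{Tr[X_c A A' X_c'] + Tr[(X_c - X_c A X_t)(X_c - X_c A X_t)']}
#' with \eqn{A = X_t'(X_t X_t' + \lambda I)^{-1}}, where \eqn{X_c} are the
#' candidate-population score rows (typically PC scores) and \eqn{X_t}
#' the training-set rows. The first trace is the prediction variance, the
#' second the squared bias of the ridge fit. Lower is better. This
#' simplified form is an affine transform of the mean squared prediction
#' error itself (MSPE = 1 + value / nc), so both are minimized by the
#' same subset.
#'
#' The nt x nt ridge system is solved rather than inverted.
#'
#' @param Z a [pc_reduce()] result or a numeric score matrix
#'   (candidates x components).
#' @param train a [training_set()] or index vector.
#' @param lambda ridge regularization parameter (> 0); default 1.
#' @return Scalar criterion value.
#' @export
mspe_ridge_v2 <- function(Z, train, lambda = 1) {
  if (inherits(Z, "pc_scores")) Z <- Z$Z
  stopifnot(is.matrix(Z), lambda > 0)
  idx <- as_indices(train)
  stopifnot(length(idx) >= 1L, all(idx >= 1L), all(idx <= nrow(Z)))
  Xt <- Z[idx, , drop = FALSE]
  nt <- nrow(Xt)
  S <- tcrossprod(Xt) + diag(lambda, nt)
  # B = Xc A = Xc Xt' S^{-1}
  B <- t(solve(S, Xt %*% t(Z)))
  resid <- Z - B %*% Xt
  sum(B * B) + sum(resid * resid)
}

#' Heuristic mean coefficient of determination of a training set
#'
#' For each candidate i the squared correlation between its true and
#' BLUP-predicted genotypic value is \eqn{A_i / B_i}, where \eqn{A_i} is
#' the i-th diagonal element of
#' \eqn{G_{ct} (M_t G_t + I)^{-1} M_t G_{ct}'} and \eqn{B_i} the i-th
#' diagonal element of the candidate covariance kernel
#' \eqn{\alpha_A K_A + \alpha_D K_D}. The criterion is the sum of these
#' ratios over all candidates (the mean up to the constant factor nc);
#' higher is better. The error variance cancels between numerator and
#' denominator, so only the variance ratios \code{alpha_A}, \code{alpha_D}
#' enter.
#'
#' A candidate with (numerically) zero genomic variance carries no
#' rankable signal; its ratio is taken as 0 with a warning.
#'
#' @param KA,KD candidate-population kinship matrices (or a
#'   \code{kinship_pair} passed as \code{KA}).
#' @param train a [training_set()] or index vector with at least 2 members.
#' @param alpha_A,alpha_D variance ratios sigmaA2/sigmaE2 and
#'   sigmaD2/sigmaE2 (>= 0, not both 0); defaults 1, 1.
#' @return Scalar criterion value (sum of squared correlations).
#' @export
cdmean_v2 <- function(KA, KD = NULL, train, alpha_A = 1, alpha_D = 1) {
  if (inherits(KA, "kinship_pair")) {
    KD <- KA$KD
    KA <- KA$KA
  }
  stopifnot(is.matrix(KA), is.matrix(KD),
            alpha_A >= 0, alpha_D >= 0, alpha_A + alpha_D > 0)
  idx <- as_indices(train)
  nt <- length(idx)
  if (nt < 2L) stop("cdmean_v2 needs a training set of at least 2")
  G <- alpha_A * KA + alpha_D * KD
  Gt <- G[idx, idx, drop = FALSE]
  Gct <- G[, idx, drop = FALSE]
  Mt <- centering_matrix(nt)
  # A_i = diag[ Gct (Mt Gt + I)^{-1} Mt Gct' ]
  W <- solve(Mt %*% Gt + diag(nt), Mt %*% t(Gct))
  A <- rowSums(Gct * t(W))
  B <- diag(G)
  degenerate <- B <= 1e-12
  if (any(degenerate))
    warning(sprintf("%d candidate(s) with zero genomic variance contribute 0",
                    sum(degenerate)))
  ratio <- A / B
  ratio[degenerate] <- 0
  sum(ratio)
}

#' Per-candidate genomic variance scores
#'
#' Score of candidate i is sigmaA2 * KA[i,i] + sigmaD2 * KD[i,i], its own
#' genomic variance under the additive + dominance GBLUP model. The trace
#' of the kernel submatrix of any subset equals the sum of its members'
#' scores, so ranking by score and taking the top nt maximizes the
#' A-optimality-like subset criterion without search.
#'
#' @param KA,KD kinship matrices (or a \code{kinship_pair} as \code{KA}).
#' @param sigmaA2,sigmaD2 variance components (>= 0, not both 0);
#'   defaults 1, 1.
#' @return Numeric score vector of length nc.
#' @export
gv_scores <- function(KA, KD = NULL, sigmaA2 = 1, sigmaD2 = 1) {
  if (inherits(KA, "kinship_pair")) {
    KD <- KA$KD
    KA <- KA$KA
  }
  stopifnot(sigmaA2 >= 0, sigmaD2 >= 0, sigmaA2 + sigmaD2 > 0)
  unname(sigmaA2 * diag(KA) + sigmaD2 * diag(KD))
}
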