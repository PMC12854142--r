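#' Centering matrix of order nt
#'
#' Mt = I - J/nt, the symmetric idempotent projector that removes the
#' mean of a length-nt vector. It absorbs the fixed general mean in the
#' closed-form BLUP formulas, so predictions are invariant to adding a
#' constant to the phenotypes.
#'
#' @param nt order (>= 1).
#' @return nt x nt matrix.
#' @export
centering_matrix <- function(nt) {
  stopifnot(nt >= 1L)
  diag(nt) - matrix(1 / nt, nt, nt)
}

# Combined training-kernel Gt with conditioning guard: adds a small
# diagonal jitter (1e-8 x mean diagonal) only when the estimated condition
# number is extreme; Gt^{-1} enters the training BLUP explicitly and the
# dominance kernel can be near-singular for related hybrids.
combined_kernel <- function(KA, KD, idx, alpha_A, alpha_D) {
  G <- alpha_A * KA + alpha_D * KD
  Gt <- G[idx, idx, drop = FALSE]
  kap <- tryCatch(kappa(Gt, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e12) {
    jit <- 1e-8 * mean(diag(Gt))
    if (!is.finite(jit) || jit <= 0) jit <- 1e-8
    message(sprintf("training kernel ill-conditioned (kappa ~ %.3g); adding %.3g jitter",
                    kap, jit))
    Gt <- Gt + diag(jit, nrow(Gt))
  }
  list(G = G, Gt = Gt)
}

#' BLUP of training-set genotypic values
#'
#' Closed-form best linear unbiased prediction under the GBLUP model
#' y = 1 mu + gA + gD + e with var(g) = sigmaE2 (alpha_A KA + alpha_D KD):
#' \deqn{\hat g_t = (M_t + G_t^{-1})^{-1} M_t y_t}
#' with \eqn{G_t = \alpha_A K_{At} + \alpha_D K_{Dt}}. This is the
#' genetic-effect block of Henderson's mixed-model equations after
#' eliminating the fixed intercept.
#'
#' @param yt phenotype vector for the training set (length nt >= 2).
#' @param train a [training_set()] or index vector.
#' @param KA,KD candidate-population kinships (or a \code{kinship_pair}
#'   as \code{KA}).
#' @param alpha_A,alpha_D variance ratios sigmaA2/sigmaE2, sigmaD2/sigmaE2.
#' @return Numeric vector of length nt.
#' @export
blup_train <- function(yt, train, KA, KD = NULL, alpha_A = 1, alpha_D = 1) {
  if (inherits(KA, "kinship_pair")) {
    KD <- KA$KD
    KA <- KA$KA
  }
  idx <- as_indices(train)
  nt <- length(idx)
  stopifnot(length(yt) == nt, nt >= 2L,
            alpha_A >= 0, alpha_D >= 0, alpha_A + alpha_D > 0)
  Gt <- combined_kernel(KA, KD, idx, alpha_A, alpha_D)$Gt
  Mt <- centering_matrix(nt)
  Gti <- tryCatch(solve(Gt), error = function(e)
    stop("training kernel numerically singular even after jitter"))
  unname(drop(solve(Mt + Gti, Mt %*% yt)))
}

#' BLUP of genotypic values for every candidate
#'
#' Genomic estimated breeding values for the whole candidate population
#' (including training members) from training-set phenotypes:
#' \deqn{\hat g_c = G_{ct} (M_t G_t + I)^{-1} M_t y_t}
#' with \eqn{G_{ct}} the candidate-by-training block of the combined
#' kernel. Restricted to training rows this agrees with
#' \eqn{G_{ct} G_t^{-1} \hat g_t}.
#'
#' @inheritParams blup_train
#' @return Numeric vector of length nc (GEBVs).
#' @export
blup_candidates <- function(yt, train, KA, KD = NULL,
                            alpha_A = 1, alpha_D = 1) {
  if (inherits(KA, "kinship_pair")) {
    KD <- KA$KD
    KA <- KA$KA
  }
  idx <- as_indices(train)
  nt <- length(idx)
  stopifnot(length(yt) == nt, nt >= 2L,
            alpha_A >= 0, alpha_D >= 0, alpha_A + alpha_D > 0)
  gk <- combined_kernel(KA, KD, idx, alpha_A, alpha_D)
  Gct <- gk$G[, idx, drop = FALSE]
  Mt <- centering_matrix(nt)
  unname(drop(Gct %*% solve(Mt %*% gk$Gt + diag(nt), Mt %*% yt)))
}
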