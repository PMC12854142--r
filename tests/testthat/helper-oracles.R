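# Independent oracles: literal dense-matrix transcriptions and classical
# mixed-model routes, kept deliberately naive (explicit inverses, no
# shared code with the package internals).

# Unsimplified ridge MSPE: 1 + (1/nc) {Tr[Xc A A' Xc'] + Tr[(Xc - Xc A Xt)(...)']}
mspe_full_oracle <- function(Z, idx, lambda) {
  Xc <- Z
  Xt <- Z[idx, , drop = FALSE]
  nc <- nrow(Xc)
  A <- t(Xt) %*% solve(Xt %*% t(Xt) + lambda * diag(nrow(Xt)))
  t1 <- sum(diag(Xc %*% A %*% t(A) %*% t(Xc)))
  R <- Xc - Xc %*% A %*% Xt
  1 + (t1 + sum(diag(R %*% t(R)))) / nc
}

# Simplified criterion transcribed directly with explicit inverses.
mspe_v2_oracle <- function(Z, idx, lambda) {
  Xc <- Z
  Xt <- Z[idx, , drop = FALSE]
  A <- t(Xt) %*% solve(Xt %*% t(Xt) + lambda * diag(nrow(Xt)))
  R <- Xc - Xc %*% A %*% Xt
  sum(diag(Xc %*% A %*% t(A) %*% t(Xc))) + sum(diag(R %*% t(R)))
}

# CD criterion from first-principles covariance algebra: the candidate
# BLUP is the linear map L y_t with L = Gct (Mt Gt + I)^-1 Mt; under the
# generative model Var(y_t) = (Gt + I) se2 and Cov(g_c, y_t) = Gct se2,
# so each squared correlation is computed from cov and both variances of
# the linear predictor, not from the printed diagonal identity.
cd_cov_oracle <- function(KA, KD, idx, alpha_A = 1, alpha_D = 1) {
  G <- alpha_A * KA + alpha_D * KD
  nt <- length(idx)
  Gt <- G[idx, idx]
  Gct <- G[, idx, drop = FALSE]
  Mt <- diag(nt) - matrix(1 / nt, nt, nt)
  L <- Gct %*% solve(Mt %*% Gt + diag(nt)) %*% Mt
  cov_gg <- diag(Gct %*% t(L))          # cov(g_c, ghat_c) / se2
  var_ghat <- diag(L %*% (Gt + diag(nt)) %*% t(L))
  var_g <- diag(G)
  sum(cov_gg^2 / (var_g * var_ghat))
}

# Henderson's mixed-model equations for y = 1 mu + g + e with
# Var(g) = Gt se2, Var(e) = I se2: the full coefficient-matrix solve.
henderson_train_oracle <- function(yt, Gt) {
  nt <- length(yt)
  Gi <- solve(Gt)
  A <- rbind(cbind(nt, t(rep(1, nt))),
             cbind(rep(1, nt), diag(nt) + Gi))
  sol <- solve(A, c(sum(yt), yt))
  unname(sol[-1])
}

# Conditional-expectation BLUP for unphenotyped individuals with the
# fixed mean estimated by GLS: ghat_c = Gct V^-1 (y - 1 muhat),
# V = Gt + I.
henderson_candidates_oracle <- function(yt, Gt, Gct) {
  nt <- length(yt)
  V <- Gt + diag(nt)
  Vi <- solve(V)
  one <- rep(1, nt)
  muhat <- drop((t(one) %*% Vi %*% yt) / (t(one) %*% Vi %*% one))
  unname(drop(Gct %*% Vi %*% (yt - one * muhat)))
}
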