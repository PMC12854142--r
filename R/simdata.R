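#' Design of a synthetic hybrid candidate population
#'
#' Describes a factorial crossing scheme between fully homozygous male
#' and female inbred parents, mirroring the structure of elite hybrid
#' breeding panels (the default 15 x 120 layout and a 500-hybrid
#' candidate sample follow the wheat panel convention). Per locus a minor
#' allele frequency is drawn uniformly from \code{[maf_low, maf_high]};
#' each parent is homozygous for the minor allele with that probability.
#'
#' @param n_male,n_female numbers of male and female inbred parents.
#' @param p number of biallelic SNP loci.
#' @param n_hybrids number of crosses sampled (without replacement) from
#'   the n_male x n_female grid.
#' @param maf_low,maf_high minor allele frequency bounds
#'   (0 < maf_low <= maf_high <= 0.5).
#' @param seed integer RNG seed.
#' @return List of class \code{hybrid_design}.
#' @export
hybrid_design <- function(n_male = 15L, n_female = 120L, p = 2000L,
                          n_hybrids = 500L, maf_low = 0.1, maf_high = 0.5,
                          seed = 1L) {
  stopifnot(maf_low > 0, maf_low <= maf_high, maf_high <= 0.5,
            n_male >= 1L, n_female >= 1L, p >= 1L)
  if (n_hybrids > n_male * n_female)
    stop("n_hybrids exceeds the number of possible crosses")
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 p = as.integer(p), n_hybrids = as.integer(n_hybrids),
                 maf_low = maf_low, maf_high = maf_high,
                 seed = as.integer(seed)),
            class = "hybrid_design")
}

#' Simulate hybrid genotypes from inbred parental lines
#'
#' Generates homozygous parental genomes locus by locus and derives each
#' sampled hybrid's genotype from its parents: AA when neither parent
#' carries the minor allele, AB when exactly one does, BB when both do.
#' Loci that come out monomorphic across the sampled hybrids are redrawn
#' up to 10 times and dropped if still monomorphic, so every returned
#' marker segregates.
#'
#' @param design a [hybrid_design()].
#' @return A [genotype_table()] with attributes \code{"male"} and
#'   \code{"female"} giving each hybrid's parents and \code{"maf"} the
#'   drawn allele frequencies of retained loci.
#' @export
simulate_hybrid_genotypes <- function(design = hybrid_design()) {
  stopifnot(inherits(design, "hybrid_design"))
  with_seed(design$seed, {
    cross <- sample.int(design$n_male * design$n_female, design$n_hybrids)
    male <- ((cross - 1L) %% design$n_male) + 1L
    female <- ((cross - 1L) %/% design$n_male) + 1L
    draw_locus <- function() {
      f <- stats::runif(1L, design$maf_low, design$maf_high)
      m_minor <- stats::rbinom(design$n_male, 1L, f)
      w_minor <- stats::rbinom(design$n_female, 1L, f)
      n_minor <- m_minor[male] + w_minor[female]   # 0, 1 or 2 minor parents
      list(f = f, calls = c("AA", "AB", "BB")[n_minor + 1L])
    }
    calls <- matrix(NA_character_, design$n_hybrids, design$p)
    maf <- numeric(design$p)
    keep <- logical(design$p)
    for (j in seq_len(design$p)) {
      for (try in 1:10) {
        loc <- draw_locus()
        if (length(unique(loc$calls)) > 1L) break
      }
      if (length(unique(loc$calls)) > 1L) {
        calls[, j] <- loc$calls
        maf[j] <- loc$f
        keep[j] <- TRUE
      }
    }
    if (!any(keep)) stop("all loci monomorphic; widen the MAF bounds")
    g <- genotype_table(calls[, keep, drop = FALSE])
    attr(g, "male") <- male
    attr(g, "female") <- female
    attr(g, "maf") <- maf[keep]
    g
  })
}

#' Phenotype simulation scenario
#'
#' Fixes the generative GBLUP model parameters: general mean mu, additive
#' variance sigmaA2, dominance-to-additive ratio gamma (so
#' sigmaD2 = gamma * sigmaA2) and broad-sense heritability h2, from which
#' the error variance is derived as
#' sigmaE2 = (1 - h2) / h2 * (sigmaA2 + sigmaD2). Defaults follow the
#' evaluation study's base setting (mu = 100, sigmaA2 = 20); gamma is
#' studied over {0.5, 1, 2, 4} and h2 over {0.3, 0.6}.
#'
#' @param mu general mean.
#' @param sigmaA2 additive genetic variance (> 0).
#' @param gamma dominance-to-additive variance ratio (> 0).
#' @param h2 broad-sense heritability in (0, 1).
#' @param n_reps number of phenotype replicates.
#' @param seed root RNG seed for replicate substreams.
#' @return List of class \code{sim_scenario} with derived \code{sigmaD2}
#'   and \code{sigmaE2}.
#' @export
sim_scenario <- function(mu = 100, sigmaA2 = 20, gamma = 1, h2 = 0.3,
                         n_reps = 200L, seed = 1L) {
  stopifnot(sigmaA2 > 0, gamma > 0, h2 > 0, h2 < 1, n_reps >= 1L)
  sigmaD2 <- gamma * sigmaA2
  structure(list(mu = mu, sigmaA2 = sigmaA2, gamma = gamma, h2 = h2,
                 sigmaD2 = sigmaD2,
                 sigmaE2 = (1 - h2) / h2 * (sigmaA2 + sigmaD2),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "sim_scenario: mu = %g, sigmaA2 = %g, gamma = %g (sigmaD2 = %g), h2 = %g (sigmaE2 = %.4g), %d reps\n",
    x$mu, x$sigmaA2, x$gamma, x$sigmaD2, x$h2, x$sigmaE2, x$n_reps))
  invisible(x)
}

# Symmetric square-root factor of a PSD kinship by eigendecomposition.
# Kinships are rank-deficient by construction (centered scores), so
# Cholesky is not assumed; eigenvalues in [-1e-6, 0) are clipped to 0 and
# anything more negative signals a corrupted matrix.
kinship_factor <- function(K) {
  ee <- eigen(K, symmetric = TRUE)
  if (min(ee$values) < -1e-6)
    stop("kinship matrix has a substantially negative eigenvalue; corrupted input")
  lam <- pmax(ee$values, 0)
  ee$vectors %*% diag(sqrt(lam), length(lam))
}

#' Simulate phenotype replicates under the additive + dominance GBLUP model
#'
#' Draws, per replicate, gA ~ MVN(0, sigmaA2 KA), gD ~ MVN(0, sigmaD2 KD)
#' and e ~ MVN(0, sigmaE2 I), and assembles g = gA + gD,
#' tbv = mu + g and y = tbv + e. The MVN factorizations use a symmetric
#' eigendecomposition with negative eigenvalues clipped at zero.
#'
#' Reproducibility contract: the root seed deterministically spawns one
#' substream seed per replicate index, so replicate r is bit-identical
#' whether simulated alone or within any batch containing it.
#'
#' @param K a \code{kinship_pair} (or list with \code{KA}, \code{KD}).
#' @param sc a [sim_scenario()].
#' @param reps integer vector of replicate indices to generate; defaults
#'   to \code{1:sc$n_reps}.
#' @return List of replicates; each has vectors \code{gA}, \code{gD},
#'   \code{g}, \code{tbv}, \code{e}, \code{y} of length nc and the
#'   replicate index \code{rep}.
#' @export
simulate_replicates <- function(K, sc, reps = seq_len(sc$n_reps)) {
  stopifnot(inherits(sc, "sim_scenario"), all(reps >= 1L))
  KA <- K$KA
  KD <- K$KD
  nc <- nrow(KA)
  LA <- kinship_factor(KA) * sqrt(sc$sigmaA2)
  LD <- kinship_factor(KD) * sqrt(sc$sigmaD2)
  se <- sqrt(sc$sigmaE2)
  rep_seeds <- with_seed(sc$seed,
                         sample.int(.Machine$integer.max, max(reps)))
  lapply(reps, function(r) {
    with_seed(rep_seeds[r], {
      gA <- drop(LA %*% stats::rnorm(nc))
      gD <- drop(LD %*% stats::rnorm(nc))
      e <- stats::rnorm(nc, sd = se)
      g <- gA + gD
      tbv <- sc$mu + g
      list(rep = r, gA = gA, gD = gD, g = g, tbv = tbv, e = e, y = tbv + e)
    })
  })
}
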