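test_that("hybrid design validates its crossing scheme", {
  expect_error(hybrid_design(n_male = 3, n_female = 4, n_hybrids = 13),
               "crosses")
  expect_error(hybrid_design(maf_low = 0), "maf_low")
  d <- hybrid_design(n_male = 5, n_female = 8, p = 50, n_hybrids = 30,
                     seed = 2)
  expect_s3_class(d, "hybrid_design")
})

test_that("hybrid genotypes follow the parental cross table", {
  d <- hybrid_design(n_male = 6, n_female = 10, p = 120, n_hybrids = 40,
                     seed = 3)
  g <- simulate_hybrid_genotypes(d)
  expect_s3_class(g, "genotype_table")
  expect_lte(ncol(g$calls), 120)
  expect_equal(nrow(g$calls), 40)
  # every marker segregates (monomorphic loci are redrawn or dropped)
  expect_true(all(apply(g$calls, 2, function(co) length(unique(co)) > 1)))
  # hybrids sharing both parents are genetically identical clones
  male <- attr(g, "male")
  female <- attr(g, "female")
  expect_equal(anyDuplicated(paste(male, female)), 0L)
  expect_true(all(male >= 1 & male <= 6))
  expect_true(all(female >= 1 & female <= 10))
})

test_that("heterozygote frequency tracks 2f(1-f) across crosses", {
  d <- hybrid_design(n_male = 40, n_female = 50, p = 300, n_hybrids = 2000,
                     maf_low = 0.3, maf_high = 0.3, seed = 4)
  g <- simulate_hybrid_genotypes(d)
  het <- mean(g$calls == "AB")
  f <- 0.3
  p_het <- 2 * f * (1 - f)
  # per-locus binomial SE, aggregated over loci
  se <- sqrt(p_het * (1 - p_het) / (2000 * ncol(g$calls)))
  # parents are shared across crosses, inflating the effective SE; allow
  # a generous multiple while still pinning the expectation
  expect_lt(abs(het - p_het), 30 * se)
  expect_identical(g$calls, simulate_hybrid_genotypes(d)$calls)
})

test_that("scenario derives dominance and error variances from gamma and h2", {
  sc <- sim_scenario(gamma = 1, h2 = 0.3)
  expect_equal(sc$sigmaD2, 20)
  expect_equal(sc$sigmaE2, (0.7 / 0.3) * 40, tolerance = 1e-12)
  expect_equal(sc$sigmaE2, 93.3333, tolerance = 1e-4)
  sc2 <- sim_scenario(gamma = 4, h2 = 0.6)
  expect_equal(sc2$sigmaD2, 80)
  expect_equal(sc2$sigmaE2, (0.4 / 0.6) * 100, tolerance = 1e-12)
  expect_error(sim_scenario(h2 = 0), "h2")
})

test_that("replicate identities hold to machine precision", {
  K <- random_kinship_pair(15, seed = 191)
  sc <- sim_scenario(n_reps = 5, seed = 9)
  reps <- simulate_replicates(K, sc)
  expect_length(reps, 5)
  for (r in reps) {
    expect_identical(r$g, r$gA + r$gD)
    expect_identical(r$tbv, sc$mu + r$g)
    expect_identical(r$y, r$tbv + r$e)
  }
})

test_that("replicate substreams are addressable and independent", {
  K <- random_kinship_pair(12, seed = 201)
  sc <- sim_scenario(n_reps = 30, seed = 17)
  all_reps <- simulate_replicates(K, sc)
  # replicate 7 alone is bit-identical to replicate 7 in the batch
  solo <- simulate_replicates(K, sc, reps = 7L)[[1]]
  expect_identical(solo, all_reps[[7]])
  # different root seed changes the draws
  sc2 <- sim_scenario(n_reps = 30, seed = 18)
  expect_false(identical(simulate_replicates(K, sc2, reps = 1L)[[1]]$gA,
                         all_reps[[1]]$gA))
  # successive replicates look independent
  m <- vapply(all_reps, function(r) mean(r$gA), numeric(1))
  expect_lt(abs(cor(m[-1], m[-length(m)])), 0.5)
})

test_that("simulator recovers the generative variance components", {
  K <- get_kin500()
  sc <- sim_scenario(gamma = 2, h2 = 0.6, n_reps = 200, seed = 23)
  reps <- simulate_replicates(K, sc)
  vA <- mean(vapply(reps, function(r) var(r$gA), numeric(1)))
  vD <- mean(vapply(reps, function(r) var(r$gD), numeric(1)))
  vE <- mean(vapply(reps, function(r) var(r$e), numeric(1)))
  # E[s2(gA)] = sigmaA2 exactly: centered scores make 1'K1 = 0 and
  # trace(K) = nc - 1
  mc_se <- function(x) sd(x) / sqrt(length(x))
  sdA <- vapply(reps, function(r) var(r$gA), numeric(1))
  sdD <- vapply(reps, function(r) var(r$gD), numeric(1))
  sdE <- vapply(reps, function(r) var(r$e), numeric(1))
  expect_lt(abs(vA - sc$sigmaA2), 3 * mc_se(sdA))
  expect_lt(abs(vD - sc$sigmaD2), 3 * mc_se(sdD))
  expect_lt(abs(vE - sc$sigmaE2), 3 * mc_se(sdE))
  expect_equal(vD / vA, sc$gamma, tolerance = 0.15)
  # overall phenotype mean near mu
  ybar <- mean(vapply(reps, function(r) mean(r$y), numeric(1)))
  expect_equal(ybar, 100, tolerance = 1)
})

test_that("kinship factorization rejects corrupted matrices", {
  K <- random_kinship_pair(6, seed = 211)
  bad <- K$KA
  bad[1, 2] <- bad[1, 2] + 0.5   # break symmetry-consistency -> negative eig
  bad[2, 1] <- bad[2, 1] + 0.5
  bad <- bad - diag(0.6, 6)
  sc <- sim_scenario(n_reps = 1, seed = 1)
  expect_error(simulate_replicates(list(KA = bad, KD = K$KD), sc),
               "eigenvalue")
})
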