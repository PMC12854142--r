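test_that("marker coding maps calls to additive and dominance scores", {
  g <- genotype_table(cbind(c("AA", "AB", "BB"), c("AA", "AA", "AA")))
  w <- code_markers(g)
  expect_equal(unname(w$WA[, 1]), c(1L, 0L, -1L))
  expect_equal(unname(w$WD[, 1]), c(0L, 1L, 0L))
  expect_equal(unname(w$WA[, 2]), c(1L, 1L, 1L))
  expect_equal(unname(w$WD[, 2]), c(0L, 0L, 0L))

  g2 <- genotype_table(matrix(c("AB", "BB", "AA", "AB"), 2, 2))
  w2 <- code_markers(g2)
  expect_equal(unname(w2$WA), matrix(c(0L, -1L, 1L, 0L), 2, 2))
  expect_equal(unname(w2$WD), matrix(c(1L, 0L, 0L, 1L), 2, 2))
})

test_that("integer 0/1/2 input maps to BB/AB/AA and bad symbols are named", {
  gi <- genotype_table(matrix(c(2L, 1L, 0L, 1L), 2, 2))
  expect_equal(unname(gi$calls), matrix(c("AA", "AB", "BB", "AB"), 2, 2))
  expect_error(genotype_table(matrix(c("AA", "XX", "BB", "AB"), 2, 2)),
               "row 2, column 1")
  expect_error(genotype_table(matrix(c(2L, 3L, 0L, 1L), 2, 2)),
               "row 2, column 1")
})

test_that("standardization centers, scales by sample sd, drops constants", {
  out <- standardize_scores(cbind(c(1, 0, -1), c(1, 1, 1), c(1, 1, -1)))
  expect_equal(out$dropped, 2L)
  expect_equal(out$retained, c(1L, 3L))
  expect_equal(unname(out$X[, 1]), c(1, 0, -1))
  # column (1, 1, -1): mean 1/3, sample sd sqrt(4/3)
  expect_equal(unname(out$X[, 2]),
               (c(1, 1, -1) - 1 / 3) / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(unname(out$X[, 2]), c(0.5774, 0.5774, -1.1547),
               tolerance = 1e-4)
  expect_error(standardize_scores(cbind(c(1, 1), c(0, 0))),
               "zero variance")
})

test_that("score pair columns are standardized and bookkeeping is kept", {
  g <- random_genotype_table(12, 40, seed = 3)
  sp <- marker_scores(g)
  for (X in list(sp$XA, sp$XD)) {
    expect_lt(max(abs(colMeans(X))), 1e-10)
    expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-10)
  }
  expect_lte(ncol(sp$XA), ncol(g$calls))
  expect_lte(ncol(sp$XD), ncol(g$calls))
  expect_equal(sort(c(sp$retained_D, sp$dropped_D)), seq_len(ncol(g$calls)))
})

test_that("kinship is X X' / p with the single-marker closed form", {
  K <- single_marker_K()
  expect_equal(K, rbind(c(1, 0, -1), c(0, 0, 0), c(-1, 0, 1)))
  expect_error(kinship(matrix(numeric(0), 3, 0)), "p_used")
})

test_that("kinship pair satisfies trace, symmetry, psd and row-sum invariants", {
  for (seed in 1:4) {
    nc <- sample(5:15, 1)
    K <- random_kinship_pair(nc, p = 25, seed = seed)
    for (M in list(K$KA, K$KD)) {
      expect_lt(max(abs(M - t(M))), 1e-10)
      expect_equal(sum(diag(M)), nc - 1, tolerance = 1e-8)
      expect_lt(max(abs(rowSums(M))), 1e-8)
      expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
                -1e-8)
    }
  }
})

test_that("duplicating every marker column leaves the kinship unchanged", {
  g <- random_genotype_table(8, 20, seed = 5)
  sp <- marker_scores(g)
  K1 <- kinship(sp$XA)
  K2 <- kinship(cbind(sp$XA, sp$XA))
  expect_equal(K1, K2, tolerance = 1e-12)
})

test_that("pc_reduce matches an independent SVD and keeps the Gram matrix", {
  # fixed 4 x 3 matrix, centered columns
  X <- scale(matrix(c(1, 2, 0, 4, 2, 0, 1, 3, 5, 1, 0, 2), 4, 3),
             scale = FALSE)
  pc <- pc_reduce(X[, 1:2, drop = FALSE], X[, 3, drop = FALSE],
                  threshold = 1)
  ee <- eigen(tcrossprod(X), symmetric = TRUE)
  r <- sum(ee$values > 1e-10)
  expect_equal(pc$m, r)
  for (j in seq_len(r)) {
    oracle_col <- ee$vectors[, j] * sqrt(ee$values[j])
    expect_lt(min(sqrt(sum((pc$Z[, j] - oracle_col)^2)),
                  sqrt(sum((pc$Z[, j] + oracle_col)^2))), 1e-8)
  }
  # Gram structure preserved at threshold 1
  expect_lt(norm(tcrossprod(pc$Z) - tcrossprod(X), "F") /
              norm(tcrossprod(X), "F"), 1e-8)
})

test_that("pc_reduce picks the minimal component count past the threshold", {
  set.seed(7)
  u <- rnorm(6)
  rank1 <- outer(u - mean(u), rnorm(4))
  pc <- pc_reduce(rank1[, 1:2], rank1[, 3:4])
  expect_equal(pc$m, 1L)
  expect_equal(pc$explained_cumvar, 1)

  sp <- marker_scores(random_genotype_table(10, 30, seed = 11))
  full <- pc_reduce(sp$XA, sp$XD, threshold = 1 - 1e-12)
  merged <- cbind(sp$XA, sp$XD)
  expect_equal(full$m, qr(merged)$rank)
  expect_error(pc_reduce(sp$XA, sp$XD, threshold = 0), "threshold")
  expect_error(pc_reduce(sp$XA, sp$XD, threshold = 1.5), "threshold")
})

test_that("dominance variance profile scales the kinship diagonal", {
  K <- single_marker_K()
  expect_equal(dominance_variance_profile(K, 2), c(2, 0, 2))
  expect_equal(dominance_variance_profile(K, 0), c(0, 0, 0))
  KD <- random_kinship_pair(9, seed = 2)$KD
  prof <- dominance_variance_profile(KD, 1)
  expect_equal(mean(prof), (9 - 1) / 9, tolerance = 1e-10)
  expect_true(all(prof > -1e-10))
})

test_that("delimited round-trip preserves the genotype table", {
  g <- random_genotype_table(6, 8, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(id = g$hybrid_ids, g$calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- read_genotypes(path)
  expect_equal(unname(g2$calls), unname(g$calls))
  # comma-separated, integer-coded variant
  path2 <- withr::local_tempfile(fileext = ".csv")
  ints <- matrix(match(g$calls, c("BB", "AB", "AA")) - 1L, nrow(g$calls))
  utils::write.table(data.frame(id = g$hybrid_ids, ints), path2, sep = ",",
                     quote = FALSE, row.names = FALSE)
  expect_equal(unname(read_genotypes(path2)$calls), unname(g$calls))
})

test_that("minimal VCF reader maps GT calls and rejects multi-allelics", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tH1\tH2\tH3",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0|1\t1/0\t0/0",
    "1\t300\tsnp3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"),
    path)
  expect_message(g <- read_vcf_genotypes(path), "1 multi-allelic")
  expect_equal(dim(g$calls), c(3L, 2L))
  expect_equal(unname(g$calls[, 1]), c("AA", "AB", "BB"))
  expect_equal(unname(g$calls[, 2]), c("AB", "AB", "AA"))
  expect_equal(g$marker_ids, c("snp1", "1:200"))
})
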