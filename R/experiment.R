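#' Study grid for the simulation experiment
#'
#' The factorial evaluation design: training set sizes, dominance ratios,
#' heritabilities, replicate count, evaluation depth k and the
#' construction methods to compare. The replicate count defaults to a
#' desk-scale 200; set \code{n_reps = 2000} for a full-scale run.
#'
#' @param nt_values training set sizes.
#' @param gamma_values dominance-to-additive variance ratios.
#' @param h2_values broad-sense heritabilities.
#' @param n_reps phenotype replicates per scenario.
#' @param k ranking evaluation depth.
#' @param methods subset of \code{c("random", "gv", "mspe", "cdmean")}.
#' @param mu,sigmaA2 generative model mean and additive variance.
#' @param lambda ridge parameter for the MSPE criterion.
#' @param seed root seed; all selection and simulation seeds derive from
#'   it.
#' @return List of class \code{study_grid}.
#' @export
study_grid <- function(nt_values = c(50L, 100L, 150L, 200L),
                       gamma_values = c(0.5, 1, 2, 4),
                       h2_values = c(0.3, 0.6),
                       n_reps = 200L, k = 20L,
                       methods = c("random", "gv", "mspe", "cdmean"),
                       mu = 100, sigmaA2 = 20, lambda = 1, seed = 1L) {
  methods <- match.arg(methods, c("random", "gv", "mspe", "cdmean"),
                       several.ok = TRUE)
  stopifnot(length(nt_values) >= 1L, length(gamma_values) >= 1L,
            length(h2_values) >= 1L, n_reps >= 2L, k >= 1L)
  structure(list(nt_values = as.integer(nt_values),
                 gamma_values = gamma_values, h2_values = h2_values,
                 n_reps = as.integer(n_reps), k = as.integer(k),
                 methods = methods, mu = mu, sigmaA2 = sigmaA2,
                 lambda = lambda, seed = as.integer(seed)),
            class = "study_grid")
}

select_for_method <- function(method, nt, K, Z, grid) {
  nc <- nrow(K$KA)
  sel_seed <- grid$seed + 97L * nt
  switch(method,
    random = select_random(nt, nc, seed = sel_seed),
    gv = select_gv_average(gv_scores(K), nt),
    mspe = select_exchange(
      function(idx) mspe_ridge_v2(Z, idx, lambda = grid$lambda),
      nt, nc, exchange_config(seed = sel_seed, direction = "minimize"),
      method = "mspe"),
    cdmean = select_exchange(
      function(idx) cdmean_v2(K$KA, K$KD, idx),
      nt, nc, exchange_config(seed = sel_seed, direction = "maximize"),
      method = "cdmean"))
}

#' Run the full training-set evaluation study
#'
#' Orchestrates the pipeline: scores and kinships from the genotypes,
#' one training set per (method, size) selected from genotype information
#' only, shared phenotype replicates per scenario (common random numbers
#' across methods, so relative improvements are not inflated by
#' independent noise), closed-form BLUP of all candidates' genotypic
#' values from each training set using the true variance ratios, and the
#' three top-k ranking metrics per replicate. Summaries report the mean
#' and standard deviation over replicates plus the relative improvement
#' percentage (RIP) of every method over the random baseline; under
#' shared replicates the random method's RIP over itself is exactly 0.
#'
#' @param genotypes a [genotype_table()].
#' @param grid a [study_grid()].
#' @param out_dir optional directory; when given, writes
#'   \code{summary.csv}, \code{rip.csv} and \code{manifest.json}.
#' @return List with data.frames \code{summary} (method, nt, gamma, h2,
#'   metric, mean, sd) and \code{rip}, the selected \code{sets}, and a
#'   run \code{manifest}.
#' @export
run_study <- function(genotypes, grid = study_grid(), out_dir = NULL) {
  stopifnot(inherits(genotypes, "genotype_table"),
            inherits(grid, "study_grid"))
  scores <- marker_scores(genotypes)
  K <- kinship_pair(scores)
  Z <- pc_reduce(scores$XA, scores$XD)
  nc <- nrow(K$KA)
  if (grid$k > nc) stop("k exceeds the candidate population size")

  sets <- list()
  for (method in grid$methods) {
    for (nt in grid$nt_values) {
      sets[[paste(method, nt, sep = ".")]] <-
        tryCatch(select_for_method(method, nt, K, Z, grid),
                 error = function(e)
                   stop(sprintf("selection failed for method=%s nt=%d: %s",
                                method, nt, conditionMessage(e))))
    }
  }

  rows <- list()
  scen_id <- 0L
  for (gamma in grid$gamma_values) {
    for (h2 in grid$h2_values) {
      scen_id <- scen_id + 1L
      sc <- sim_scenario(mu = grid$mu, sigmaA2 = grid$sigmaA2,
                         gamma = gamma, h2 = h2, n_reps = grid$n_reps,
                         seed = grid$seed + 1009L * scen_id)
      replicates <- simulate_replicates(K, sc)
      aA <- sc$sigmaA2 / sc$sigmaE2
      aD <- sc$sigmaD2 / sc$sigmaE2
      for (method in grid$methods) {
        for (nt in grid$nt_values) {
          set <- sets[[paste(method, nt, sep = ".")]]
          vals <- vapply(replicates, function(repl) {
            gebv <- tryCatch(
              blup_candidates(repl$y[set$indices], set, K,
                              alpha_A = aA, alpha_D = aD),
              error = function(e)
                stop(sprintf(
                  "BLUP failed at method=%s nt=%d gamma=%g h2=%g rep=%d: %s",
                  method, nt, gamma, h2, repl$rep, conditionMessage(e))))
            c(ndcg = ndcg_at_k(repl$tbv, gebv, grid$k),
              src = src_at_k(repl$tbv, gebv, grid$k),
              rs_ratio = rs_ratio_at_k(repl$tbv, gebv, grid$k))
          }, numeric(3L))
          for (metric in rownames(vals)) {
            rows[[length(rows) + 1L]] <- data.frame(
              method = method, nt = nt, gamma = gamma, h2 = h2,
              metric = metric, mean = mean(vals[metric, ]),
              sd = stats::sd(vals[metric, ]))
          }
        }
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  rip_df <- NULL
  if ("random" %in% grid$methods) {
    base <- summary[summary$method == "random",
                    c("nt", "gamma", "h2", "metric", "mean")]
    names(base)[5L] <- "mean_random"
    rip_df <- merge(summary, base, by = c("nt", "gamma", "h2", "metric"))
    rip_df$rip <- rip(rip_df$mean, rip_df$mean_random)
    rip_df <- rip_df[order(rip_df$method, rip_df$nt, rip_df$gamma,
                           rip_df$h2, rip_df$metric),
                     c("method", "nt", "gamma", "h2", "metric",
                       "mean", "mean_random", "rip")]
    rownames(rip_df) <- NULL
  }

  manifest <- list(
    package = "hybridTS",
    version = as.character(utils::packageVersion("hybridTS")),
    seed = grid$seed,
    nc = nc, n_markers = ncol(genotypes$calls),
    grid = grid[c("nt_values", "gamma_values", "h2_values", "n_reps",
                  "k", "methods", "mu", "sigmaA2", "lambda")],
    sets = lapply(sets, function(s)
      list(method = s$method, nt = s$nt,
           criterion_value = s$criterion_value, indices = s$indices)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(rip_df))
      utils::write.csv(rip_df, file.path(out_dir, "rip.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary, rip = rip_df, sets = sets, manifest = manifest)
}

#' Parameter-robustness report for the selection criteria
#'
#' Quantifies how sensitive each selection criterion is to its tuning
#' parameters, on any dataset: for a
#' panel of random training sets, the ridge MSPE criterion is evaluated
#' over a grid of regularization parameters and the CD criterion over a
#' grid of (alpha_A, alpha_D) weights; Pearson and Spearman correlations
#' against the default setting quantify ranking concordance. For the
#' genomic-variance ranking, the top-nt overlap and the rank-sum ratio
#' between the default (1, 1) variance components and alternative
#' settings are reported (positive rescaling leaves the ranking
#' untouched, so equal-ratio settings give perfect concordance on any
#' dataset).
#'
#' @param genotypes a [genotype_table()].
#' @param n_sets number of random training sets.
#' @param nt training set size.
#' @param seed RNG seed for the random sets.
#' @param lambda_grid ridge parameters evaluated (default setting 1).
#' @param alpha_grid 2-column matrix of (alpha_A, alpha_D) settings;
#'   default grid includes the (1, 1) default.
#' @param sigma_grid 2-column matrix of (sigmaA2, sigmaD2) settings for
#'   the genomic-variance ranking.
#' @return List with data.frames \code{mspe_values}, \code{cd_values},
#'   \code{mspe_concordance}, \code{cd_concordance}, \code{gv_stability}.
#' @export
robustness_report <- function(genotypes, n_sets = 20L, nt = 50L, seed = 1L,
                              lambda_grid = c(0.01, 0.1, 1, 10, 100),
                              alpha_grid = cbind(c(0.5, 0.5, 1, 1, 1),
                                                 c(0.5, 1, 1, 2, 4)),
                              sigma_grid = cbind(c(0.5, 0.5, 1, 1, 1),
                                                 c(0.5, 1, 1, 2, 4))) {
  stopifnot(inherits(genotypes, "genotype_table"))
  scores <- marker_scores(genotypes)
  K <- kinship_pair(scores)
  Z <- pc_reduce(scores$XA, scores$XD)
  nc <- nrow(K$KA)
  sets <- lapply(seq_len(n_sets),
                 function(i) select_random(nt, nc, seed = seed + i)$indices)

  mspe_values <- sapply(lambda_grid, function(lam)
    vapply(sets, function(idx) mspe_ridge_v2(Z, idx, lambda = lam),
           numeric(1L)))
  colnames(mspe_values) <- paste0("lambda_", lambda_grid)

  cd_values <- apply(alpha_grid, 1L, function(a)
    vapply(sets, function(idx) cdmean_v2(K$KA, K$KD, idx,
                                         alpha_A = a[1L], alpha_D = a[2L]),
           numeric(1L)))
  colnames(cd_values) <- sprintf("alpha_%g_%g", alpha_grid[, 1L],
                                 alpha_grid[, 2L])

  concord <- function(values, default_col, labels) {
    data.frame(
      setting = labels,
      pearson = apply(values, 2L, stats::cor, y = values[, default_col]),
      spearman = apply(values, 2L, stats::cor, y = values[, default_col],
                       method = "spearman"),
      row.names = NULL)
  }
  default_lam <- which(lambda_grid == 1)[1L]
  default_alpha <- which(alpha_grid[, 1L] == 1 & alpha_grid[, 2L] == 1)[1L]

  ref_scores <- gv_scores(K, sigmaA2 = 1, sigmaD2 = 1)
  ref_top <- select_gv_average(ref_scores, nt)$indices
  gv_stability <- do.call(rbind, lapply(seq_len(nrow(sigma_grid)),
    function(i) {
      sc <- gv_scores(K, sigmaA2 = sigma_grid[i, 1L],
                      sigmaD2 = sigma_grid[i, 2L])
      top <- select_gv_average(sc, nt)$indices
      data.frame(
        sigmaA2 = sigma_grid[i, 1L], sigmaD2 = sigma_grid[i, 2L],
        overlap = length(intersect(top, ref_top)) / nt,
        rs_ratio = rs_ratio_at_k(ref_scores, sc, nt))
    }))

  list(mspe_values = as.data.frame(mspe_values),
       cd_values = as.data.frame(cd_values),
       mspe_concordance = concord(mspe_values, default_lam,
                                  paste0("lambda=", lambda_grid)),
       cd_concordance = concord(cd_values, default_alpha,
                                sprintf("alpha=(%g,%g)", alpha_grid[, 1L],
                                        alpha_grid[, 2L])),
       gv_stability = gv_stability)
}
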