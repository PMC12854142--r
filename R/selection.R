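#' Select a training set by genomic-variance ranking
#'
#' Takes the nt candidates with the largest per-candidate genomic
#' variance scores (see [gv_scores()]). Ties are broken by ascending
#' candidate index, making the selection fully deterministic; no search
#' is involved.
#'
#' @param scores numeric score vector over candidates.
#' @param nt training set size (1 <= nt <= nc).
#' @return A [training_set()] with \code{criterion_value} equal to the
#'   selected subset's score sum.
#' @export
select_gv_average <- function(scores, nt) {
  nc <- length(scores)
  if (nt < 1L || nt > nc) stop("nt must be in 1..nc")
  ord <- order(-scores, seq_len(nc))
  idx <- ord[seq_len(nt)]
  training_set(idx, nc, method = "gv_average",
               criterion_value = sum(scores[idx]))
}

#' Select a training set by uniform random sampling
#'
#' The baseline construction method: a uniform sample of nt candidates
#' without replacement, reproducible under the given seed.
#'
#' @param nt training set size.
#' @param nc candidate population size.
#' @param seed integer RNG seed.
#' @return A [training_set()].
#' @export
select_random <- function(nt, nc, seed) {
  if (nt < 1L || nt > nc) stop("nt must be in 1..nc")
  idx <- with_seed(seed, sample.int(nc, nt))
  training_set(idx, nc, method = "random", seed = seed)
}

#' Exchange-algorithm configuration
#'
#' @param max_rounds maximum full-neighborhood passes per restart.
#' @param n_restarts independent random starts; the best final subset is
#'   returned.
#' @param seed integer seed controlling the random starts.
#' @param direction \code{"minimize"} or \code{"maximize"}.
#' @return List of class \code{exchange_config}.
#' @export
exchange_config <- function(max_rounds = 50L, n_restarts = 1L,
                            seed = 1L,
                            direction = c("minimize", "maximize")) {
  direction <- match.arg(direction)
  stopifnot(max_rounds >= 1L, n_restarts >= 1L)
  structure(list(max_rounds = as.integer(max_rounds),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), direction = direction),
            class = "exchange_config")
}

#' Optimize a training set by steepest-ascent exchange
#'
#' Local search over fixed-size subsets: starting from a seeded uniform
#' random subset, every round evaluates all nt x (nc - nt) single
#' (member, non-member) swaps and applies the best strictly improving
#' one; the search stops when no swap improves the criterion or
#' \code{max_rounds} is reached. With several restarts the best final
#' subset is returned. The trajectory of accepted criterion values is
#' strictly monotone in the configured direction.
#'
#' For a modular (additive over members) criterion such as the genomic
#' variance sum the exchange converges to the exact top-nt set from any
#' start; for the subset criteria it is a local optimizer, as is usual
#' for exchange-type training-set design.
#'
#' @param criterion function taking an integer index vector and returning
#'   a scalar; must be defined for all size-nt subsets.
#' @param nt training set size.
#' @param nc candidate population size.
#' @param cfg an [exchange_config()].
#' @param method tag stored in the result.
#' @return A [training_set()] with the achieved \code{criterion_value};
#'   attribute \code{"trajectory"} holds the per-restart accepted-value
#'   sequences, attribute \code{"rounds"} the rounds used.
#' @export
select_exchange <- function(criterion, nt, nc, cfg = exchange_config(),
                            method = "exchange") {
  if (nt < 1L || nt > nc) stop("nt must be in 1..nc")
  if (nt == nc) {
    idx <- seq_len(nc)
    return(training_set(idx, nc, method = method,
                        criterion_value = criterion(idx), seed = cfg$seed))
  }
  sgn <- if (cfg$direction == "maximize") 1 else -1
  starts <- with_seed(cfg$seed, lapply(seq_len(cfg$n_restarts),
                                       function(i) sort(sample.int(nc, nt))))
  best <- NULL
  trajectories <- vector("list", cfg$n_restarts)
  rounds_used <- integer(cfg$n_restarts)
  for (r in seq_len(cfg$n_restarts)) {
    cur <- starts[[r]]
    cur_val <- criterion(cur)
    traj <- cur_val
    for (round in seq_len(cfg$max_rounds)) {
      outside <- setdiff(seq_len(nc), cur)
      best_swap <- NULL
      best_val <- cur_val
      for (i in seq_along(cur)) {
        for (j in seq_along(outside)) {
          cand <- cur
          cand[i] <- outside[j]
          val <- criterion(cand)
          if (sgn * (val - best_val) > 1e-12) {
            best_val <- val
            best_swap <- c(i, j)
          }
        }
      }
      if (is.null(best_swap)) break
      cur[best_swap[1L]] <- outside[best_swap[2L]]
      cur <- sort(cur)
      cur_val <- best_val
      traj <- c(traj, cur_val)
      rounds_used[r] <- round
    }
    trajectories[[r]] <- traj
    if (is.null(best) || sgn * (cur_val - best$value) > 0) {
      best <- list(indices = cur, value = cur_val)
    }
  }
  out <- training_set(best$indices, nc, method = method,
                      criterion_value = best$value, seed = cfg$seed)
  attr(out, "trajectory") <- trajectories
  attr(out, "rounds") <- rounds_used
  out
}

# Run code under a temporary RNG state so selection and simulation seeds
# never disturb (or depend on) the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
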