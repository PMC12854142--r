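# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Random genotype table with segregating loci (polymorphic in both the
# additive and, with high probability, the dominance coding).
random_genotype_table <- function(nc, p, seed = 1) {
  set.seed(seed)
  repeat {
    calls <- matrix(sample(c("AA", "AB", "BB"), nc * p, replace = TRUE),
                    nc, p)
    ok_a <- apply(calls, 2, function(co) length(unique(co)) > 1)
    ok_d <- apply(calls, 2, function(co) any(co == "AB") && !all(co == "AB"))
    if (any(ok_a & ok_d)) {
      return(genotype_table(calls[, ok_a & ok_d, drop = FALSE]))
    }
  }
}

random_kinship_pair <- function(nc, p = 30, seed = 1) {
  kinship_pair(random_genotype_table(nc, p, seed = seed))
}

# The 3-candidate single-marker example population: additive column
# (1, 0, -1) standardized to itself gives K = outer product.
single_marker_K <- function() {
  x <- matrix(c(1, 0, -1), 3, 1)
  kinship(x, 1)
}

# Wheat-like synthetic candidate population at study scale, shared by the
# slower integration and acceptance tests.
get_pop500 <- function() {
  cached("pop500", function()
    simulate_hybrid_genotypes(hybrid_design(seed = 1)))
}

get_kin500 <- function() {
  cached("kin500", function() kinship_pair(get_pop500()))
}
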