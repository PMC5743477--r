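# small fixtures built in code

# minimal 2-species, 2-region reciprocal dataset with fixed biomasses
toy_dataset <- function() {
  grid <- expand.grid(replicate = 1:3, ecotype = c("A", "B"),
                      garden = c("A", "B"),
                      species = c("sp1", "sp2"),
                      stringsAsFactors = FALSE)
  set.seed(99)
  grid$biomass <- exp(rnorm(nrow(grid), mean = log(2), sd = 0.3))
  transplant_dataset(grid)
}

# single-species config, convenient for per-species analysis tests
one_species_config <- function(sympatry_effect = 0, seed = 1,
                               replicates = 12, ...) {
  simulation_config(regions = c("N", "E", "S", "W"),
                    species_specs = list(solo = c("N", "E", "S", "W")),
                    replicates = replicates,
                    species_mean = c(solo = 2),
                    sympatry_effect = sympatry_effect, seed = seed, ...)
}

# hand-built Tukey comparison table for classification rule tests:
# `rows` is a data.frame with ecotype_a, ecotype_b, diff, p_adj
make_pairs <- function(rows, alpha = 0.05) {
  structure(rows, alpha = alpha,
            class = c("pairwise_comparisons", "data.frame"))
}

# hand-built posterior draws object around a given draw matrix
make_draws <- function(mat, seed = 0L) {
  structure(list(draws = mat, sigma_draws = rep(1, nrow(mat)),
                 n_draws = nrow(mat), seed = seed),
            class = "posterior_draws")
}
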