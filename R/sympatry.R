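#' Standardize biomass within each species
#'
#' Species differ greatly in size, so cross-species analyses operate on
#' biomass centered and scaled within species: each species' measured
#' values are transformed to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Missing biomass stays missing.
#'
#' @param ds a [transplant_dataset].
#' @return The record table (data.frame) with added columns `biomass_std`,
#'   `sympatric` (0/1 indicator ecotype == garden) and `species_ecotype`
#'   (composite random-effect key).
#' @export
standardize_within_species <- function(ds) {
  stopifnot(inherits(ds, "transplant_dataset"))
  rec <- ds$records
  rec$biomass_std <- NA_real_
  for (sp in unique(rec$species)) {
    idx <- rec$species == sp & !is.na(rec$biomass)
    if (sum(idx) < 2L) {
      stop("species '", sp, "' has fewer than 2 measured plants")
    }
    s <- stats::sd(rec$biomass[idx])
    if (s == 0) stop("species '", sp, "' has zero within-species SD")
    rec$biomass_std[idx] <- (rec$biomass[idx] - mean(rec$biomass[idx])) / s
  }
  rec$sympatric <- as.integer(rec$ecotype == rec$garden)
  rec$species_ecotype <- paste(rec$species, rec$ecotype, sep = ":")
  rec
}

#' Approximate conditional R-squared of a mixed-model fit
#'
#' Proportion of response variance explained jointly by the fixed and
#' random effects, in the Nakagawa-Schielzeth conditional form:
#' \deqn{R^2_c = \frac{\mathrm{var}(X\hat\beta) + \hat\sigma_g^2}
#'   {\mathrm{var}(X\hat\beta) + \hat\sigma_g^2 + \hat\sigma^2}.}
#' Returns 0 by convention when all three components are zero.
#'
#' @param fit an [fit_lmm()] result.
#' @param fixed_predictions optional numeric vector of fixed-effect fitted
#'   values; defaults to the fit's own `X %*% beta`.
#' @return A proportion in \[0, 1\].
#' @export
conditional_r2 <- function(fit, fixed_predictions = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (is.null(fixed_predictions)) {
    fixed_predictions <- as.numeric(fit$X %*% fit$beta)
  }
  var_f <- stats::var(fixed_predictions)
  denom <- var_f + fit$sigma2_group + fit$sigma2_resid
  if (denom == 0) return(0)
  (var_f + fit$sigma2_group) / denom
}

verdict_from_probability <- function(p) {
  if (p > 0.95) "local_adaptation" else if (p < 0.05) "maladaptation"
  else "inconclusive"
}

new_sympatry_result <- function(scope, fit, post, effect_percent_draws,
                                effect_std, p_symp) {
  if (!is.null(effect_percent_draws)) {
    est_percent <- stats::median(effect_percent_draws)
    ci <- stats::quantile(effect_percent_draws, c(0.025, 0.975), type = 7,
                          names = FALSE)
  } else {
    est_percent <- NA_real_
    ci <- credible_interval(post, "sympatric", 0.95)
  }
  structure(
    list(scope = scope,
         effect_size_percent = est_percent,
         effect_size_standardized = effect_std,
         ci_lower = ci[[1L]], ci_upper = ci[[2L]],
         posterior_probability = p_symp,
         conditional_r2 = conditional_r2(fit),
         verdict = verdict_from_probability(p_symp),
         n_obs = fit$n_obs,
         fit = fit),
    class = "sympatry_result"
  )
}

#' @export
print.sympatry_result <- function(x, ...) {
  cat("Sympatric/allopatric contrast [", x$scope, "], n = ", x$n_obs, "\n",
      sep = "")
  if (!is.na(x$effect_size_percent)) {
    cat(sprintf("  sympatry effect: %+.1f%% [%.1f, %.1f]\n",
                x$effect_size_percent, x$ci_lower, x$ci_upper))
  } else {
    cat(sprintf("  sympatry effect (SD units): %+.3f [%.3f, %.3f]\n",
                x$effect_size_standardized, x$ci_lower, x$ci_upper))
  }
  cat(sprintf("  P(sympatric > allopatric) = %.3f -> %s; conditional R2 = %.3f\n",
              x$posterior_probability, x$verdict, x$conditional_r2))
  invisible(x)
}

#' @export
as.data.frame.sympatry_result <- function(x, ...) {
  data.frame(scope = x$scope,
             effect_size_percent = x$effect_size_percent,
             effect_size_standardized = x$effect_size_standardized,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             posterior_probability = x$posterior_probability,
             conditional_r2 = x$conditional_r2,
             verdict = x$verdict, n_obs = x$n_obs,
             stringsAsFactors = FALSE)
}

#' Per-species sympatric/allopatric analysis
#'
#' Fits, on raw biomass of one species, a linear mixed model with garden
#' identity and the sympatry indicator as fixed factors and ecotype as a
#' random intercept. The effect size is the percentage difference between
#' plants in sympatry and allopatry: 100 x beta_sympatry divided by the
#' model-fitted allopatric biomass averaged over the species' gardens
#' (random effects at zero). Uncertainty comes from posterior simulation:
#' the percent effect is recomputed for every posterior draw, the interval
#' is the 2.5%-97.5% range of those draws, and the posterior probability is
#' the fraction of draws with a positive sympatry coefficient. Posterior
#' probability above 0.95 is read as evidence of local adaptation, below
#' 0.05 as maladaptation.
#'
#' @param ds a [transplant_dataset].
#' @param species species identifier present in the dataset.
#' @param n_draws posterior draws (default 10,000).
#' @param seed RNG seed for the posterior simulation.
#' @param method `"REML"` (default) or `"ML"`.
#' @return A `sympatry_result`.
#' @export
analyze_species <- function(ds, species, n_draws = 10000L, seed = 1L,
                            method = "REML") {
  rec <- complete_records(ds)
  rec <- rec[rec$species == species, , drop = FALSE]
  if (nrow(rec) == 0L) stop("species '", species, "' not found")
  if (length(unique(rec$ecotype)) < 2L) {
    stop("species '", species, "' has fewer than 2 ecotypes")
  }
  spec <- lmm_spec("biomass", c("garden", "sympatric"), "ecotype",
                   method = method)
  fit <- fit_lmm(rec, spec)
  post <- simulate_posterior(fit, n_draws = n_draws, seed = seed)
  # allopatric baseline: fixed-effect fitted value averaged over gardens
  gardens <- unique(rec$garden)
  grid <- data.frame(garden = gardens, sympatric = 0)
  L <- fixed_design_rows(fit, grid)$L
  c_base <- colMeans(L)
  baseline_draws <- as.numeric(post$draws %*% c_base)
  percent_draws <- 100 * post$draws[, "sympatric"] / baseline_draws
  p_symp <- posterior_probability(post, "sympatric", ">0")
  new_sympatry_result(scope = species, fit = fit, post = post,
                      effect_percent_draws = percent_draws,
                      effect_std = NA_real_, p_symp = p_symp)
}

#' Cross-species sympatric/allopatric analysis
#'
#' The most general test: biomass is standardized within species, then a
#' single mixed model is fitted across all species with garden identity and
#' the sympatry indicator as fixed factors and ecotype nested within
#' species (the species:ecotype composite key) as the random intercept.
#' The effect size is the sympatry coefficient in within-species SD units;
#' posterior simulation supplies the 95% credible interval and the
#' posterior probability that sympatric plants outperform allopatric ones,
#' with the same 0.95/0.05 evidence thresholds as the per-species analysis.
#'
#' @param ds a [transplant_dataset] with at least 2 species.
#' @inheritParams analyze_species
#' @return A `sympatry_result` with scope `"ALL"`.
#' @export
analyze_all_species <- function(ds, n_draws = 10000L, seed = 1L,
                                method = "REML") {
  if (length(unique(ds$records$species)) < 2L) {
    stop("cross-species analysis requires at least 2 species")
  }
  std <- standardize_within_species(ds)
  std <- std[!is.na(std$biomass_std), , drop = FALSE]
  spec <- lmm_spec("biomass_std", c("garden", "sympatric"),
                   "species_ecotype", method = method)
  fit <- fit_lmm(std, spec)
  post <- simulate_posterior(fit, n_draws = n_draws, seed = seed)
  p_symp <- posterior_probability(post, "sympatric", ">0")
  new_sympatry_result(scope = "ALL", fit = fit, post = post,
                      effect_percent_draws = NULL,
                      effect_std = fit$beta[["sympatric"]], p_symp = p_symp)
}

#' Resampling check equalizing power with the per-species models
#'
#' The cross-species model sees far more plants than any single-species
#' model, so part of its strength is raw sample size. This check refits the
#' cross-species model on subsamples whose size matches a single-species
#' model: each permutation draws `target_n` rows without replacement from
#' the standardized cross-species data (stratified proportionally by
#' species, so no species vanishes), refits by maximum likelihood, and
#' records whether the sympatry coefficient is positive. The report is the
#' proportion of permutations pointing toward an advantage in sympatry.
#'
#' @param ds a [transplant_dataset].
#' @param target_n subsample size; defaults to the largest single-species
#'   sample size in the dataset.
#' @param n_permutations number of resampling repeats (the analysis default
#'   is 10,000).
#' @param seed RNG seed.
#' @param redraw_cap maximum redraws per permutation when a subsample
#'   cannot support the model (fewer than 2 random-effect levels or a
#'   degenerate fixed design).
#' @return An object of class `resample_report`: `n_permutations`,
#'   `target_n`, `proportion_positive`, `signs` (per-permutation +/-1),
#'   `seed`.
#' @export
resample_power_check <- function(ds, target_n = NULL,
                                 n_permutations = 10000L, seed = 1L,
                                 redraw_cap = 100L) {
  std <- standardize_within_species(ds)
  std <- std[!is.na(std$biomass_std), , drop = FALSE]
  sp_idx <- split(seq_len(nrow(std)), std$species)
  n_sp <- lengths(sp_idx)
  if (is.null(target_n)) target_n <- max(n_sp)
  if (target_n > nrow(std)) stop("target_n exceeds the number of measured plants")
  # proportional allocation, largest-remainder rounding
  raw <- target_n * n_sp / sum(n_sp)
  quota <- floor(raw)
  rem <- target_n - sum(quota)
  if (rem > 0) {
    top <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[top] <- quota[top] + 1L
  }
  if (any(quota > n_sp)) stop("target_n too large for proportional stratification")
  spec <- lmm_spec("biomass_std", c("garden", "sympatric"),
                   "species_ecotype", method = "ML")
  set.seed(as.integer(seed))
  signs <- integer(n_permutations)
  for (b in seq_len(n_permutations)) {
    ok <- FALSE
    for (attempt in seq_len(redraw_cap)) {
      rows <- unlist(lapply(names(sp_idx), function(sp) {
        sample(sp_idx[[sp]], quota[[sp]])
      }), use.names = FALSE)
      sub <- std[rows, , drop = FALSE]
      fit <- tryCatch(fit_lmm(sub, spec), error = function(e) NULL)
      if (!is.null(fit)) {
        signs[b] <- if (fit$beta[["sympatric"]] > 0) 1L else -1L
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not draw a fittable subsample after ", redraw_cap,
                  " attempts; increase target_n")
  }
  structure(
    list(n_permutations = as.integer(n_permutations),
         target_n = as.integer(target_n),
         proportion_positive = mean(signs > 0),
         signs = signs, seed = as.integer(seed)),
    class = "resample_report"
  )
}

#' @export
print.resample_report <- function(x, ...) {
  cat("Power-equalized resampling: ", x$n_permutations, " permutations of n = ",
      x$target_n, "\n  proportion with sympatric advantage: ",
      round(x$proportion_positive, 4), "\n", sep = "")
  invisible(x)
}

#' Detection-rate comparison of the three analysis tiers
#'
#' Simulates datasets on a grid of true sympatry advantages and measures,
#' at each grid point, how often each tier reports local adaptation:
#' tier 1 as the fraction of species x garden cells classified
#' "local_is_best", tier 2 as the fraction of per-species analyses with a
#' local-adaptation verdict, tier 3 as the fraction of datasets whose
#' cross-species analysis gives that verdict. The strict tier-1 rule is by
#' construction the most conservative and the pooled tier-3 model the most
#' powerful.
#'
#' @param delta_grid numeric vector of log-scale sympatry advantages.
#' @param n_sims simulated datasets per grid point.
#' @param config_fn function(sympatry_effect, seed) returning a
#'   [simulation_config()]; defaults to [study_design_config()] with
#'   heterogeneous ecotype quality.
#' @param alpha tier-1 significance level.
#' @param n_draws posterior draws for tiers 2-3.
#' @param seed master seed; per-dataset seeds are derived from it.
#' @return data.frame with columns `delta`, `tier1_rate`, `tier2_rate`,
#'   `tier3_rate`, `n_sims`.
#' @export
tier_power_comparison <- function(delta_grid, n_sims = 100L,
                                  config_fn = study_design_config,
                                  alpha = 0.05, n_draws = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  seed_tab <- matrix(sample.int(2^31 - 1L, length(delta_grid) * n_sims),
                     nrow = length(delta_grid))
  out <- vector("list", length(delta_grid))
  for (d in seq_along(delta_grid)) {
    t1_hits <- t1_cells <- t2_hits <- t2_species <- t3_hits <- 0L
    for (i in seq_len(n_sims)) {
      s <- seed_tab[d, i]
      ds <- generate_dataset(config_fn(sympatry_effect = delta_grid[d],
                                       seed = s))
      t1 <- run_local_foreign(ds, alpha = alpha)
      t1_hits <- t1_hits + sum(t1$verdict == "local_is_best")
      t1_cells <- t1_cells + sum(t1$verdict != "skipped")
      for (sp in unique(ds$records$species)) {
        r2 <- analyze_species(ds, sp, n_draws = n_draws, seed = s)
        t2_hits <- t2_hits + (r2$verdict == "local_adaptation")
        t2_species <- t2_species + 1L
      }
      r3 <- analyze_all_species(ds, n_draws = n_draws, seed = s)
      t3_hits <- t3_hits + (r3$verdict == "local_adaptation")
    }
    out[[d]] <- data.frame(delta = delta_grid[d],
                           tier1_rate = t1_hits / t1_cells,
                           tier2_rate = t2_hits / t2_species,
                           tier3_rate = t3_hits / n_sims,
                           n_sims = n_sims)
  }
  do.call(rbind, out)
}
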