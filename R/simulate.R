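#' Configure a synthetic reciprocal transplant experiment
#'
#' The generator draws log-scale biomass for every species x garden x
#' ecotype x replicate combination:
#' \deqn{\log B = \log(\mu_s) + G_{s,g} + Q_{s,e} + \delta\,1[e = g] + \varepsilon}
#' with garden effects \eqn{G \sim N(0, \sigma_G^2)}, ecotype intrinsic
#' quality \eqn{Q \sim N(0, \sigma_Q^2)}, residual
#' \eqn{\varepsilon \sim N(0, \sigma^2)}, all drawn independently per
#' species. `sympatry_effect` is the log-scale advantage \eqn{\delta} of
#' plants growing in their region of origin; \eqn{\delta = 0} means no local
#' adaptation, and \eqn{e^\delta - 1} is the multiplicative (percent / 100)
#' advantage. Biomass is `exp()` of the log value, hence strictly positive.
#'
#' @param regions ordered character vector of region identifiers.
#' @param species_specs named list mapping species id to its available
#'   regions (a subset of `regions` with at least 2 elements).
#' @param replicates plants per species x garden x ecotype combination.
#' @param species_mean named numeric, median biomass in grams per species.
#' @param species_sd_log residual SD on the log scale.
#' @param garden_effect_sd SD of garden main effects (log scale).
#' @param ecotype_quality_sd SD of ecotype intrinsic-quality effects
#'   (log scale).
#' @param sympatry_effect log-scale sympatry advantage \eqn{\delta}.
#' @param mortality_rate probability that a plant dies before harvest
#'   (its biomass is recorded as missing).
#' @param seed integer RNG seed.
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [generate_dataset()], [study_design_config()]
#' @export
simulation_config <- function(regions, species_specs, replicates = 12L,
                              species_mean = NULL, species_sd_log = 0.4,
                              garden_effect_sd = 0.3,
                              ecotype_quality_sd = 0.2,
                              sympatry_effect = 0, mortality_rate = 0,
                              seed = 1L) {
  regions <- as.character(regions)
  if (length(species_specs) == 0L) stop("species_specs must not be empty")
  if (is.null(names(species_specs)) || any(names(species_specs) == "")) {
    stop("species_specs must be a named list")
  }
  for (sp in names(species_specs)) {
    sr <- species_specs[[sp]]
    if (!all(sr %in% regions)) {
      stop("species '", sp, "' lists region(s) outside the vocabulary")
    }
    if (length(sr) < 2L) stop("species '", sp, "' needs at least 2 regions")
  }
  if (is.null(species_mean)) {
    species_mean <- stats::setNames(rep(1, length(species_specs)),
                                    names(species_specs))
  }
  if (is.null(names(species_mean))) {
    species_mean <- stats::setNames(rep_len(species_mean, length(species_specs)),
                                    names(species_specs))
  }
  stopifnot(
    replicates >= 1L,
    species_sd_log >= 0, garden_effect_sd >= 0, ecotype_quality_sd >= 0,
    mortality_rate >= 0, mortality_rate <= 1,
    all(species_mean > 0)
  )
  structure(
    list(regions = regions, species_specs = species_specs,
         replicates = as.integer(replicates), species_mean = species_mean,
         species_sd_log = species_sd_log, garden_effect_sd = garden_effect_sd,
         ecotype_quality_sd = ecotype_quality_sd,
         sympatry_effect = sympatry_effect, mortality_rate = mortality_rate,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Configuration reproducing the multispecies study design
#'
#' Six perennial grassland species transplanted among four regional gardens
#' in a full reciprocal layout: four species with ecotypes from all four
#' regions, two species with ecotypes from only three, and twelve replicates
#' per species x garden x ecotype combination. This yields 22 species x
#' garden cells and 984 plants. Region labels are site initials
#' (F, H, M, T); default species medians span the size range typical of
#' mixed grassland perennials (1.5-8 g dry mass after one season).
#'
#' @param sympatry_effect log-scale sympatry advantage \eqn{\delta}.
#' @param seed integer RNG seed.
#' @param replicates replicates per combination (12 for the study layout).
#' @param ... further arguments passed to [simulation_config()] to override
#'   the default variance parameters.
#' @return A `simulation_config`.
#' @export
study_design_config <- function(sympatry_effect = 0, seed = 1L,
                                replicates = 12L, ...) {
  regions <- c("F", "H", "M", "T")
  species_specs <- list(
    species_1 = regions, species_2 = regions,
    species_3 = regions, species_4 = regions,
    species_5 = c("F", "H", "M"), species_6 = c("F", "M", "T")
  )
  species_mean <- c(species_1 = 8, species_2 = 5, species_3 = 3,
                    species_4 = 2, species_5 = 4, species_6 = 1.5)
  simulation_config(regions = regions, species_specs = species_specs,
                    replicates = replicates, species_mean = species_mean,
                    sympatry_effect = sympatry_effect, seed = seed, ...)
}

# one deterministic pass: draw effects and records in a fixed ordering so
# the same seed always yields the same dataset and ground truth
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  species <- names(cfg$species_specs)
  garden_effects <- list()
  ecotype_effects <- list()
  rows <- vector("list", length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    sr <- cfg$species_specs[[sp]]
    G <- stats::setNames(stats::rnorm(length(sr), 0, cfg$garden_effect_sd), sr)
    Q <- stats::setNames(stats::rnorm(length(sr), 0, cfg$ecotype_quality_sd), sr)
    garden_effects[[sp]] <- G
    ecotype_effects[[sp]] <- Q
    grid <- expand.grid(replicate = seq_len(cfg$replicates), ecotype = sr,
                        garden = sr, stringsAsFactors = FALSE)
    eps <- stats::rnorm(nrow(grid), 0, cfg$species_sd_log)
    lb <- log(cfg$species_mean[[sp]]) + G[grid$garden] + Q[grid$ecotype] +
      cfg$sympatry_effect * (grid$ecotype == grid$garden) + eps
    biomass <- exp(lb)
    if (cfg$mortality_rate > 0) {
      dead <- stats::runif(nrow(grid)) < cfg$mortality_rate
      biomass[dead] <- NA_real_
    }
    rows[[i]] <- data.frame(species = sp, garden = grid$garden,
                            ecotype = grid$ecotype,
                            replicate = grid$replicate, biomass = biomass,
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  list(
    dataset = transplant_dataset(records, regions = cfg$regions),
    truth = list(sympatry_effect = cfg$sympatry_effect,
                 species_mean = cfg$species_mean,
                 garden_effects = garden_effects,
                 ecotype_effects = ecotype_effects)
  )
}

#' Generate a synthetic transplant dataset
#'
#' Fully reproducible from `cfg$seed`; the realized garden and ecotype
#' effects are attached as attribute `"ground_truth"` and also available via
#' [ground_truth()].
#'
#' @param cfg a [simulation_config()].
#' @return A [transplant_dataset].
#' @export
generate_dataset <- function(cfg) {
  sim <- simulate_experiment(cfg)
  attr(sim$dataset, "ground_truth") <- sim$truth
  sim$dataset
}

#' True parameters behind a simulated dataset
#'
#' Returns the generative sympatry advantage together with the realized
#' per-species garden and ecotype-quality effects for the given
#' configuration, for use in parameter-recovery tests.
#'
#' @param cfg a [simulation_config()].
#' @return A list with elements `sympatry_effect`, `species_mean`,
#'   `garden_effects`, `ecotype_effects`.
#' @export
ground_truth <- function(cfg) {
  simulate_experiment(cfg)$truth
}
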