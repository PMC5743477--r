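# localadapt

Whether plant populations are locally adapted — whether "local is best" when
choosing seed material for ecosystem restoration — depends strikingly on how
a transplant experiment is analyzed. `localadapt` implements a three-tier
statistical framework for multispecies reciprocal transplant experiments and
a synthetic-data generator that reproduces the classic full-reciprocal study
layout (6 species × 4 gardens × up to 4 ecotypes × 12 replicates), so every
stage of the analysis can be exercised and validated with known ground
truth. It is written for ecologists and biostatisticians analyzing
provenance trials, common-garden experiments, and seed-sourcing studies.

## The three tiers

Given one row per plant (species, garden region, ecotype origin region,
aboveground dry biomass as the fitness proxy):

1. **Local vs. foreign** (per species × garden cell). A one-way model
   `biomass ~ ecotype`, all-pairwise Tukey–Kramer comparisons from the
   studentized range distribution, and the strict classification:
   *local is best* iff the local ecotype significantly outperforms **every**
   foreign ecotype; *nonlocal is best* iff **any** foreign ecotype
   significantly outperforms the local one.
2. **Sympatric vs. allopatric, per species.** A linear mixed model on raw
   biomass, `biomass ~ garden + sympatric + (1 | ecotype)`, where
   `sympatric = 1[ecotype == garden]`. The effect size is the percentage
   difference between plants in sympatry and allopatry,
   `100 · β_symp / (mean fitted allopatric biomass)`.
3. **Sympatric vs. allopatric, across species.** Biomass is standardized to
   mean 0, SD 1 within each species, then
   `z ~ garden + sympatric + (1 | species:ecotype)` is fitted across all
   species; the effect size is `β_symp` in within-species SD units.

The mixed-model engine is a profiled-likelihood fitter (REML default):
for each variance ratio λ = σ²_group/σ²_resid the fixed effects are the GLS
solution and σ²_resid has a closed form, leaving a 1-D Brent search over
log λ. It agrees with `lme4::lmer` to ~1e-6 (checked in the test suite).

Inference on the sympatry effect is simulation-based: 10,000 posterior
draws of the fixed effects under a noninformative prior
(σ² ~ scaled-inverse-χ², β | σ² Gaussian around the estimates, variance
components held fixed), giving 95% credible intervals and the posterior
probability P(sympatric > allopatric). Probability > 0.95 is read as
evidence of local adaptation, < 0.05 as maladaptation. A resampling check
refits the cross-species model on 10,000 species-stratified subsamples the
size of a single-species model, reporting how often the effect points
toward a sympatric advantage. Approximate conditional R² (the
Nakagawa–Schielzeth form) summarizes model fit.

## Worked example

```r
library(localadapt)

# simulate the full reciprocal design with a 20% sympatric advantage
ds <- generate_dataset(study_design_config(sympatry_effect = log(1.2), seed = 1))
summarize_design(ds)
#> Design: 6 species, 4 gardens, 22 species x garden cells, 984 measured plants (of 984 records)

# tier 1: strict per-cell classification
table(run_local_foreign(ds, alpha = 0.05)$verdict)
#>    local_is_best    no_difference nonlocal_is_best
#>                2               19                1

# tier 2: one species
analyze_species(ds, "species_1", n_draws = 2000, seed = 1)
#> Sympatric/allopatric contrast [species_1], n = 192
#>   sympatry effect: +10.5% [-4.5, 26.7]
#>   P(sympatric > allopatric) = 0.917 -> inconclusive; conditional R2 = 0.396

# tier 3: all species pooled
analyze_all_species(ds, n_draws = 2000, seed = 1)
#> Sympatric/allopatric contrast [ALL], n = 984
#>   sympatry effect (SD units): +0.338 [0.205, 0.473]
#>   P(sympatric > allopatric) = 1.000 -> local_adaptation; conditional R2 = 0.103
```

Even with a genuine 20% advantage built into every species, the strict
tier-1 rule certifies "local is best" in only 2 of 22 cells (and calls one
cell maladapted), the per-species models are mostly inconclusive, and the
pooled cross-species model detects local adaptation decisively — the power
ordering the framework is designed to expose. `run_pipeline()` executes all
three tiers plus the resampling check from one config and writes tidy CSV /
JSON outputs.

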