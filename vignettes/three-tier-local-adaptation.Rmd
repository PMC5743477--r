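---
title: "Three tiers of evidence for local adaptation in reciprocal transplants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three tiers of evidence for local adaptation in reciprocal transplants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localadapt)
```

## The problem

Reciprocal transplant experiments grow seed material from several origin
regions ("ecotypes") at gardens located in those same regions. Local
adaptation predicts that a plant grown in its region of origin (in
*sympatry*) outperforms plants grown away from home (in *allopatry*). The
same dataset, however, supports three quite different questions, and the
three corresponding analyses differ enormously in stringency and power.
`localadapt` implements all three so their conclusions can be compared on
equal footing, and ships a generator for the canonical full reciprocal
layout so every claim the package makes can be checked against data with
known ground truth.

The package's data unit is one measured plant: species, garden region,
ecotype origin region, replicate label, and aboveground dry biomass in
grams as the fitness proxy. A plant is sympatric when `ecotype == garden`.
Plants that died before harvest carry a missing biomass; they stay in the
dataset and are excluded from every model fit (complete-case within each
model — the standard default for a single-harvest design). Replicate ids
are labels only; no blocking structure is modeled.

## Tier 1: local vs. foreign, per site

For each species × garden cell, `fit_cell()` fits the one-way model
`biomass ~ ecotype` (group means, pooled residual variance, R² =
SS\_between / SS\_total) and `tukey_pairwise()` adjusts all k(k−1)/2
pairwise comparisons with the studentized range distribution, using the
Tukey–Kramer standard error for unequal group sizes:

$$q = \frac{|\bar y_a - \bar y_b|}{\sqrt{\tfrac{s^2}{2}\left(\tfrac{1}{n_a}+\tfrac{1}{n_b}\right)}},
\qquad p = P(Q_{k,\nu} \ge q).$$

For k = 2 the range statistic reduces exactly to $|t|\sqrt2$, and the
implementation uses that closed form (the pooled two-sided t-test p-value)
rather than the numeric tail of the q distribution; for k > 2 the tail is
validated in the tests against a 10⁶-draw Monte-Carlo simulation of the
studentized range and against `multcomp`'s single-step contrasts. Whether
the single-step multivariate-t adjustment (which differs slightly from the
studentized range for unbalanced cells) should be preferred is not
determinable from the framework itself; the studentized-range choice is
fixed here and tested against its own oracle.

`classify_cell()` applies the strict rule: **local is best** only if the
local ecotype's mean is strictly greater than every foreign ecotype's *and*
each of those pairs is significant at α (default 0.05); **nonlocal is
best** if any foreign ecotype significantly outperforms the local one. Both
directionality and significance are required — "outperformed" alone is not
enough. The rule is deliberately asymmetric and very conservative: one
non-significant pair denies "local is best", while a single significant
reversal certifies maladaptation. Compact-letter displays are not part of
the classification path; the pairwise table is used directly.

## Tiers 2 and 3: sympatric vs. allopatric mixed models

The per-species model (`analyze_species()`) is fitted on raw biomass:

$$y = \beta_0 + \text{garden} + \beta_s\,\text{sympatric} + u_{\text{ecotype}} + \varepsilon,
\qquad u \sim N(0, \sigma_g^2),\ \varepsilon \sim N(0, \sigma^2).$$

Ecotype enters as a *random* intercept rather than a fixed factor: the
variance of ecotype quality is corrected for, but not its mean, because for
restoration decisions intrinsic quality differences between seed sources
are part of the practical reality. The effect size is reported as the
percentage difference between sympatry and allopatry,
$100\,\beta_s / \bar y_{\text{allo}}$, where the allopatric baseline is the
model-fitted value averaged over the species' gardens with random effects
at zero — a pure function of the fitted model, insensitive to accidental
imbalance in the raw allopatric mean. The percent effect is recomputed for
every posterior draw, so its interval reflects uncertainty in both the
numerator and the baseline.

The cross-species model (`analyze_all_species()`) first standardizes
biomass within species (sample SD, n−1 denominator; results at these sample
sizes are insensitive to the population-SD alternative) so that species of
very different stature contribute comparably, then fits the same fixed
structure with a single random intercept on the composite key
`species:ecotype`. Because within-species standardization removes species
means, no separate species-level intercept is included — "ecotype nested in
species" collapses to the composite-key intercept. The effect size is
$\beta_s$ in within-species SD units.

### The mixed-model engine

`fit_lmm()` maximizes the Gaussian likelihood (REML by default; ML is used
where likelihoods must be comparable across refits, as in the resampling
check) by profiling: at each variance ratio
$\lambda = \sigma_g^2/\sigma^2$, the inverse covariance follows from the
Woodbury identity on the block structure, the fixed effects are the GLS
solution, and $\sigma^2$ is closed-form, leaving a one-dimensional Brent
search over $\log\lambda \in [\log 10^{-10}, \log 10^{10}]$ with the
$\lambda = 0$ boundary checked explicitly — negative variance estimates
are impossible by construction, and $\sigma_g^2 = 0$ is a legitimate
outcome. Dummy coding uses the first-observed level as reference, recorded
in `design_info`. `loglik_at()` exposes the objective so tests can verify
the maximum against generic two-parameter optimization; the suite also
checks the engine against closed-form balanced ANOVA estimators and
against `lme4` (agreement ~1e-6, including the log-likelihood value).

### Posterior inference

`simulate_posterior()` draws fixed-effect samples under a noninformative
prior: $\sigma^2 = \hat\sigma^2\nu/\chi^2_\nu$ with $\nu$ the residual
degrees of freedom, then $\beta \mid \sigma^2 \sim
N(\hat\beta, (\sigma^2/\hat\sigma^2)\,\widehat{\text{cov}}(\hat\beta))$.
Variance components are *not* resampled — the convention of the classic
`sim` approach; the intervals therefore understate variance-component
uncertainty, a documented limitation that matters most when the number of
random-effect levels is small. Draws are seeded and bit-reproducible.
Credible intervals are equal-tailed type-7 empirical quantiles (fixed so
intervals are reproducible); the posterior probability counts exact zeros
half toward each side so the two directions always sum to one. The default
is 10,000 draws; the evidence thresholds are posterior probability > 0.95
for local adaptation and < 0.05 for maladaptation. The engine's REML
estimates seed the posterior by default (the point estimates, not their
ML variants; both are available via `method`).

Approximate conditional R² uses the Nakagawa–Schielzeth form
$({\rm var}(X\hat\beta) + \hat\sigma_g^2) / ({\rm var}(X\hat\beta) +
\hat\sigma_g^2 + \hat\sigma^2)$, with 0 returned by convention when all
components vanish.

### Equalizing power: the resampling check

The cross-species model sees every plant, so part of its advantage over the
per-species models is sheer sample size. `resample_power_check()` redraws
`target_n` rows without replacement from the standardized cross-species
data — stratified proportionally by species with largest-remainder
rounding, so no species vanishes from a subsample — refits by ML, and
records the sign of the sympatry coefficient; the report is the proportion
of permutations pointing toward a sympatric advantage. Which
single-species sample size the subsample should match is genuinely
ambiguous in a design whose species differ in size (192 vs 108 plants
here); the default is the largest single-species n, exposed as a
parameter. Subsamples that cannot support the model (fewer than two
random-effect levels, a degenerate fixed design) are redrawn up to a cap.

## The synthetic-data generator

`generate_dataset()` draws log-scale biomass per plant:

$$\log B = \log\mu_s + G_{s,g} + Q_{s,e} + \delta\,1[e=g] + \varepsilon,$$

with per-species garden effects $G \sim N(0,\sigma_G^2)$, ecotype
intrinsic-quality effects $Q \sim N(0,\sigma_Q^2)$ and residual
$\varepsilon \sim N(0,\sigma^2)$. The model is multiplicative (log-normal)
so biomass is strictly positive and $\delta$ maps directly onto the percent
effect size ($e^\delta - 1$). Effects are drawn independently per species —
the per-species analysis tier treats species separately, so independence is
the minimal assumption. A single seeded stream, consumed in a fixed
species/garden/ecotype/replicate order, makes every dataset and its
`ground_truth()` (realized $G$, $Q$, $\delta$) exactly reproducible.

`study_design_config()` reproduces the canonical layout: 6 species, 4
garden regions, 12 replicates, with two species restricted to 3 regions —
22 species × garden cells and 984 plants. The variance defaults are package
choices, not study estimates (none are published):
$\sigma_G = 0.3$ (gardens are the dominant environmental signal),
$\sigma_Q = 0.2$ (real provenances differ in intrinsic quality),
$\sigma = 0.4$ (log-scale residual typical of biomass data), species
medians 1.5–8 g spanning the stature range of mixed grassland perennials,
and mortality 0 (per-cell realized sample sizes in the original design are
unknown; the mortality parameter exists for sensitivity work).

What the generator does *not* emulate: genotype × environment structure
beyond the single sympatry indicator, spatial or temporal autocorrelation,
year effects, and non-normal residuals. Passing tests therefore demonstrate
that the machinery is correct and calibrated under a clean factorial
log-normal world — not that any particular field dataset satisfies those
assumptions.

## Calibration results the test suite computes

Problem sizes here are the package's chosen simulation scales.

- **Type-I error** (200 null datasets, 2,000 draws each): the cross-species
  local-adaptation verdict fires at the nominal 5% rate, and the strict
  tier-1 rule certifies "local is best" in well under 5% of cells — it is
  conservative by construction, as the all-pairs requirement implies.
- **Power ordering** (δ ∈ {0.05, 0.15, 0.3}, 100 simulations each, with
  heterogeneous ecotype quality): detection frequency satisfies
  tier 3 ≥ tier 2 ≥ tier 1 at every grid point. This is the framework's
  headline property: the same data can look like "no local adaptation"
  under the strict per-site rule and like decisive local adaptation under
  the pooled sympatric/allopatric test.
- **Interval coverage** (δ = ln 1.2, 4× replication, 200 simulations): the
  tier-3 credible interval covers the generative effect ~95% of the time.
  The reference value is computed per dataset, conditional on its realized
  garden and ecotype effects, by rebuilding a 1,500-replicate dataset from
  the same `ground_truth()` and refitting — under a multiplicative
  generative model the sympatry coefficient of the additive analysis model
  depends on the realized effects, so the marginal average across datasets
  is not the quantity a single dataset's interval estimates.
- **Resampling null symmetry** (1,000 independent null datasets, one
  subsample refit each): the sympatry coefficient is positive in half the
  refits, as an exact binomial check. Note that repeated subsamples of
  *one* dataset are strongly correlated (they share the full-data
  estimate), so the 0.5 expectation holds across datasets, not within one.

## Numerical choices and degenerate inputs

Zero residual variance in a tier-1 cell yields p = 0 for unequal means and
p = 1 for equal means; an all-constant cell has R² defined as 0. Cells
failing preconditions (fewer than 2 ecotypes, a group with fewer than 2
plants) are reported as skipped with the reason, not errors. Non-positive
or non-finite biomass on input is treated as missing. The profiled
optimizer's reported log-likelihood is verified to within 1e-5 of generic
two-parameter maximization on randomized problems; ties at the variance
boundary resolve to σ²_g = 0. All pipeline randomness flows from one master
seed split by fixed stage offsets, and every output row carries that seed.

## Limitations

Single-harvest, single-response data only; no crossed random effects,
random slopes, survival/fecundity composites, or geographic-distance
predictors. The posterior is a large-sample approximation around the
(RE)ML fit rather than a full MCMC posterior, and variance components are
treated as known at their estimates.
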