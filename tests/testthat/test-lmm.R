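# random small dataset with a grouping factor and one binary fixed term
random_lmm_data <- function(seed, n_groups = 5, m = 6, sg = 0.6, se = 0.8) {
  set.seed(seed)
  g <- rep(paste0("g", seq_len(n_groups)), each = m)
  x <- rbinom(n_groups * m, 1, 0.5)
  y <- 1 + 0.5 * x + rep(rnorm(n_groups, 0, sg), each = m) +
    rnorm(n_groups * m, 0, se)
  data.frame(y = y, x = x, g = g, stringsAsFactors = FALSE)
}

test_that("zero between-group variability collapses to the OLS solution", {
  # identical value sets in every group: between-group mean square is zero,
  # so the group variance sits on the boundary and the fit is plain OLS
  set.seed(51)
  template_y <- rnorm(10)
  template_x <- rbinom(10, 1, 0.5)
  d <- data.frame(y = rep(template_y, 4), x = rep(template_x, 4),
                  g = rep(c("a", "b", "c", "d"), each = 10))
  spec <- lmm_spec("y", "x", "g", method = "REML")
  fit <- fit_lmm(d, spec)
  ols <- lm(y ~ x, d)
  expect_lt(fit$sigma2_group, 1e-8)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  # ML at the boundary equals the OLS Gaussian log-likelihood closed form
  specml <- lmm_spec("y", "x", "g", method = "ML")
  rss <- sum(resid(ols)^2); n <- nrow(d); s2 <- rss / n
  ll_closed <- -0.5 * (n * log(2 * pi * s2) + n)
  expect_equal(loglik_at(d, specml, sigma2_group = 0, sigma2_resid = s2,
                         beta = coef(ols)),
               ll_closed, tolerance = 1e-10)
})

test_that("balanced one-way variance components match the ANOVA estimators", {
  set.seed(52)
  J <- 8; m <- 5
  g <- rep(paste0("g", 1:J), each = m)
  y <- rep(rnorm(J, 0, 1.2), each = m) + rnorm(J * m, 0, 0.7)
  d <- data.frame(y = y, g = g, x = 1)
  spec <- lmm_spec("y", character(0), "g", method = "REML")
  fit <- fit_lmm(d, spec)
  gm <- tapply(y, g, mean)
  msb <- m * var(gm)
  msw <- sum((y - gm[g])^2) / (J * (m - 1))
  expect_equal(fit$sigma2_resid, msw, tolerance = 1e-6)
  expect_equal(fit$sigma2_group, (msb - msw) / m, tolerance = 1e-6)
  # REML and ML fixed effects agree in the balanced case
  fitml <- fit_lmm(d, lmm_spec("y", character(0), "g", method = "ML"))
  expect_equal(fit$beta, fitml$beta, tolerance = 1e-8)
})

test_that("profiled search attains the maximum found by a 2-parameter optimizer", {
  for (seed in 1:20) {
    d <- random_lmm_data(seed)
    for (method in c("ML", "REML")) {
      spec <- lmm_spec("y", "x", "g", method = method)
      fit <- fit_lmm(d, spec)
      neg <- function(par) {
        -loglik_at(d, spec, sigma2_group = exp(par[1]),
                   sigma2_resid = exp(par[2]))
      }
      opt <- optim(c(log(0.3), log(0.5)), neg, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
      expect_gte(fit$loglik, -opt$value - 1e-5)
      # and the fit's own reported parameters reproduce its log-likelihood
      expect_equal(loglik_at(d, spec, fit$sigma2_group, fit$sigma2_resid),
                   fit$loglik, tolerance = 1e-6)
    }
  }
})

test_that("fitted parameters beat random perturbations of the likelihood", {
  d <- random_lmm_data(101)
  spec <- lmm_spec("y", "x", "g", method = "ML")
  fit <- fit_lmm(d, spec)
  set.seed(7)
  for (i in 1:50) {
    ll <- loglik_at(d, spec,
                    sigma2_group = fit$sigma2_group * exp(rnorm(1, 0, 0.4)),
                    sigma2_resid = fit$sigma2_resid * exp(rnorm(1, 0, 0.4)),
                    beta = fit$beta + rnorm(length(fit$beta), 0, 0.2))
    expect_lte(ll, fit$loglik + 1e-8)
  }
})

test_that("doubling the response shifts the ML log-likelihood by -n log 2", {
  d <- random_lmm_data(102)
  spec <- lmm_spec("y", "x", "g", method = "ML")
  fit <- fit_lmm(d, spec)
  d2 <- d; d2$y <- 2 * d$y
  ll2 <- loglik_at(d2, spec, sigma2_group = 4 * fit$sigma2_group,
                   sigma2_resid = 4 * fit$sigma2_resid, beta = 2 * fit$beta)
  expect_equal(ll2, fit$loglik - nrow(d) * log(2), tolerance = 1e-8)
})

test_that("fit is invariant to row order and group relabeling", {
  d <- random_lmm_data(103)
  spec <- lmm_spec("y", "x", "g", method = "REML")
  fit <- fit_lmm(d, spec)
  set.seed(9)
  d2 <- d[sample(nrow(d)), ]
  d2$g <- chartr("g", "Z", d2$g)
  fit2 <- fit_lmm(d2, spec)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-8)
  expect_equal(fit$sigma2_group, fit2$sigma2_group, tolerance = 1e-6)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-9)
})

test_that("estimates and likelihood agree with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  ds <- generate_dataset(study_design_config(0.15, seed = 42))
  std <- standardize_within_species(ds)
  spec <- lmm_spec("biomass_std", c("garden", "sympatric"),
                   "species_ecotype", method = "REML")
  fit <- fit_lmm(std, spec)
  m <- lme4::lmer(biomass_std ~ garden + sympatric + (1 | species_ecotype),
                  std, REML = TRUE)
  expect_equal(max(abs(fit$beta - lme4::fixef(m))), 0, tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$sigma2_group, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-5)
})

test_that("rank-deficient designs and degenerate groupings are rejected", {
  d <- random_lmm_data(104)
  d$x2 <- d$x   # exact copy: collinear
  expect_error(fit_lmm(d, lmm_spec("y", c("x", "x2"), "g")),
               "rank deficient.*x2")
  d$one_group <- "same"
  expect_error(fit_lmm(d, lmm_spec("y", "x", "one_group")),
               "fewer than 2 levels")
  expect_error(fit_lmm(d, lmm_spec("y", "x", "nope")), "not found")
})

test_that("parameter recovery: the sympatry coefficient tracks the generative advantage", {
  delta <- 0.2
  cfg <- one_species_config(delta, seed = 77, replicates = 120,
                            species_sd_log = 0.1, garden_effect_sd = 0.05,
                            ecotype_quality_sd = 0.05)
  ds <- generate_dataset(cfg)
  rec <- ds$records
  rec$sympatric <- as.integer(rec$ecotype == rec$garden)
  fit <- fit_lmm(rec, lmm_spec("biomass", c("garden", "sympatric"), "ecotype"))
  # small-noise multiplicative model: additive contrast ~ mean_allo * (e^d - 1)
  implied <- mean(rec$biomass[rec$sympatric == 0]) * (exp(delta) - 1)
  se <- sqrt(fit$beta_cov["sympatric", "sympatric"])
  expect_lt(abs(fit$beta[["sympatric"]] - implied), 3 * se + 0.02 * implied)
})
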