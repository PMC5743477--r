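test_that("one-way cell fit matches the hand-computed ANOVA", {
  df <- data.frame(species = "s", garden = "A",
                   ecotype = rep(c("A", "B"), each = 2), replicate = 1:4,
                   biomass = c(2, 4, 6, 8))
  ds <- transplant_dataset(df,
                           regions = c("A", "B"))
  fit <- fit_cell(ds, "s", "A")
  expect_equal(fit$ecotype_means, c(A = 3, B = 7), tolerance = 1e-12)
  expect_equal(fit$residual_variance, 2, tolerance = 1e-12)
  expect_equal(fit$residual_df, 2L)
  expect_equal(fit$r_squared, 16 / 20, tolerance = 1e-12)
})

test_that("cell fit handles degenerate data and enforces preconditions", {
  df <- data.frame(species = "s", garden = "A",
                   ecotype = rep(c("A", "B"), each = 2), replicate = 1:4,
                   biomass = rep(5, 4))
  ds <- transplant_dataset(df)
  fit <- fit_cell(ds, "s", "A")
  expect_equal(fit$r_squared, 0)
  expect_equal(fit$residual_variance, 0)
  pt <- tukey_pairwise(fit)
  expect_equal(pt$p_adj, 1)

  # zero residual variance with unequal means: p = 0
  df$biomass <- rep(c(1, 2), each = 2)
  pt2 <- tukey_pairwise(fit_cell(transplant_dataset(df), "s", "A"))
  expect_equal(pt2$p_adj, 0)

  one_eco <- df; one_eco$ecotype <- "A"
  expect_error(fit_cell(transplant_dataset(one_eco), "s", "A"),
               "fewer than 2 ecotypes")
  thin <- df[c(1, 3, 4), ]
  expect_error(fit_cell(transplant_dataset(thin), "s", "A"),
               "fewer than 2 observations")
})

test_that("cell fit is invariant to observation order and label names", {
  set.seed(21)
  df <- data.frame(species = "s", garden = "A",
                   ecotype = rep(c("A", "B", "C"), each = 5),
                   replicate = 1:15, biomass = rexp(15) + 1)
  ds <- transplant_dataset(df)
  fit <- fit_cell(ds, "s", "A")
  shuf <- transplant_dataset(df[sample(15), ])
  fit2 <- fit_cell(shuf, "s", "A")
  expect_equal(sort(fit$ecotype_means), sort(fit2$ecotype_means))
  expect_equal(fit$r_squared, fit2$r_squared)
  expect_equal(fit$residual_variance, fit2$residual_variance)
})

test_that("Tukey p with two groups equals the pooled two-sided t-test", {
  set.seed(31)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    df <- data.frame(species = "s", garden = "G",
                     ecotype = rep(c("G", "B"), c(n1, n2)),
                     replicate = seq_len(n1 + n2),
                     biomass = rexp(n1 + n2) + 0.5)
    fit <- fit_cell(transplant_dataset(df), "s", "G")
    p_tukey <- tukey_pairwise(fit)$p_adj
    p_t <- t.test(biomass ~ ecotype, df, var.equal = TRUE)$p.value
    expect_equal(p_tukey, p_t, tolerance = 1e-10)
  }
})

test_that("Tukey-adjusted p matches a Monte-Carlo studentized range tail", {
  df <- data.frame(species = "s", garden = "A",
                   ecotype = rep(c("A", "B", "C"), each = 4),
                   replicate = 1:12,
                   biomass = c(3.1, 2.7, 3.4, 2.9, 4.0, 4.4, 3.8, 4.1,
                               3.2, 3.0, 3.6, 3.3))
  fit <- fit_cell(transplant_dataset(df), "s", "A")
  tab <- tukey_pairwise(fit)
  # observed studentized range statistic for the A-B pair
  n <- 4; k <- 3; dfres <- fit$residual_df
  i <- which(tab$ecotype_a == "A" & tab$ecotype_b == "B")
  q_obs <- abs(tab$diff[i]) / sqrt(fit$residual_variance / n)
  set.seed(17)
  m <- 1e6
  Z1 <- rnorm(m); Z2 <- rnorm(m); Z3 <- rnorm(m)
  rng <- pmax(Z1, Z2, Z3) - pmin(Z1, Z2, Z3)
  S <- sqrt(rchisq(m, dfres) / dfres)
  p_mc <- mean(rng / S >= q_obs)
  expect_equal(tab$p_adj[i], p_mc, tolerance = 0.005)
})

test_that("pairwise table agrees with multcomp's single-step Tukey contrasts", {
  skip_if_not_installed("multcomp")
  set.seed(41)
  df <- data.frame(species = "s", garden = "A",
                   ecotype = rep(c("A", "B", "C", "D"), each = 6),
                   replicate = 1:24,
                   biomass = rlnorm(24, meanlog = rep(c(0, 0.3, 0.1, 0.5),
                                                      each = 6), sdlog = 0.3))
  fit <- fit_cell(transplant_dataset(df), "s", "A")
  tab <- tukey_pairwise(fit)
  df$ecotype <- factor(df$ecotype)
  mod <- stats::aov(biomass ~ ecotype, df)
  gl <- summary(multcomp::glht(mod, linfct = multcomp::mcp(ecotype = "Tukey")))
  p_mc <- as.numeric(gl$test$pvalues)
  names(p_mc) <- rownames(gl$linfct)
  key <- paste(tab$ecotype_b, "-", tab$ecotype_a)
  expect_equal(tab$p_adj, unname(p_mc[key]), tolerance = 2e-3)
})

test_that("classification follows the strict rule over all sign/significance patterns", {
  pat <- expand.grid(d1 = c(1, -1), s1 = c(TRUE, FALSE),
                     d2 = c(1, -1), s2 = c(TRUE, FALSE))
  for (r in seq_len(nrow(pat))) {
    p <- pat[r, ]
    tab <- make_pairs(data.frame(
      ecotype_a = c("L", "L", "a"),
      ecotype_b = c("a", "b", "b"),
      diff = c(p$d1 * 2, p$d2 * 2, 5),
      p_adj = c(ifelse(p$s1, 0.01, 0.4), ifelse(p$s2, 0.01, 0.4), 0.001)
    ))
    got <- classify_cell(tab, "L")$verdict
    beats <- c(p$d1 > 0 & p$s1, p$d2 > 0 & p$s2)
    beaten <- c(p$d1 < 0 & p$s1, p$d2 < 0 & p$s2)
    want <- if (all(beats)) "local_is_best"
            else if (any(beaten)) "nonlocal_is_best" else "no_difference"
    expect_identical(got, want)
  }
  expect_error(classify_cell(make_pairs(data.frame(
    ecotype_a = "x", ecotype_b = "y", diff = 1, p_adj = 0.5)), "L"),
    "not present")
})

test_that("verdicts are invariant to reversed pair orientation", {
  tab <- make_pairs(data.frame(ecotype_a = c("a", "b"), ecotype_b = c("L", "L"),
                               diff = c(-3, -1), p_adj = c(0.01, 0.02)))
  expect_identical(classify_cell(tab, "L")$verdict, "local_is_best")
})

test_that("the full local/foreign scan covers every cell and reports skips", {
  ds <- generate_dataset(study_design_config(3, seed = 5,
                                             species_sd_log = 0.05,
                                             garden_effect_sd = 0.05,
                                             ecotype_quality_sd = 0.02))
  res <- run_local_foreign(ds)
  expect_equal(nrow(res), 22L)
  expect_true(all(res$verdict == "local_is_best"))

  # knock out a cell's replication: it is skipped, the rest still run
  ds2 <- generate_dataset(study_design_config(0, seed = 6))
  drop <- with(ds2$records, species == "species_1" & garden == "F" &
                 ecotype == "H" & replicate > 1)
  ds2$records$biomass[drop] <- NA
  res2 <- run_local_foreign(ds2)
  sk <- res2[res2$species == "species_1" & res2$garden == "F", ]
  expect_identical(sk$verdict, "skipped")
  expect_match(sk$reason, "fewer than 2 observations")
  expect_equal(sum(res2$verdict != "skipped"), 21L)
})
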