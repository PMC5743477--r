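#' One-way ecotype model for a single species x garden cell
#'
#' Fits the one-way fixed-effects model biomass ~ ecotype within one garden
#' for one species: group means, pooled within-group (residual) variance and
#' the model R-squared (between-group over total sum of squares). Missing
#' biomass rows are dropped.
#'
#' @param ds a [transplant_dataset].
#' @param species,garden identify the cell.
#' @return An object of class `cell_fit` with elements `species`, `garden`,
#'   `ecotype_means`, `group_n`, `residual_variance`, `residual_df`,
#'   `r_squared`.
#' @export
fit_cell <- function(ds, species, garden) {
  rec <- complete_records(ds)
  rec <- rec[rec$species == species & rec$garden == garden, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no data for species '", species,
                            "' in garden '", garden, "'")
  y <- rec$biomass
  g <- factor(rec$ecotype, levels = unique(rec$ecotype))
  k <- nlevels(g)
  if (k < 2L) stop("cell has fewer than 2 ecotypes; one-way model undefined")
  n_i <- tabulate(g)
  if (any(n_i < 2L)) {
    stop("ecotype '", levels(g)[which(n_i < 2L)[1L]],
         "' has fewer than 2 observations in this cell")
  }
  n <- length(y)
  means <- tapply(y, g, mean)
  sse <- sum((y - means[g])^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(
      species = species, garden = garden,
      ecotype_means = stats::setNames(as.numeric(means), levels(g)),
      group_n = stats::setNames(n_i, levels(g)),
      residual_variance = sse / (n - k),
      residual_df = n - k,
      r_squared = if (sst > 0) 1 - sse / sst else 0
    ),
    class = "cell_fit"
  )
}

#' Tukey all-pairwise ecotype comparisons
#'
#' Computes every unordered pair of ecotype mean differences within a cell
#' and adjusts p-values with the studentized range distribution
#' (Tukey-Kramer form for unequal group sizes):
#' \deqn{q = |\bar y_a - \bar y_b| / \sqrt{(s^2/2)(1/n_a + 1/n_b)},\quad
#'       p = P(Q_{k,\nu} \ge q)}
#' with \eqn{k} groups and \eqn{\nu} residual degrees of freedom. When the
#' residual variance is exactly zero, unequal means get p = 0 and equal
#' means p = 1.
#'
#' @param fit a [fit_cell()] result.
#' @param alpha significance level carried into downstream classification.
#' @return An object of class `pairwise_comparisons`: data.frame with
#'   columns `ecotype_a`, `ecotype_b`, `diff` (mean a minus mean b),
#'   `p_adj`, plus attributes `alpha` and `means`.
#' @export
tukey_pairwise <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cell_fit"))
  if (fit$residual_df < 1L) stop("residual degrees of freedom must be >= 1")
  means <- fit$ecotype_means
  n_i <- fit$group_n
  k <- length(means)
  pairs <- utils::combn(names(means), 2L)
  diff <- means[pairs[1L, ]] - means[pairs[2L, ]]
  s2 <- fit$residual_variance
  if (s2 > 0) {
    se <- sqrt(s2 / 2 * (1 / n_i[pairs[1L, ]] + 1 / n_i[pairs[2L, ]]))
    q_obs <- abs(diff) / se
    if (k == 2L) {
      # exact closed form: the range of 2 means reduces to |t| * sqrt(2)
      p_adj <- 2 * stats::pt(q_obs / sqrt(2), df = fit$residual_df,
                             lower.tail = FALSE)
    } else {
      p_adj <- stats::ptukey(q_obs, nmeans = k, df = fit$residual_df,
                             lower.tail = FALSE)
    }
  } else {
    p_adj <- ifelse(abs(diff) > 0, 0, 1)
  }
  out <- data.frame(ecotype_a = pairs[1L, ], ecotype_b = pairs[2L, ],
                    diff = as.numeric(diff), p_adj = as.numeric(p_adj),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, alpha = alpha, means = means, class = c("pairwise_comparisons", "data.frame"))
}

#' Classify a cell as local-is-best, nonlocal-is-best, or no difference
#'
#' The strict local-vs-foreign rule: `"local_is_best"` requires the local
#' ecotype to have a strictly greater mean than *every* nonlocal ecotype
#' with the Tukey-adjusted p-value below alpha for each pair;
#' `"nonlocal_is_best"` (maladaptation) requires at least one nonlocal
#' ecotype to significantly outperform the local one; anything else is
#' `"no_difference"`. The two verdicts are mutually exclusive.
#'
#' @param pairs a [tukey_pairwise()] table.
#' @param local_ecotype the ecotype whose origin region is this garden.
#' @return An object of class `cell_verdict`: list with `verdict`,
#'   `local_ecotype`, `n_significant_pairs`, and the supporting comparisons
#'   against the local ecotype.
#' @export
classify_cell <- function(pairs, local_ecotype) {
  stopifnot(inherits(pairs, "pairwise_comparisons"))
  alpha <- attr(pairs, "alpha")
  in_a <- pairs$ecotype_a == local_ecotype
  in_b <- pairs$ecotype_b == local_ecotype
  if (!any(in_a | in_b)) stop("local ecotype '", local_ecotype,
                              "' not present in the comparison table")
  rel <- pairs[in_a | in_b, , drop = FALSE]
  # orient every difference as local minus nonlocal
  rel$diff <- ifelse(rel$ecotype_a == local_ecotype, rel$diff, -rel$diff)
  rel$nonlocal <- ifelse(rel$ecotype_a == local_ecotype,
                         rel$ecotype_b, rel$ecotype_a)
  local_best <- all(rel$diff > 0 & rel$p_adj < alpha)
  nonlocal_best <- any(rel$diff < 0 & rel$p_adj < alpha)
  verdict <- if (local_best) "local_is_best"
             else if (nonlocal_best) "nonlocal_is_best"
             else "no_difference"
  structure(
    list(verdict = verdict, local_ecotype = local_ecotype,
         n_significant_pairs = sum(pairs$p_adj < alpha),
         comparisons = rel[, c("nonlocal", "diff", "p_adj")]),
    class = "cell_verdict"
  )
}

#' Run the local/foreign analysis over every species x garden cell
#'
#' Applies [fit_cell()], [tukey_pairwise()] and [classify_cell()] to each
#' cell of the dataset. Cells that fail the fitting preconditions (too few
#' ecotypes or replicates) are reported as skipped with the reason rather
#' than aborting the run.
#'
#' @param ds a [transplant_dataset].
#' @param alpha significance level for the Tukey-adjusted comparisons.
#' @return A data.frame with one row per cell: `species`, `garden`,
#'   `verdict` (`"local_is_best"`, `"nonlocal_is_best"`, `"no_difference"`,
#'   or `"skipped"`), `local_ecotype`, `n_significant_pairs`, `r_squared`,
#'   `reason` (NA unless skipped).
#' @export
run_local_foreign <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "transplant_dataset"))
  cells <- unique(ds$records[, c("species", "garden")])
  cells <- cells[order(cells$species, cells$garden), , drop = FALSE]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]; gd <- cells$garden[i]
    res <- tryCatch({
      fit <- fit_cell(ds, sp, gd)
      verdict <- classify_cell(tukey_pairwise(fit, alpha), local_ecotype = gd)
      data.frame(species = sp, garden = gd, verdict = verdict$verdict,
                 local_ecotype = gd,
                 n_significant_pairs = verdict$n_significant_pairs,
                 r_squared = fit$r_squared, reason = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(species = sp, garden = gd, verdict = "skipped",
                 local_ecotype = gd, n_significant_pairs = NA_integer_,
                 r_squared = NA_real_, reason = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
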