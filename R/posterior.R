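#' Simulate posterior draws of the fixed effects
#'
#' Simulation-based Bayesian summary of a fitted mixed model under a
#' noninformative prior, following the classic sim convention: for each
#' draw, the residual variance is sampled from its scaled inverse-chi-square
#' conditional, \eqn{\sigma^2 = \hat\sigma^2\,\nu / \chi^2_\nu} with
#' \eqn{\nu} the residual degrees of freedom, and the coefficients from
#' \eqn{\beta \mid \sigma^2 \sim N(\hat\beta,\,
#' (\sigma^2/\hat\sigma^2)\,\widehat{\mathrm{cov}}(\hat\beta))}. Variance
#' components are held at their point estimates (not resampled), so the
#' draws describe fixed-effect uncertainty only.
#'
#' @param fit an [fit_lmm()] result.
#' @param n_draws number of posterior samples (the analysis default is
#'   10,000).
#' @param seed integer seed; the whole draw matrix is reproducible from it.
#' @return An object of class `posterior_draws`: `draws`
#'   (n_draws x n_coefficients matrix, named columns), `sigma_draws`
#'   (residual-SD samples), `n_draws`, `seed`.
#' @export
simulate_posterior <- function(fit, n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "lmm_fit"), n_draws >= 1L)
  if (fit$df_resid < 1L) stop("positive residual degrees of freedom required")
  p <- length(fit$beta)
  # symmetric square root via eigendecomposition: tolerates the PSD boundary
  ev <- eigen((fit$beta_cov + t(fit$beta_cov)) / 2, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1))) {
    stop("beta_cov is not positive semidefinite")
  }
  R <- diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
  set.seed(as.integer(seed))
  nu <- fit$df_resid
  sigma_hat <- sqrt(fit$sigma2_resid)
  sigma_draws <- sigma_hat * sqrt(nu / stats::rchisq(n_draws, df = nu))
  Z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  draws <- sweep(Z %*% R, 1L, sigma_draws / sigma_hat, `*`)
  draws <- sweep(draws, 2L, fit$beta, `+`)
  colnames(draws) <- names(fit$beta)
  structure(list(draws = draws, sigma_draws = sigma_draws,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "posterior_draws")
}

# resolve a coefficient name or weight vector into a vector of effect draws
effect_draws <- function(draws, effect) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.character(effect)) {
    if (length(effect) != 1L || !effect %in% colnames(draws$draws)) {
      stop("effect must name one coefficient of the fit")
    }
    draws$draws[, effect]
  } else {
    stopifnot(is.numeric(effect), length(effect) == ncol(draws$draws))
    as.numeric(draws$draws %*% effect)
  }
}

#' Equal-tailed credible interval for a fixed effect
#'
#' Empirical quantiles of the posterior draws of a coefficient or a linear
#' combination of coefficients. Quantiles use linear interpolation between
#' order statistics (R's type-7 rule), fixed so intervals are reproducible.
#'
#' @param draws a [simulate_posterior()] object.
#' @param effect coefficient name, or numeric weight vector over the
#'   coefficients.
#' @param level interval mass in (0, 1); 0.95 gives the 2.5% and 97.5%
#'   quantiles.
#' @return Named numeric `c(lower, upper)`.
#' @export
credible_interval <- function(draws, effect, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1")
  }
  e <- effect_draws(draws, effect)
  a <- (1 - level) / 2
  q <- stats::quantile(e, probs = c(a, 1 - a), type = 7, names = FALSE)
  stats::setNames(q, c("lower", "upper"))
}

#' Posterior probability of an effect's sign
#'
#' Fraction of posterior draws on the stated side of zero; exact zeros
#' count half toward each side so the two directions always sum to one.
#'
#' @inheritParams credible_interval
#' @param direction `">0"` (default) or `"<0"`.
#' @return Probability in \[0, 1\].
#' @export
posterior_probability <- function(draws, effect, direction = c(">0", "<0")) {
  direction <- match.arg(direction)
  e <- effect_draws(draws, effect)
  p_gt <- mean(e > 0) + 0.5 * mean(e == 0)
  if (direction == ">0") p_gt else 1 - p_gt
}
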