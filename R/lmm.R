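#' Specify a random-intercept linear mixed model
#'
#' The engine fits Gaussian models with arbitrary categorical/indicator
#' fixed terms and a single random-intercept grouping factor:
#' \deqn{y = X\beta + Z b + \varepsilon,\quad b \sim N(0, \sigma_g^2 I),\quad
#'       \varepsilon \sim N(0, \sigma^2 I).}
#' Character/factor fixed terms are dummy coded against the first-observed
#' level; numeric terms (such as a 0/1 sympatry indicator) enter as is.
#'
#' @param response name of the response column.
#' @param fixed_factors character vector of fixed-effect column names.
#' @param random_group name of the grouping column for the random intercept
#'   (may be a composite key such as species:ecotype, prebuilt as a column).
#' @param method `"REML"` (default, standard for variance components) or
#'   `"ML"` (used where likelihoods must be comparable across datasets, as
#'   in the resampling check).
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(response, fixed_factors, random_group,
                     method = c("REML", "ML")) {
  method <- match.arg(method)
  structure(list(response = response, fixed_factors = fixed_factors,
                 random_group = random_group, method = method),
            class = "lmm_spec")
}

# model matrix with first-observed-level reference coding, plus group factor
build_design <- function(data, spec) {
  for (v in c(spec$response, spec$fixed_factors, spec$random_group)) {
    if (!v %in% names(data)) stop("column '", v, "' not found in data")
  }
  y <- data[[spec$response]]
  stopifnot(is.numeric(y), all(is.finite(y)))
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (v in spec$fixed_factors) {
    x <- data[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
    } else {
      f <- factor(as.character(x), levels = unique(as.character(x)))
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(mm) <- paste0(v, levels(f)[-1L])
        for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
      }
    }
  }
  X <- do.call(cbind, cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  g <- factor(as.character(data[[spec$random_group]]))
  if (nlevels(g) < 2L) stop("random grouping factor '", spec$random_group,
                            "' has fewer than 2 levels")
  list(y = as.numeric(y), X = X, group = g)
}

# profiled (restricted) log-likelihood pieces at variance ratio
# lambda = sigma2_group / sigma2_resid, via Woodbury on the block structure:
# V = I + lambda Z Z', V^-1 = I - Z diag(lambda/(1+lambda n_j)) Z'
profile_pieces <- function(XtX, Xty, yty, Xg, yg, n_j, lambda) {
  w <- lambda / (1 + lambda * n_j)
  XtVX <- XtX - crossprod(Xg * w, Xg)
  XtVy <- Xty - crossprod(Xg * w, yg)
  beta <- solve(XtVX, XtVy)
  q <- yty - sum(w * yg^2) - sum(beta * XtVy)
  q <- max(q, 1e-300)
  list(beta = beta, q = q, logdetV = sum(log1p(lambda * n_j)), XtVX = XtVX)
}

profile_loglik <- function(pieces, n, p, method) {
  if (method == "ML") {
    s2 <- pieces$q / n
    -0.5 * (n * log(2 * pi * s2) + pieces$logdetV + n)
  } else {
    s2 <- pieces$q / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + pieces$logdetV +
              determinant(pieces$XtVX, logarithm = TRUE)$modulus[1] +
              (n - p))
  }
}

#' Fit a random-intercept linear mixed model
#'
#' Maximizes the (restricted) Gaussian likelihood by a one-dimensional
#' profiled search: for each candidate variance ratio
#' \eqn{\lambda = \sigma_g^2/\sigma^2} the fixed effects are the GLS
#' solution and the residual variance is profiled out in closed form, so
#' only \eqn{\log\lambda} is optimized (Brent search over
#' \eqn{\lambda \in [10^{-10}, 10^{10}]}, with the \eqn{\lambda = 0}
#' boundary checked explicitly). Negative variances are impossible by
#' construction; \eqn{\sigma_g^2} may legitimately hit 0.
#'
#' @param data data.frame of observations (complete cases).
#' @param spec an [lmm_spec()].
#' @return An object of class `lmm_fit`: `beta` (named fixed effects),
#'   `beta_cov`, `sigma2_resid`, `sigma2_group`, `loglik`, `n_obs`,
#'   `df_resid`, `method`, `design_info`, plus the design (`X`, `y`,
#'   `group`) for downstream prediction.
#' @export
fit_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "lmm_spec"))
  d <- build_design(data, spec)
  X <- d$X; y <- d$y; g <- d$group
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("fewer observations than fixed-effect parameters")
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  Xg <- rowsum(X, g); yg <- as.numeric(rowsum(y, g))
  n_j <- as.numeric(table(g))

  obj <- function(loglambda) {
    pc <- profile_pieces(XtX, Xty, yty, Xg, yg, n_j, exp(loglambda))
    -profile_loglik(pc, n, p, spec$method)
  }
  opt <- stats::optimize(obj, interval = log(c(1e-10, 1e10)), tol = 1e-10)
  lambda <- exp(opt$minimum)
  ll <- -opt$objective
  # boundary: no between-group variance
  pc0 <- profile_pieces(XtX, Xty, yty, Xg, yg, n_j, 0)
  ll0 <- profile_loglik(pc0, n, p, spec$method)
  if (ll0 >= ll) {
    lambda <- 0
    ll <- ll0
  }
  pc <- profile_pieces(XtX, Xty, yty, Xg, yg, n_j, lambda)
  s2 <- pc$q / if (spec$method == "ML") n else n - p
  beta <- as.numeric(pc$beta)
  names(beta) <- colnames(X)
  beta_cov <- s2 * solve(pc$XtVX)
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  structure(
    list(beta = beta, beta_cov = beta_cov,
         sigma2_resid = s2, sigma2_group = lambda * s2,
         loglik = ll, n_obs = n, df_resid = n - p, method = spec$method,
         design_info = list(columns = colnames(X),
                            fixed_factors = spec$fixed_factors,
                            response = spec$response,
                            random_group = spec$random_group,
                            group_levels = levels(g)),
         X = X, y = y, group = g, spec = spec),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (", x$method, "), n = ", x$n_obs, ", groups = ",
      length(x$design_info$group_levels), "\n", sep = "")
  print(round(x$beta, 4))
  cat("sigma2_group = ", signif(x$sigma2_group, 5),
      ", sigma2_resid = ", signif(x$sigma2_resid, 5),
      ", logLik = ", round(x$loglik, 3), "\n", sep = "")
  invisible(x)
}

#' Evaluate the model log-likelihood at given parameters
#'
#' Exposes the objective maximized by [fit_lmm()]: the Gaussian
#' log-likelihood (method `"ML"`) or restricted log-likelihood (`"REML"`)
#' of a random-intercept model at arbitrary admissible variance components.
#' For ML a fixed-effect vector may be supplied; if omitted (and always for
#' REML, whose criterion is free of beta) the GLS solution at these variance
#' components is used.
#'
#' @param data,spec as in [fit_lmm()].
#' @param sigma2_group,sigma2_resid variance components (both >= 0,
#'   `sigma2_resid` > 0).
#' @param beta optional fixed-effect vector (ML only).
#' @return The log-likelihood value.
#' @export
loglik_at <- function(data, spec, sigma2_group, sigma2_resid, beta = NULL) {
  stopifnot(inherits(spec, "lmm_spec"), sigma2_resid > 0, sigma2_group >= 0)
  d <- build_design(data, spec)
  X <- d$X; y <- d$y; g <- d$group
  n <- length(y); p <- ncol(X)
  lambda <- sigma2_group / sigma2_resid
  n_j <- as.numeric(table(g))
  w <- lambda / (1 + lambda * n_j)
  Xg <- rowsum(X, g); yg <- as.numeric(rowsum(y, g))
  XtVX <- crossprod(X) - crossprod(Xg * w, Xg)
  XtVy <- crossprod(X, y) - crossprod(Xg * w, yg)
  logdetV <- sum(log1p(lambda * n_j))
  if (is.null(beta)) beta_use <- solve(XtVX, XtVy) else beta_use <- beta
  r <- y - X %*% beta_use
  rg <- as.numeric(rowsum(as.numeric(r), g))
  quad <- sum(r^2) - sum(w * rg^2)
  if (spec$method == "ML") {
    -0.5 * (n * log(2 * pi * sigma2_resid) + logdetV + quad / sigma2_resid)
  } else {
    -0.5 * ((n - p) * log(2 * pi * sigma2_resid) + logdetV +
              determinant(XtVX, logarithm = TRUE)$modulus[1] +
              quad / sigma2_resid)
  }
}

#' Fixed-effect fitted values for new factor combinations
#'
#' Builds rows of the fixed-effect design for the supplied combinations
#' (using the fit's reference coding) and returns the linear-combination
#' weight matrix and predictions, with random effects at zero.
#'
#' @param fit an [fit_lmm()] result.
#' @param newdata data.frame with the fit's fixed-effect columns.
#' @return A list with `L` (rows of the design matrix) and `pred`
#'   (`L %*% beta`).
#' @keywords internal
fixed_design_rows <- function(fit, newdata) {
  cols <- fit$design_info$columns
  L <- matrix(0, nrow(newdata), length(cols),
              dimnames = list(NULL, cols))
  L[, "(Intercept)"] <- 1
  for (v in fit$design_info$fixed_factors) {
    x <- newdata[[v]]
    if (is.numeric(x)) {
      if (v %in% cols) L[, v] <- x
    } else {
      nm <- paste0(v, as.character(x))
      for (i in seq_along(nm)) {
        if (nm[i] %in% cols) L[i, nm[i]] <- 1
      }
    }
  }
  list(L = L, pred = as.numeric(L %*% fit$beta))
}
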