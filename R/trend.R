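#' Fit a Poisson log-linear model by iteratively reweighted least squares
#'
#' Maximises the Poisson log-likelihood with log link and an offset
#' (typically log person-years) for stratum-year event counts. The solver is
#' plain IRLS on the working response with step-halving whenever a step
#' would decrease the log-likelihood, so the likelihood is non-decreasing
#' across iterations. Convergence is declared when the relative
#' log-likelihood change falls below `tol` or the score norm does.
#'
#' The covariance is the inverse observed information `(X'WX)^-1` at the
#' optimum. A Pearson dispersion statistic (sum of squared Pearson
#' residuals over residual degrees of freedom) is reported as a diagnostic
#' only; overdispersion is not modelled.
#'
#' @param formula model formula, e.g. `count ~ year_c + age_band + sex`.
#'   Centre the calendar-year term before fitting for conditioning; the IRR
#'   per year is invariant to centring.
#' @param data data frame of cells.
#' @param offset numeric vector of log person-years (default all zero), or
#'   the name of a column of `data` holding person-years, in which case its
#'   log is used.
#' @param tol convergence tolerance (default 1e-10).
#' @param max_iter maximum IRLS iterations.
#' @return an object of class `poisson_fit`: `coefficients`, `vcov`,
#'   `log_likelihood`, `converged`, `n_iter`, `df` (number of parameters),
#'   `nobs`, `fitted`, `pearson_dispersion`.
#' @examples
#' d <- data.frame(count = c(50, 55), year_c = c(-0.5, 0.5), py = c(1e5, 1e5))
#' fit <- fit_poisson(count ~ year_c, d, offset = "py")
#' irr_per_year(fit)
#' @export
fit_poisson <- function(formula, data, offset = NULL, tol = 1e-10,
                        max_iter = 50L) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.character(offset)) {
    if (!offset %in% names(data))
      stop("offset column not found: ", offset, call. = FALSE)
    offset <- log(data[[offset]])
  }
  if (is.null(offset)) offset <- rep(0, length(y))
  if (any(!is.finite(offset))) stop("offsets must be finite", call. = FALSE)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  loglik <- function(beta) {
    eta <- drop(X %*% beta) + offset
    sum(y * eta - exp(eta) - lgamma(y + 1))
  }
  beta <- rep(0, ncol(X))
  names(beta) <- colnames(X)
  if ("(Intercept)" %in% colnames(X))
    beta["(Intercept)"] <- log(sum(y) / sum(exp(offset)))
  ll <- loglik(beta)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    w <- mu                               # Poisson working weights
    z <- eta - offset + (y - mu) / mu     # working response (offset removed)
    XtW <- t(X * w)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    ## step-halving: never accept a likelihood decrease
    step <- beta_new - beta
    ll_new <- loglik(beta_new)
    halvings <- 0L
    while (!is.finite(ll_new) || ll_new < ll) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      step <- step / 2
      beta_new <- beta + step
      ll_new <- loglik(beta_new)
    }
    score <- drop(t(X) %*% (y - exp(drop(X %*% beta_new) + offset)))
    rel_change <- abs(ll_new - ll) / (abs(ll_new) + 0.1)
    beta <- beta_new
    ll <- ll_new
    if (rel_change < tol || sqrt(sum(score^2)) < tol) {
      converged <- TRUE
      break
    }
  }

  mu <- exp(drop(X %*% beta) + offset)
  info <- t(X * mu) %*% X
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  resid_df <- length(y) - ncol(X)
  pearson <- if (resid_df > 0) sum((y - mu)^2 / mu) / resid_df else NA_real_

  structure(list(coefficients = beta, vcov = vcov, log_likelihood = ll,
                 converged = converged, n_iter = iter, df = ncol(X),
                 nobs = length(y), fitted = mu,
                 pearson_dispersion = pearson, formula = formula),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("<poisson_fit> ", deparse(x$formula), "\n", sep = "")
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, se = se,
                   irr = exp(x$coefficients)))
  cat("log-likelihood ", format(x$log_likelihood), ", ",
      if (x$converged) "converged" else "NOT converged", " in ", x$n_iter,
      " iterations; Pearson dispersion ",
      format(round(x$pearson_dispersion, 3)), "\n", sep = "")
  invisible(x)
}

#' Incidence rate ratio per calendar year from a Poisson fit
#'
#' Exponentiates the calendar-year coefficient with a Wald confidence
#' interval `exp(beta +/- z * se)`.
#'
#' @param fit a [fit_poisson()] result containing a linear year term.
#' @param term name of the year coefficient (default `"year_c"`).
#' @param alpha two-sided significance level.
#' @return a one-row `data.table` with `term`, `irr`, `ci_low`, `ci_high`,
#'   `log_irr`, `se`.
#' @export
irr_per_year <- function(fit, term = "year_c", alpha = 0.05) {
  stopifnot(inherits(fit, "poisson_fit"))
  if (!fit$converged)
    warning("fit did not converge; IRR may be unreliable", call. = FALSE)
  if (!term %in% names(fit$coefficients))
    stop("no '", term, "' term in the model; terms: ",
         paste(names(fit$coefficients), collapse = ", "), call. = FALSE)
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- qnorm(1 - alpha / 2)
  data.table(term = term, irr = exp(b), ci_low = exp(b - z * se),
             ci_high = exp(b + z * se), log_irr = b, se = se)
}

#' Likelihood-ratio test for nested Poisson models
#'
#' @param null_fit,alt_fit nested [fit_poisson()] results (the alternative
#'   must contain the null's parameters).
#' @return a one-row `data.table` with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "poisson_fit"), inherits(alt_fit, "poisson_fit"))
  df <- alt_fit$df - null_fit$df
  if (df < 0L)
    stop("models are not nested (alternative must not have fewer parameters)",
         call. = FALSE)
  stat <- 2 * (alt_fit$log_likelihood - null_fit$log_likelihood)
  if (stat < -1e-6)
    stop("alternative model has lower likelihood than the null; check convergence",
         call. = FALSE)
  stat <- max(stat, 0)
  ## identical models (df 0): statistic 0 by construction, p-value 1
  p <- if (df == 0L) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  data.table(statistic = stat, df = df, p_value = p)
}

#' Stratum-specific calendar trend in incidence
#'
#' Convenience wrapper reproducing per-panel trend estimates: filters an
#' incidence cell table (from [make_table()] with `strata = "sex_age"`) to
#' one outcome and stratum, centres calendar year at its midpoint, fits
#' `count ~ year_c` (adding `age_band` as a categorical adjustment when the
#' stratum spans several bands) with log person-year offset, and returns the
#' IRR per year.
#'
#' @param cells incidence cell table with columns `year`, `sex`,
#'   `age_band`, `outcome`, `count`, `person_years`, `observable`.
#' @param outcome outcome to model.
#' @param sex optional sex filter.
#' @param age_bands optional character vector of age bands to include.
#' @param alpha significance level for the IRR interval.
#' @return a one-row `data.table`: stratum description, `irr`, `ci_low`,
#'   `ci_high`, plus fit diagnostics (`converged`, `n_cells`).
#' @export
trend_irr <- function(cells, outcome = "oad", sex = NULL, age_bands = NULL,
                      alpha = 0.05) {
  d <- as.data.table(cells)
  keep <- d[["outcome"]] == outcome & d[["observable"]] %in% TRUE &
    !is.na(d[["count"]])
  if (!is.null(sex)) keep <- keep & d[["sex"]] %in% sex
  if (!is.null(age_bands)) keep <- keep & as.character(d[["age_band"]]) %in% age_bands
  d <- d[keep]
  if (nrow(d) == 0L) stop("no observable cells for this stratum", call. = FALSE)
  d[, year_c := year - mean(range(year))]
  multi_band <- length(unique(as.character(d$age_band))) > 1L
  multi_sex <- length(unique(d$sex)) > 1L
  f <- count ~ year_c
  if (multi_band) f <- update(f, . ~ . + factor(age_band))
  if (multi_sex) f <- update(f, . ~ . + factor(sex))
  fit <- fit_poisson(f, d, offset = "person_years")
  est <- irr_per_year(fit, alpha = alpha)
  data.table(outcome = outcome,
             sex = if (is.null(sex)) "total" else paste(sex, collapse = "+"),
             age_bands = if (is.null(age_bands)) "all"
             else paste(age_bands, collapse = ","),
             irr = est$irr, ci_low = est$ci_low, ci_high = est$ci_high,
             converged = fit$converged, n_cells = nrow(d))
}

#' @importFrom stats update
NULL
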