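# One row of estimator output; the common currency of the simulation engine.
.estimate_result <- function(method, estimand, estimate = NA_real_,
                             se = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, df = NA_real_,
                             p_value = NA_real_, converged = FALSE,
                             n_used = NA_integer_) {
  data.frame(method = method, estimand = estimand, estimate = estimate,
             se = se, ci_low = ci_low, ci_high = ci_high, df = df,
             p_value = p_value, converged = converged,
             n_used = as.integer(n_used), stringsAsFactors = FALSE)
}

# Least-squares fit with rank handling: coefficients (NA when aliased),
# model-based SEs, residual df, RSS, and the unscaled covariance in
# original column order.
.ols <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  p <- ncol(X)
  rank <- fit$rank
  df <- length(y) - rank
  rss <- sum(fit$residuals^2)
  sigma2 <- if (df > 0) rss / df else 0
  piv <- fit$qr$pivot[seq_len(rank)]
  R <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov_red <- chol2inv(R)
  cov_unscaled <- matrix(NA_real_, p, p)
  cov_unscaled[piv, piv] <- cov_red
  se <- rep(NA_real_, p)
  se[piv] <- sqrt(pmax(sigma2 * diag(cov_red), 0))
  list(coef = fit$coefficients, se = se, df = df, rank = rank, rss = rss,
       sigma2 = sigma2, cov_unscaled = cov_unscaled,
       full_rank = rank == p)
}

# Columns to adjust for, by method code. `fp_powers` (optional) freezes the
# FP transformation instead of selecting per dataset.
.adjustment_columns <- function(dat, adjustment, family, fp_powers = NULL) {
  switch(adjustment,
         none = list(Z = NULL, basis = NULL),
         categories = list(Z = cbind(x_strat = as.numeric(dat$x_strat)),
                           basis = NULL),
         linear = list(Z = cbind(x = dat$x), basis = NULL),
         fp2 = {
           b <- fp2_select(dat$x, dat$y, dat$t, family, powers = fp_powers)
           list(Z = b$columns, basis = b)
         },
         rcs5 = {
           b <- rcs_basis(dat$x, 5L)
           list(Z = b$columns, basis = b)
         },
         stop("unknown adjustment method: ", adjustment, call. = FALSE))
}

.adjustments <- c("none", "categories", "linear", "fp2", "rcs5")

#' Treatment effect from a linear model, with a chosen adjustment
#'
#' Ordinary least squares of the outcome on treatment plus the requested
#' covariate-adjustment terms (none, the stratification indicator, the raw
#' covariate, a selected two-term fractional-polynomial basis, or a 5-knot
#' restricted cubic spline), with no treatment-by-covariate interaction.
#' Analysis rows are restricted to observed outcomes (complete-case). The
#' confidence interval uses the t distribution on the residual degrees of
#' freedom and model-based standard errors; the estimand is the mean
#' difference between arms.
#'
#' @param dataset trial `data.frame` with columns `x`, `x_strat`, `t`, `y`,
#'   `y_observed`.
#' @param adjustment one of `"none"`, `"categories"`, `"linear"`, `"fp2"`,
#'   `"rcs5"`.
#' @param fp_powers optional fixed FP power pair (skips per-dataset
#'   selection).
#' @param conf_level confidence level (default 0.95).
#' @return A one-row `data.frame` (see the package overview for columns).
#' @export
fit_continuous <- function(dataset, adjustment = .adjustments,
                           fp_powers = NULL, conf_level = 0.95) {
  adjustment <- match.arg(adjustment)
  obs <- dataset[dataset$y_observed, , drop = FALSE]
  n_used <- nrow(obs)
  adj <- tryCatch(.adjustment_columns(obs, adjustment, "gaussian", fp_powers),
                  error = function(e) NULL)
  if (is.null(adj)) {
    return(.estimate_result(adjustment, "mean_difference", n_used = n_used))
  }
  X <- cbind(1, t = obs$t, adj$Z)
  fit <- .ols(X, obs$y)
  est <- unname(fit$coef[2])
  se <- fit$se[2]
  if (is.na(est) || is.na(se) || fit$df <= 0) {
    return(.estimate_result(adjustment, "mean_difference", n_used = n_used))
  }
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, fit$df)
  tstat <- if (se > 0) est / se else sign(est) * Inf
  p <- 2 * stats::pt(abs(tstat), fit$df, lower.tail = FALSE)
  .estimate_result(adjustment, "mean_difference", estimate = est, se = se,
                   ci_low = est - tcrit * se, ci_high = est + tcrit * se,
                   df = fit$df, p_value = p, converged = TRUE,
                   n_used = n_used)
}

# Shared logistic machinery: IWLS fit with covariance, used by both the
# conditional-OR and standardised risk-difference estimators.
.logistic_fit <- function(dataset, adjustment, fp_powers = NULL) {
  obs <- dataset[dataset$y_observed, , drop = FALSE]
  n_used <- nrow(obs)
  fail <- function() list(converged = FALSE, n_used = n_used)
  if (n_used < 2L || stats::var(obs$y) == 0) return(fail())
  adj <- tryCatch(.adjustment_columns(obs, adjustment, "binomial", fp_powers),
                  error = function(e) NULL)
  if (is.null(adj)) return(fail())
  X <- cbind(1, t = obs$t, adj$Z)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, obs$y, family = stats::binomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || fit$rank < ncol(X)) return(fail())
  p <- ncol(X)
  Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rmat[lower.tri(Rmat)] <- 0
  vcov <- tryCatch(chol2inv(Rmat), error = function(e) NULL)
  if (is.null(vcov)) return(fail())
  piv <- fit$qr$pivot
  vc <- matrix(NA_real_, p, p)
  vc[piv, piv] <- vcov
  se <- sqrt(diag(vc))
  # crude separation guard: an SE this size means the likelihood is flat
  if (any(!is.finite(se)) || se[2] > 100) return(fail())
  list(converged = TRUE, coef = fit$coefficients, vcov = vc, se = se,
       X = X, obs = obs, full = dataset, basis = adj$basis, n_used = n_used)
}

#' Conditional treatment odds ratio from logistic regression
#'
#' Maximum-likelihood logistic regression of a binary outcome on treatment
#' plus the requested adjustment terms. The estimate is the log conditional
#' odds ratio for treatment; confidence intervals are Wald intervals on the
#' log-odds scale (normal reference, `df = Inf`). Separation or
#' non-convergence is reported via `converged = FALSE` so the replication
#' can be excluded from summaries.
#'
#' @inheritParams fit_continuous
#' @return A one-row `data.frame` with `estimand = "conditional_log_or"`.
#' @export
fit_binary_conditional <- function(dataset, adjustment = .adjustments,
                                   fp_powers = NULL, conf_level = 0.95) {
  adjustment <- match.arg(adjustment)
  L <- .logistic_fit(dataset, adjustment, fp_powers)
  if (!L$converged) {
    return(.estimate_result(adjustment, "conditional_log_or",
                            n_used = L$n_used))
  }
  est <- unname(L$coef[2])
  se <- L$se[2]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
  .estimate_result(adjustment, "conditional_log_or", estimate = est, se = se,
                   ci_low = est - z * se, ci_high = est + z * se, df = Inf,
                   p_value = p, converged = TRUE, n_used = L$n_used)
}

#' Standardised (g-computation) marginal risk difference
#'
#' Fits the adjusted logistic model, predicts each analysed participant's
#' event probability with treatment set to 1 and to 0, and averages the
#' difference — the marginal risk difference by standardisation. The
#' standard error propagates the logistic coefficient covariance through the
#' averaging by the delta method; the interval is Wald-normal.
#'
#' @inheritParams fit_continuous
#' @return A one-row `data.frame` with `estimand = "risk_difference"`.
#' @export
standardised_risk_difference <- function(dataset, adjustment = .adjustments,
                                         fp_powers = NULL,
                                         conf_level = 0.95) {
  adjustment <- match.arg(adjustment)
  L <- .logistic_fit(dataset, adjustment, fp_powers)
  if (!L$converged) {
    return(.estimate_result(adjustment, "risk_difference",
                            n_used = L$n_used))
  }
  X1 <- X0 <- L$X
  X1[, 2] <- 1
  X0[, 2] <- 0
  p1 <- stats::plogis(drop(X1 %*% L$coef))
  p0 <- stats::plogis(drop(X0 %*% L$coef))
  rd <- mean(p1) - mean(p0)
  grad <- colMeans(p1 * (1 - p1) * X1) - colMeans(p0 * (1 - p0) * X0)
  se <- sqrt(drop(t(grad) %*% L$vcov %*% grad))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(abs(rd / se), lower.tail = FALSE)
  .estimate_result(adjustment, "risk_difference", estimate = rd, se = se,
                   ci_low = rd - z * se, ci_high = rd + z * se, df = Inf,
                   p_value = p, converged = TRUE, n_used = L$n_used)
}

#' Mantel-Haenszel common odds ratio with the CMH test
#'
#' Stratifies the 2x2 treatment-by-outcome table on the randomisation
#' categories and computes the Mantel-Haenszel common odds ratio, the
#' Robins-Breslow-Greenland standard error for its logarithm, and the
#' (continuity-uncorrected) Cochran-Mantel-Haenszel test p-value. With a
#' single stratum the estimate collapses to the ordinary cross-product odds
#' ratio. Strata with a zero margin contribute nothing; if every stratum is
#' degenerate the estimator is undefined and an error is raised.
#'
#' @param dataset trial `data.frame` with binary `y`; strata taken from
#'   `x_strat`, analysis restricted to `y_observed`.
#' @param conf_level confidence level (default 0.95).
#' @return A one-row `data.frame` with `method = "cmh"` and the log common
#'   odds ratio as the estimate.
#' @export
cmh_odds_ratio <- function(dataset, conf_level = 0.95) {
  obs <- dataset[dataset$y_observed, , drop = FALSE]
  n_used <- nrow(obs)
  strata <- sort(unique(obs$x_strat))
  a <- b <- cc <- d <- numeric(length(strata))
  for (i in seq_along(strata)) {
    s <- obs[obs$x_strat == strata[i], ]
    a[i] <- sum(s$t == 1 & s$y == 1)
    b[i] <- sum(s$t == 1 & s$y == 0)
    cc[i] <- sum(s$t == 0 & s$y == 1)
    d[i] <- sum(s$t == 0 & s$y == 0)
  }
  n_i <- a + b + cc + d
  keep <- n_i > 0
  a <- a[keep]; b <- b[keep]; cc <- cc[keep]; d <- d[keep]; n_i <- n_i[keep]
  R <- a * d / n_i
  S <- b * cc / n_i
  if (sum(R) == 0 || sum(S) == 0) {
    stop("all strata are degenerate: the Mantel-Haenszel odds ratio is ",
         "undefined", call. = FALSE)
  }
  log_or <- log(sum(R) / sum(S))
  P <- (a + d) / n_i
  Q <- (b + cc) / n_i
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  se <- sqrt(var_log)
  # CMH statistic (no continuity correction)
  m1 <- a + b   # treated margin
  c1 <- a + cc  # event margin
  expect_a <- m1 * c1 / n_i
  var_a <- m1 * (n_i - m1) * c1 * (n_i - c1) / (n_i^2 * pmax(n_i - 1, 1))
  stat <- sum(a - expect_a)^2 / sum(var_a)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  .estimate_result("cmh", "conditional_log_or", estimate = log_or, se = se,
                   ci_low = log_or - z * se, ci_high = log_or + z * se,
                   df = Inf, p_value = p, converged = TRUE, n_used = n_used)
}

#' Multiple imputation of missing continuous outcomes
#'
#' Proper multiple imputation for a univariate continuous outcome with the
#' imputation model matching the analysis model. For each of `m`
#' imputations, the residual variance and coefficients of the normal-linear
#' model (same covariate terms as the analysis model, fitted to complete
#' cases) are drawn from their posterior under the standard noninformative
#' prior, missing outcomes are imputed from the predictive distribution, and
#' the analysis model is refitted to the completed data (fractional
#' polynomial selection is re-run within each imputation, treating it as
#' part of the analysis procedure). Estimates are pooled by Rubin's rules
#' with Barnard-Rubin degrees of freedom.
#'
#' @inheritParams fit_continuous
#' @param m number of imputations (>= 2; default 30).
#' @return A one-row `data.frame` with `estimand = "mean_difference"`.
#' @export
multiple_imputation_estimate <- function(dataset, adjustment = .adjustments,
                                         m = 30L, fp_powers = NULL,
                                         conf_level = 0.95) {
  adjustment <- match.arg(adjustment)
  stopifnot(m >= 2L)
  obs_idx <- dataset$y_observed
  if (!any(obs_idx)) {
    stop("no complete cases to fit the imputation model", call. = FALSE)
  }
  if (all(obs_idx)) {
    # nothing to impute: pooled estimate equals the complete-data estimate,
    # between-imputation variance 0
    return(fit_continuous(dataset, adjustment, fp_powers, conf_level))
  }
  cc <- dataset[obs_idx, , drop = FALSE]
  mis <- dataset[!obs_idx, , drop = FALSE]
  adj_cc <- .adjustment_columns(cc, adjustment, "gaussian", fp_powers)
  Xcc <- cbind(1, t = cc$t, adj_cc$Z)
  imp_fit <- .ols(Xcc, cc$y)
  if (!imp_fit$full_rank || imp_fit$df <= 0) {
    return(.estimate_result(adjustment, "mean_difference",
                            n_used = nrow(dataset)))
  }
  Zmis <- if (!is.null(adj_cc$basis)) {
    apply_basis(adj_cc$basis, mis$x)
  } else if (adjustment == "categories") {
    cbind(x_strat = as.numeric(mis$x_strat))
  } else if (adjustment == "linear") {
    cbind(x = mis$x)
  } else NULL
  Xmis <- cbind(1, t = mis$t, Zmis)
  U <- chol(imp_fit$cov_unscaled)
  p <- ncol(Xcc)

  ests <- ses <- numeric(m)
  dfs_com <- numeric(m)
  ok <- logical(m)
  completed <- dataset
  completed$y_observed <- TRUE
  for (k in seq_len(m)) {
    sigma2_star <- imp_fit$rss / stats::rchisq(1, imp_fit$df)
    beta_star <- imp_fit$coef +
      sqrt(sigma2_star) * drop(crossprod(U, stats::rnorm(p)))
    completed$y[!obs_idx] <- drop(Xmis %*% beta_star) +
      stats::rnorm(nrow(mis), sd = sqrt(sigma2_star))
    completed$y[obs_idx] <- dataset$y[obs_idx]
    fit_k <- fit_continuous(completed, adjustment, fp_powers, conf_level)
    ok[k] <- fit_k$converged
    ests[k] <- fit_k$estimate
    ses[k] <- fit_k$se
    dfs_com[k] <- fit_k$df
  }
  if (sum(ok) < 2L) {
    return(.estimate_result(adjustment, "mean_difference",
                            n_used = nrow(dataset)))
  }
  ests <- ests[ok]; ses <- ses[ok]
  m_eff <- length(ests)
  qbar <- mean(ests)
  W <- mean(ses^2)
  B <- stats::var(ests)
  Tvar <- W + (1 + 1 / m_eff) * B
  lambda <- (1 + 1 / m_eff) * B / Tvar
  df_com <- dfs_com[ok][1]
  if (lambda <= 0) {
    df_pool <- df_com
  } else {
    df_old <- (m_eff - 1) / lambda^2
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
    df_pool <- 1 / (1 / df_old + 1 / df_obs)
  }
  se_pool <- sqrt(Tvar)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_pool)
  tstat <- if (se_pool > 0) qbar / se_pool else sign(qbar) * Inf
  pval <- 2 * stats::pt(abs(tstat), df_pool, lower.tail = FALSE)
  out <- .estimate_result(adjustment, "mean_difference", estimate = qbar,
                          se = se_pool, ci_low = qbar - tcrit * se_pool,
                          ci_high = qbar + tcrit * se_pool, df = df_pool,
                          p_value = pval, converged = TRUE,
                          n_used = nrow(dataset))
  # per-imputation components, for auditing the pooling
  attr(out, "imputation_estimates") <- ests
  attr(out, "imputation_ses") <- ses
  out
}
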