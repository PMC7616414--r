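#' Summarise replications into performance measures
#'
#' Aggregates per-replication estimator output into the usual
#' simulation-study performance measures with their Monte Carlo standard
#' errors: bias, percentage (relative) bias, empirical SE, coverage of the
#' confidence interval, and the rejection rate of the two-sided test
#' (type-I error when the true effect is null, power otherwise).
#' Non-converged replications are excluded and counted.
#'
#' Monte Carlo SEs use the standard formulas over K used replications:
#' `mcse_bias = emp_se / sqrt(K)`, `mcse_emp_se = emp_se / sqrt(2(K - 1))`,
#' and `sqrt(p(1 - p) / K)` for the proportions.
#'
#' @param estimates `data.frame` of per-replication results with columns
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `converged` (e.g. from
#'   [run_scenario()]).
#' @param true_effect true value of the estimand.
#' @param alpha test size for the rejection rate (default 0.05).
#' @return A one-row `data.frame`: `n_reps_used`, `n_nonconverged`, `bias`,
#'   `pct_bias`, `emp_se`, `coverage`, `rejection_rate` and the four
#'   `mcse_*` columns. `pct_bias` (100 * bias / true_effect) is `NA` when
#'   the true effect is 0.
#' @examples
#' cfg <- scenario_config(beta1 = 0.4, n_reps = 20, seed = 1)
#' est <- run_scenario(cfg, methods = "none")
#' summarise_performance(est, true_effect = 0.4)
#' @export
summarise_performance <- function(estimates, true_effect, alpha = 0.05) {
  conv <- estimates[estimates$converged, , drop = FALSE]
  K <- nrow(conv)
  if (K < 2L) {
    stop("need at least 2 converged replications to summarise performance ",
         "(got ", K, ")", call. = FALSE)
  }
  est <- conv$estimate
  bias <- mean(est) - true_effect
  emp_se <- stats::sd(est)
  coverage <- mean(conv$ci_low <= true_effect & true_effect <= conv$ci_high)
  rejection <- mean(conv$p_value < alpha)
  pct_bias <- if (true_effect == 0) NA_real_ else 100 * bias / true_effect
  data.frame(
    n_reps_used = K,
    n_nonconverged = sum(!estimates$converged),
    bias = bias,
    pct_bias = pct_bias,
    emp_se = emp_se,
    coverage = coverage,
    rejection_rate = rejection,
    mcse_bias = emp_se / sqrt(K),
    mcse_emp_se = emp_se / sqrt(2 * (K - 1)),
    mcse_coverage = sqrt(coverage * (1 - coverage) / K),
    mcse_rejection = sqrt(rejection * (1 - rejection) / K)
  )
}
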