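#' Covariate shape functions
#'
#' Applies the covariate-outcome shape transformation `f` to a covariate
#' vector: identity, exponential, square, or the step function
#' `1{x >= 0}` defined by the stratification threshold.
#'
#' @param x numeric vector.
#' @param shape one of `"linear"`, `"exponential"`, `"quadratic"`, `"step"`.
#' @return Numeric vector `f(x)`.
#' @examples
#' transform_covariate(c(-0.5, 0, 2), "step")
#' @export
transform_covariate <- function(x, shape) {
  if (length(shape) != 1L || !shape %in% .shapes) {
    stop("unknown covariate shape: ", paste(shape, collapse = ", "),
         " (expected one of ", paste(.shapes, collapse = ", "), ")",
         call. = FALSE)
  }
  switch(shape,
         linear      = x,
         exponential = exp(x),
         quadratic   = x^2,
         step        = as.numeric(x >= 0))
}

# E over X ~ N(0,1) of expit(offset + slope * X), by adaptive quadrature.
.expit_normal_mean <- function(offset, slope) {
  stats::integrate(function(x) stats::plogis(offset + slope * x) * stats::dnorm(x),
                   -Inf, Inf, rel.tol = 1e-12)$value
}

#' Calibrate the missingness-model intercept
#'
#' Finds the intercept `gamma` such that, averaging over X ~ N(0,1) and
#' T ~ Bernoulli(0.5), the missingness probability
#' expit(gamma + coef_t T + coef_x X + coef_xt X T) equals the model's
#' `target_rate`. The expectation over X is computed by deterministic
#' quadrature and the average over T exactly, so the calibration is free of
#' Monte Carlo noise.
#'
#' @param model a [missingness_model()].
#' @param tol absolute tolerance on the achieved rate (default 1e-6).
#' @return The calibrated intercept (numeric scalar).
#' @examples
#' # with all coefficients 0 the answer is analytic: logit(0.3)
#' m <- missingness_model(coef_t = 0, coef_x = 0, coef_xt = 0)
#' calibrate_missingness_intercept(m)  # ~ -0.8473
#' @export
calibrate_missingness_intercept <- function(model, tol = 1e-6) {
  stopifnot(inherits(model, "missingness_model"))
  rate <- function(g) {
    0.5 * .expit_normal_mean(g, model$coef_x) +
      0.5 * .expit_normal_mean(g + model$coef_t, model$coef_x + model$coef_xt)
  }
  lo <- -40; hi <- 40
  r_lo <- rate(lo); r_hi <- rate(hi)
  if (model$target_rate < r_lo || model$target_rate > r_hi) {
    stop(sprintf(paste0("target rate %.4f is outside the achievable range ",
                        "[%.4g, %.4g] for these coefficients"),
                 model$target_rate, r_lo, r_hi), call. = FALSE)
  }
  stats::uniroot(function(g) rate(g) - model$target_rate,
                 c(lo, hi), tol = tol)$root
}

#' Calibrate the binary-outcome intercept
#'
#' Finds `beta0` such that the control-arm event rate
#' E over X ~ N(0,1) of expit(beta0 + beta2 f(X)) equals `target_rate`,
#' by quadrature and root finding.
#'
#' @param shape covariate-outcome shape code.
#' @param beta2 covariate effect on the log-odds scale.
#' @param target_rate control-arm event rate (default 0.5).
#' @return Calibrated intercept (numeric scalar).
#' @export
calibrate_binary_intercept <- function(shape, beta2, target_rate = 0.5) {
  rate <- function(b0) {
    stats::integrate(function(x) {
      stats::plogis(b0 + beta2 * transform_covariate(x, shape)) * stats::dnorm(x)
    }, -Inf, Inf, rel.tol = 1e-12)$value
  }
  lo <- -40; hi <- 40
  r_lo <- rate(lo); r_hi <- rate(hi)
  if (target_rate < r_lo || target_rate > r_hi) {
    stop(sprintf("target event rate %.4f is outside the achievable range [%.4g, %.4g]",
                 target_rate, r_lo, r_hi), call. = FALSE)
  }
  stats::uniroot(function(b0) rate(b0) - target_rate, c(lo, hi),
                 tol = 1e-10)$root
}

#' Generate one simulated trial dataset
#'
#' Draws the baseline covariate X ~ N(0,1), dichotomises it at 0 into the
#' stratification variable, randomises 1:1 (stratified permuted blocks or
#' simple randomisation), and generates the outcome from the scenario's
#' linear-normal or logistic model. If the scenario includes missingness the
#' outcome is then flagged missing at random via [impose_missingness()];
#' `y` itself is always retained so that oracle checks against the full data
#' remain possible.
#'
#' @param config a [scenario_config()].
#' @param miss_model optional pre-calibrated [missingness_model()]; when the
#'   scenario has `missingness = "mar30"` and this is `NULL`, a default model
#'   is calibrated on the fly (calibrate once and pass it in when simulating
#'   many replications).
#' @return A `data.frame` with columns `id`, `x`, `x_strat`, `t`, `y`,
#'   `y_observed`.
#' @examples
#' set.seed(7)
#' dat <- generate_trial(scenario_config(beta1 = 0.4, n_reps = 1))
#' head(dat)
#' @export
generate_trial <- function(config, miss_model = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n
  x <- stats::rnorm(n)
  x_strat <- as.integer(x >= 0)
  t <- if (config$randomisation == "stratified_blocks") {
    randomise_stratified_blocks(x_strat, config$block_size)
  } else {
    randomise_simple(n)
  }
  fx <- transform_covariate(x, config$shape)
  lp <- config$beta0 + config$beta1 * t + config$beta2 * fx +
    config$beta3 * fx * t
  y <- if (config$outcome_type == "continuous") {
    lp + stats::rnorm(n)
  } else {
    stats::rbinom(n, 1L, stats::plogis(lp))
  }
  dat <- data.frame(id = seq_len(n), x = x, x_strat = x_strat, t = t,
                    y = y, y_observed = TRUE)
  if (config$missingness == "mar30") {
    if (is.null(miss_model)) {
      miss_model <- missingness_model()
      miss_model$gamma <- calibrate_missingness_intercept(miss_model)
    }
    dat <- impose_missingness(dat, miss_model)
  }
  dat
}

#' Flag outcomes missing at random
#'
#' Draws the missingness indicator from the logistic model
#' logit P(missing) = gamma + coef_t T + coef_x X + coef_xt X T,
#' independently across participants. Outcome values are kept in `y`
#' (analyses must respect `y_observed`), so the complete data remain
#' available for truth-knowing diagnostics.
#'
#' @param dataset trial `data.frame` with columns `x`, `t`, `y`.
#' @param model a [missingness_model()] with a non-`NULL` (calibrated)
#'   `gamma`.
#' @return The dataset with `y_observed` updated.
#' @export
impose_missingness <- function(dataset, model) {
  stopifnot(inherits(model, "missingness_model"))
  if (is.null(model$gamma)) {
    stop("missingness model intercept is NULL; calibrate it first with ",
         "calibrate_missingness_intercept()", call. = FALSE)
  }
  p_miss <- stats::plogis(model$gamma + model$coef_t * dataset$t +
                            model$coef_x * dataset$x +
                            model$coef_xt * dataset$x * dataset$t)
  dataset$y_observed <- stats::rbinom(nrow(dataset), 1L, 1 - p_miss) == 1L
  dataset
}
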