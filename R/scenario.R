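#' Covariate-effect presets by shape and strength
#'
#' Coefficients chosen so that moving from the 10th to the 90th percentile of
#' f(X), X ~ N(0,1), shifts the outcome mean by one ("moderate") or two
#' ("strong") residual standard deviations.
#'
#' @keywords internal
.beta2_presets <- list(
  linear      = c(moderate = 0.39, strong = 0.78),
  exponential = c(moderate = 0.30, strong = 0.60),
  quadratic   = c(moderate = 0.37, strong = 0.74),
  step        = c(moderate = 1.00, strong = 2.00)
)

.shapes <- c("linear", "exponential", "quadratic", "step")

#' Define a simulation scenario
#'
#' A scenario bundles the data-generating mechanism and analysis options for
#' one cell of the simulation study: a standard-normal baseline covariate
#' dichotomised at zero for stratified 1:1 randomisation in permuted blocks,
#' an outcome model (continuous-normal or binary-logistic) in which the
#' covariate enters through a shape function `f`, and optional
#' missing-at-random outcome data.
#'
#' The outcome models are
#' \deqn{Y = \beta_0 + \beta_1 T + \beta_2 f(X) + \beta_3 f(X) T + e,\quad
#'       e \sim N(0,1)}
#' for continuous outcomes, and
#' \deqn{Y \sim \mathrm{Bernoulli}\{\mathrm{expit}(\beta_0 + \beta_1 T +
#'       \beta_2 f(X) + \beta_3 f(X) T)\}}
#' for binary outcomes, where `beta1` is then a log conditional odds ratio.
#'
#' When `beta2` is `NULL` it is filled in from the preset grid for the given
#' `shape` and `strength` (see `.beta2_presets`). For binary outcomes a
#' `NULL` `beta0` is calibrated by quadrature so that the control-arm event
#' rate is 50%.
#'
#' @param n participants per trial (default 200).
#' @param n_reps simulation replications (default 5000).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param shape covariate-outcome shape: `"linear"` (f(X)=X), `"exponential"`
#'   (f(X)=e^X), `"quadratic"` (f(X)=X^2) or `"step"` (f(X)=1\{X>=0\}).
#' @param beta0 intercept; `NULL` means 0 (continuous) or calibrated to a
#'   50% control-arm event rate (binary).
#' @param beta1 treatment effect (mean difference, or log conditional OR).
#' @param beta2 covariate main effect; `NULL` uses the shape/strength preset.
#' @param beta3 treatment-by-covariate interaction effect (default 0).
#' @param strength `"moderate"` or `"strong"`; used only to resolve a `NULL`
#'   `beta2`.
#' @param randomisation `"stratified_blocks"` (permuted blocks within strata)
#'   or `"simple"` (independent fair coin).
#' @param block_size permuted-block length; must be a positive even integer.
#' @param missingness `"none"` or `"mar30"` (30% missing outcomes overall,
#'   odds of missingness increased by 1.5 per unit of T, X and XT).
#' @param missing_handler `"complete_case"` or `"multiple_imputation"`.
#' @param m_imputations imputations for multiple imputation (default 30).
#' @param seed root seed for the scenario's replication streams.
#' @param scenario_id optional label; autogenerated when `NULL`.
#'
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' cfg <- scenario_config(shape = "exponential", strength = "strong",
#'                        beta1 = 0.4, n_reps = 10)
#' cfg$beta2  # preset 0.60
#' @export
scenario_config <- function(n = 200L,
                            n_reps = 5000L,
                            outcome_type = c("continuous", "binary"),
                            shape = c("linear", "exponential", "quadratic", "step"),
                            beta0 = NULL,
                            beta1 = 0,
                            beta2 = NULL,
                            beta3 = 0,
                            strength = c("moderate", "strong"),
                            randomisation = c("stratified_blocks", "simple"),
                            block_size = 4L,
                            missingness = c("none", "mar30"),
                            missing_handler = c("complete_case", "multiple_imputation"),
                            m_imputations = 30L,
                            seed = 1L,
                            scenario_id = NULL) {
  outcome_type <- match.arg(outcome_type)
  shape <- match.arg(shape)
  strength <- match.arg(strength)
  randomisation <- match.arg(randomisation)
  missingness <- match.arg(missingness)
  missing_handler <- match.arg(missing_handler)

  stopifnot(is.numeric(n), length(n) == 1L, n >= 2,
            is.numeric(n_reps), length(n_reps) == 1L, n_reps >= 1,
            is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(block_size) || length(block_size) != 1L ||
      block_size <= 0 || block_size %% 2 != 0) {
    stop("`block_size` must be a positive even integer (permuted blocks need ",
         "equal numbers of each arm).", call. = FALSE)
  }
  if (is.null(beta2)) {
    beta2 <- unname(.beta2_presets[[shape]][strength])
  }
  if (is.null(beta0)) {
    beta0 <- if (outcome_type == "binary") {
      calibrate_binary_intercept(shape, beta2, target_rate = 0.5)
    } else 0
  }
  if (is.null(scenario_id)) {
    scenario_id <- paste(substr(outcome_type, 1, 4), shape, strength,
                         paste0("b1_", beta1),
                         if (beta3 != 0) paste0("b3_", beta3),
                         if (missingness != "none") missingness,
                         sep = "-")
    scenario_id <- gsub("-+$", "", scenario_id)
  }

  structure(list(
    scenario_id = scenario_id,
    n = as.integer(n), n_reps = as.integer(n_reps),
    outcome_type = outcome_type, shape = shape,
    beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
    strength = strength, randomisation = randomisation,
    block_size = as.integer(block_size),
    missingness = missingness, missing_handler = missing_handler,
    m_imputations = as.integer(m_imputations),
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$scenario_id, "\n", sep = "")
  cat(sprintf("  %s outcome, shape %s (%s), n = %d, reps = %d\n",
              x$outcome_type, x$shape, x$strength, x$n, x$n_reps))
  cat(sprintf("  beta0 = %.4g, beta1 = %.4g, beta2 = %.4g, beta3 = %.4g\n",
              x$beta0, x$beta1, x$beta2, x$beta3))
  cat(sprintf("  randomisation = %s (block %d), missingness = %s (%s)\n",
              x$randomisation, x$block_size, x$missingness, x$missing_handler))
  invisible(x)
}

#' Missingness model for outcomes missing at random
#'
#' Logistic model for the probability that an outcome is missing:
#' \deqn{\mathrm{logit}\,P(Y_i\ \mathrm{missing}) = \gamma + a T_i + b X_i +
#'       c X_i T_i.}
#' Defaults set `a = b = c = log(1.5)`: the odds of missingness are 1.5 times
#' higher per SD of X in the control arm and 2.25 times higher per SD in the
#' treated arm, with `gamma` left `NULL` to be calibrated to the overall
#' `target_rate` by [calibrate_missingness_intercept()].
#'
#' @param gamma intercept on the logit scale, or `NULL` to calibrate.
#' @param coef_t,coef_x,coef_xt log-odds coefficients for T, X and XT.
#' @param target_rate overall missingness proportion the intercept should
#'   achieve (default 0.30).
#' @return An object of class `missingness_model`.
#' @export
missingness_model <- function(gamma = NULL,
                              coef_t = log(1.5),
                              coef_x = log(1.5),
                              coef_xt = log(1.5),
                              target_rate = 0.30) {
  stopifnot(is.numeric(target_rate), length(target_rate) == 1L,
            target_rate > 0, target_rate < 1)
  structure(list(gamma = gamma, coef_t = coef_t, coef_x = coef_x,
                 coef_xt = coef_xt, target_rate = target_rate),
            class = "missingness_model")
}
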