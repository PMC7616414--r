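#' Apply every analysis method to one trial dataset
#'
#' Dispatches each requested method on a single simulated (or real) trial:
#' linear regression for continuous outcomes (complete-case or multiple
#' imputation, per the scenario's `missing_handler`), and for binary
#' outcomes both the conditional log odds ratio and the standardised risk
#' difference per adjustment method, plus the Mantel-Haenszel estimator when
#' `"cmh"` is among the methods.
#'
#' @param dataset a trial `data.frame` from [generate_trial()].
#' @param config the [scenario_config()] the dataset was generated under.
#' @param methods character vector of method codes (subset of `"none"`,
#'   `"categories"`, `"linear"`, `"fp2"`, `"rcs5"`, and `"cmh"` for binary
#'   outcomes).
#' @param fp_powers optional fixed FP power pair passed through to the
#'   estimators.
#' @return `data.frame` of estimator rows, one per method (two for binary
#'   adjustment methods: odds ratio and risk difference).
#' @export
analyse_trial <- function(dataset, config,
                          methods = c("none", "categories", "linear",
                                      "fp2", "rcs5"),
                          fp_powers = NULL) {
  rows <- list()
  for (meth in methods) {
    if (config$outcome_type == "continuous") {
      if (meth == "cmh") {
        stop("the Cochran-Mantel-Haenszel method applies to binary outcomes ",
             "only", call. = FALSE)
      }
      r <- if (config$missing_handler == "multiple_imputation" &&
               any(!dataset$y_observed)) {
        multiple_imputation_estimate(dataset, meth,
                                     m = config$m_imputations,
                                     fp_powers = fp_powers)
      } else {
        fit_continuous(dataset, meth, fp_powers = fp_powers)
      }
      rows[[length(rows) + 1L]] <- r
    } else if (meth == "cmh") {
      r <- tryCatch(cmh_odds_ratio(dataset), error = function(e) {
        .estimate_result("cmh", "conditional_log_or",
                         n_used = sum(dataset$y_observed))
      })
      rows[[length(rows) + 1L]] <- r
    } else {
      rows[[length(rows) + 1L]] <-
        fit_binary_conditional(dataset, meth, fp_powers = fp_powers)
      rows[[length(rows) + 1L]] <-
        standardised_risk_difference(dataset, meth, fp_powers = fp_powers)
    }
  }
  do.call(rbind, rows)
}

#' Run all replications of one scenario
#'
#' Generates `config$n_reps` trial datasets (each replication on its own
#' seed stream derived from the scenario seed, see [replication_seeds()]),
#' applies every requested analysis method, and returns the stacked
#' per-replication estimates. When the scenario includes missingness the
#' missingness-model intercept is calibrated once, up front.
#'
#' @inheritParams analyse_trial
#' @param config a [scenario_config()].
#' @return `data.frame` of per-replication estimator rows with `scenario_id`
#'   and `rep` prepended.
#' @examples
#' cfg <- scenario_config(beta1 = 0.4, n_reps = 5, seed = 42)
#' run_scenario(cfg, methods = c("none", "linear"))
#' @export
run_scenario <- function(config,
                         methods = c("none", "categories", "linear",
                                     "fp2", "rcs5"),
                         fp_powers = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- replication_seeds(config$seed, config$n_reps)
  miss_model <- NULL
  if (config$missingness == "mar30") {
    miss_model <- missingness_model()
    miss_model$gamma <- calibrate_missingness_intercept(miss_model)
  }
  out <- vector("list", config$n_reps)
  for (r in seq_len(config$n_reps)) {
    set.seed(seeds[r])
    dat <- generate_trial(config, miss_model)
    res <- analyse_trial(dat, config, methods, fp_powers)
    res$rep <- r
    out[[r]] <- res
  }
  res <- do.call(rbind, out)
  res$scenario_id <- config$scenario_id
  res[, c("scenario_id", "rep",
          setdiff(names(res), c("scenario_id", "rep")))]
}

#' True value of an estimand under a scenario
#'
#' The reference value performance is measured against: the average
#' treatment effect `beta1 + beta3 E[f(X)]` for the mean difference, the
#' conditional log odds ratio `beta1` for logistic scenarios (exactly the
#' coefficient of the generating model), and the marginal risk difference
#' computed by quadrature over X ~ N(0,1) for the standardised estimand.
#'
#' @param config a [scenario_config()].
#' @param estimand `"mean_difference"`, `"conditional_log_or"` or
#'   `"risk_difference"`.
#' @return Numeric scalar.
#' @export
true_estimand_value <- function(config, estimand = c("mean_difference",
                                                     "conditional_log_or",
                                                     "risk_difference")) {
  estimand <- match.arg(estimand)
  e_fx <- switch(config$shape,
                 linear = 0, exponential = exp(0.5), quadratic = 1,
                 step = 0.5)
  switch(estimand,
         mean_difference = config$beta1 + config$beta3 * e_fx,
         conditional_log_or = config$beta1,
         risk_difference = {
           arm_rate <- function(t) {
             stats::integrate(function(x) {
               fx <- transform_covariate(x, config$shape)
               stats::plogis(config$beta0 + config$beta1 * t +
                               config$beta2 * fx + config$beta3 * fx * t) *
                 stats::dnorm(x)
             }, -Inf, Inf, rel.tol = 1e-12)$value
           }
           arm_rate(1) - arm_rate(0)
         })
}

#' Bundle scenarios into a study manifest
#'
#' @param scenarios list of [scenario_config()] objects with unique ids.
#' @param methods method codes to run on every scenario.
#' @param output_dir optional directory for CSV output from [run_study()].
#' @param root_seed optional study-level seed; when given, each scenario is
#'   assigned a distinct derived seed (overriding its own).
#' @return An object of class `study_manifest`.
#' @export
study_manifest <- function(scenarios,
                           methods = c("none", "categories", "linear",
                                       "fp2", "rcs5"),
                           output_dir = NULL, root_seed = NULL) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1L,
            all(vapply(scenarios, inherits, TRUE, "scenario_config")))
  ids <- vapply(scenarios, `[[`, "", "scenario_id")
  if (anyDuplicated(ids)) {
    stop("scenario ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(root_seed)) {
    sseeds <- replication_seeds(root_seed, length(scenarios))
    for (i in seq_along(scenarios)) {
      scenarios[[i]]$seed <- sseeds[i]
    }
  }
  structure(list(scenarios = scenarios, methods = methods,
                 output_dir = output_dir, root_seed = root_seed),
            class = "study_manifest")
}

#' The full pre-set scenario grid of the simulation study
#'
#' Enumerates the study's scenario grid: for continuous outcomes, the four
#' covariate-outcome shapes crossed with moderate/strong strength and null
#' (0) or non-null (0.4) treatment effect, with complete or 30%
#' missing-at-random outcomes; the treatment-by-covariate interaction
#' scenarios (linear shape only, average effect 0.4, complete and missing);
#' and the binary-outcome analogue with a conditional odds ratio of 1 or
#' 1.5. Binary-scenario intercepts and covariate coefficients are package
#' defaults (50% control-arm event rate, continuous-case coefficient
#' presets); see the methods vignette.
#'
#' @param n_reps replications per scenario (default 5000).
#' @param blocks which scenario blocks to include.
#' @return A list of [scenario_config()] objects.
#' @export
paper_scenarios <- function(n_reps = 5000L,
                            blocks = c("continuous_complete",
                                       "continuous_missing",
                                       "interaction", "binary")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  scen <- list()
  add <- function(s) scen[[length(scen) + 1L]] <<- s
  strengths <- c("moderate", "strong")
  if ("continuous_complete" %in% blocks) {
    for (sh in .shapes) for (st in strengths) for (b1 in c(0, 0.4)) {
      add(scenario_config(n_reps = n_reps, shape = sh, strength = st,
                          beta1 = b1))
    }
  }
  if ("continuous_missing" %in% blocks) {
    for (sh in .shapes) for (st in strengths) for (b1 in c(0, 0.4)) {
      add(scenario_config(n_reps = n_reps, shape = sh, strength = st,
                          beta1 = b1, missingness = "mar30"))
    }
  }
  if ("interaction" %in% blocks) {
    for (st in strengths) for (ms in c("none", "mar30")) {
      b3 <- unname(.beta2_presets$linear[st])
      add(scenario_config(n_reps = n_reps, shape = "linear", strength = st,
                          beta1 = 0.4, beta2 = 0, beta3 = b3,
                          missingness = ms,
                          scenario_id = paste0("cont-interaction-", st,
                                               if (ms != "none") "-mar30")))
    }
  }
  if ("binary" %in% blocks) {
    for (sh in .shapes) for (st in strengths) for (b1 in c(0, log(1.5))) {
      for (ms in c("none", "mar30")) {
        add(scenario_config(n_reps = n_reps, outcome_type = "binary",
                            shape = sh, strength = st, beta1 = b1,
                            missingness = ms))
      }
    }
  }
  scen
}

#' Run a whole study
#'
#' Executes every scenario in a manifest, stacks the per-replication
#' estimates, and summarises each scenario x method (x estimand) cell with
#' [summarise_performance()] against the scenario's true estimand value.
#' Results are deterministic given the manifest's seeds, regardless of
#' execution order. When the manifest has an `output_dir`, per-replication
#' estimates, the summary table and a run log are written as CSV/text.
#'
#' @param manifest a [study_manifest()].
#' @param verbose print one progress line per scenario.
#' @return List with `estimates` (per-replication rows) and `summary`
#'   (one row per scenario x method x estimand).
#' @export
run_study <- function(manifest, verbose = FALSE) {
  stopifnot(inherits(manifest, "study_manifest"))
  all_est <- vector("list", length(manifest$scenarios))
  summaries <- list()
  log_lines <- character(0)
  for (i in seq_along(manifest$scenarios)) {
    cfg <- manifest$scenarios[[i]]
    methods <- manifest$methods
    if (cfg$outcome_type == "continuous") {
      methods <- setdiff(methods, "cmh")
    }
    t0 <- proc.time()[["elapsed"]]
    est <- run_scenario(cfg, methods)
    elapsed <- proc.time()[["elapsed"]] - t0
    all_est[[i]] <- est
    groups <- unique(est[, c("method", "estimand")])
    for (g in seq_len(nrow(groups))) {
      sub <- est[est$method == groups$method[g] &
                   est$estimand == groups$estimand[g], ]
      truth <- true_estimand_value(cfg, groups$estimand[g])
      s <- tryCatch(summarise_performance(sub, truth), error = function(e) {
        warning("scenario ", cfg$scenario_id, " / ", groups$method[g], ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(s)) next
      s <- cbind(data.frame(scenario_id = cfg$scenario_id,
                            method = groups$method[g],
                            estimand = groups$estimand[g],
                            true_value = truth), s)
      summaries[[length(summaries) + 1L]] <- s
    }
    line <- sprintf("%s: %d reps, %d non-converged rows, %.1fs",
                    cfg$scenario_id, cfg$n_reps, sum(!est$converged),
                    elapsed)
    log_lines <- c(log_lines, line)
    if (verbose) message(line)
  }
  estimates <- do.call(rbind, all_est)
  summary <- if (length(summaries)) do.call(rbind, summaries) else NULL
  if (!is.null(manifest$output_dir)) {
    dir.create(manifest$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(estimates,
                     file.path(manifest$output_dir, "estimates.csv"),
                     row.names = FALSE)
    if (!is.null(summary)) {
      utils::write.csv(summary,
                       file.path(manifest$output_dir, "summary.csv"),
                       row.names = FALSE)
    }
    writeLines(log_lines, file.path(manifest$output_dir, "run_log.txt"))
  }
  list(estimates = estimates, summary = summary)
}

#' Read a study manifest from a YAML config file
#'
#' The file holds flat defaults plus a `scenarios` list; each scenario entry
#' is a set of [scenario_config()] arguments overriding the defaults.
#' Top-level keys `methods`, `output_dir` and `root_seed` map to the
#' corresponding [study_manifest()] fields.
#'
#' @param path path to a YAML file.
#' @return A `study_manifest`.
#' @export
read_manifest <- function(path) {
  # keep keys like `n` and `y` literal instead of YAML-1.1 booleans
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (x %in% c("true", "True", "TRUE")) TRUE else x,
    "bool#no" = function(x) if (x %in% c("false", "False", "FALSE")) FALSE else x
  ))
  defaults <- cfg$defaults %||% list()
  scen_specs <- cfg$scenarios
  if (is.null(scen_specs)) stop("manifest has no `scenarios` list",
                                call. = FALSE)
  scenarios <- lapply(scen_specs, function(s) {
    do.call(scenario_config, utils::modifyList(defaults, as.list(s)))
  })
  study_manifest(scenarios,
                 methods = cfg$methods %||% c("none", "categories", "linear",
                                              "fp2", "rcs5"),
                 output_dir = cfg$output_dir,
                 root_seed = cfg$root_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial dataset as CSV
#'
#' @param dataset trial `data.frame`.
#' @param path output file.
#' @export
write_trial_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
}
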