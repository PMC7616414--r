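test_that("a noise-free treatment effect is recovered exactly with zero SE", {
  set.seed(21)
  x <- rnorm(40)
  dat <- data.frame(id = 1:40, x = x, x_strat = as.integer(x >= 0),
                    t = rep(0:1, 20), y = 0.4 * rep(0:1, 20),
                    y_observed = TRUE)
  for (adj in c("none", "categories", "linear", "rcs5")) {
    r <- fit_continuous(dat, adj)
    expect_true(r$converged)
    expect_equal(r$estimate, 0.4, tolerance = 1e-10)
    expect_equal(r$se, 0, tolerance = 1e-7)
    expect_equal(r$estimand, "mean_difference")
  }
})

test_that("OLS treatment estimate matches independent normal-equation and Nelder-Mead oracles", {
  dat <- data.frame(id = 1:6,
                    x = c(-1.2, 0.3, 0.8, -0.5, 1.5, -2.0),
                    x_strat = c(0L, 1L, 1L, 0L, 1L, 0L),
                    t = c(0L, 1L, 0L, 1L, 1L, 0L),
                    y = c(0.1, 1.3, 0.9, 0.2, 2.1, -1.5),
                    y_observed = TRUE)
  r <- fit_continuous(dat, "linear")
  X <- cbind(1, dat$t, dat$x)
  beta <- solve(t(X) %*% X, t(X) %*% dat$y)
  expect_equal(r$estimate, beta[2], tolerance = 1e-10)
  rss <- sum((dat$y - X %*% beta)^2)
  se2 <- rss / (6 - 3) * solve(t(X) %*% X)[2, 2]
  expect_equal(r$se, sqrt(se2), tolerance = 1e-10)
  # brute-force minimiser of the residual sum of squares
  nm <- optim(c(0, 0, 0), function(b) sum((dat$y - X %*% b)^2),
              method = "Nelder-Mead",
              control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(r$estimate, nm$par[2], tolerance = 1e-4)
  # df is residual: n_used - parameters
  expect_equal(r$df, 3)
})

test_that("complete-case analysis uses only observed outcomes", {
  dat <- make_fixture_trial(n = 60, seed = 31)
  dat$y_observed[1:15] <- FALSE
  r <- fit_continuous(dat, "linear")
  expect_equal(r$n_used, 45L)
  direct <- lm(y ~ t + x, data = dat[dat$y_observed, ])
  expect_equal(r$estimate, unname(coef(direct)[2]), tolerance = 1e-12)
  expect_equal(r$se, unname(sqrt(diag(vcov(direct)))[2]), tolerance = 1e-12)
  # t-based interval on residual df
  expect_equal(r$ci_high - r$estimate, qt(0.975, direct$df.residual) * r$se,
               tolerance = 1e-12)
})

test_that("logistic fit matches an independent Newton iteration on the score equations", {
  dat <- make_fixture_trial(n = 20, seed = 41, binary = TRUE)
  r <- fit_binary_conditional(dat, "linear")
  X <- cbind(1, dat$t, dat$x)
  oracle <- irls_logistic_oracle(X, dat$y)
  expect_equal(r$estimate, oracle$coef[2], tolerance = 1e-6)
  expect_equal(r$se, sqrt(oracle$vcov[2, 2]), tolerance = 1e-6)
  expect_equal(r$df, Inf)
})

test_that("degenerate binary outcomes are reported as non-converged", {
  dat <- make_fixture_trial(n = 30, seed = 51, binary = TRUE)
  dat$y <- 0L
  r <- fit_binary_conditional(dat, "none")
  expect_false(r$converged)
  rd <- standardised_risk_difference(dat, "none")
  expect_false(rd$converged)
})

test_that("standardised risk difference is zero when arms are exchangeable", {
  # mirror-image arms (same covariates, same outcomes): the fitted
  # treatment coefficient is 0 and so is the standardised contrast
  x <- rep(c(-1, -0.2, 0.4, 1.3), 5)
  y <- rep(c(1L, 0L, 0L, 1L, 0L), 4)
  dat <- data.frame(id = 1:40, x = c(x, x),
                    x_strat = as.integer(c(x, x) >= 0),
                    t = rep(0:1, each = 20), y = c(y, y),
                    y_observed = TRUE)
  r <- standardised_risk_difference(dat, "categories")
  expect_equal(r$estimate, 0, tolerance = 1e-8)
})

test_that("delta-method SE for the risk difference agrees with a parametric bootstrap", {
  dat <- make_fixture_trial(n = 40, seed = 61, binary = TRUE)
  r <- standardised_risk_difference(dat, "linear")
  # oracle: resample coefficients from their asymptotic normal and
  # recompute the standardised contrast each time
  X <- cbind(1, dat$t, dat$x)
  fit <- glm.fit(X, dat$y, family = binomial())
  Rm <- fit$qr$qr[1:3, 1:3]; Rm[lower.tri(Rm)] <- 0
  V <- chol2inv(Rm)[order(fit$qr$pivot), order(fit$qr$pivot)]
  set.seed(62)
  U <- chol(V)
  draws <- replicate(10000, {
    b <- fit$coefficients + drop(crossprod(U, rnorm(3)))
    X1 <- X; X1[, 2] <- 1
    X0 <- X; X0[, 2] <- 0
    mean(plogis(X1 %*% b)) - mean(plogis(X0 %*% b))
  })
  expect_lt(abs(r$se - sd(draws)), 0.1 * sd(draws))
})

test_that("Mantel-Haenszel estimator collapses, symmetrises, and matches its oracles", {
  # single stratum: MH equals the raw cross-product odds ratio
  dat1 <- make_fixture_trial(n = 60, seed = 71, binary = TRUE)
  dat1$x_strat <- 0L
  r1 <- cmh_odds_ratio(dat1)
  tab <- table(factor(dat1$t, c(1, 0)), factor(dat1$y, c(1, 0)))
  raw_or <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  expect_equal(exp(r1$estimate), unname(raw_or), tolerance = 1e-10)

  # two identical balanced strata: OR exactly 1
  bal <- do.call(rbind, lapply(0:1, function(s) {
    data.frame(id = 0, x = s, x_strat = s,
               t = rep(c(1, 0), each = 20),
               y = rep(c(1, 0, 1, 0), each = 10), y_observed = TRUE)
  }))
  expect_equal(cmh_odds_ratio(bal)$estimate, 0, tolerance = 1e-12)

  # seeded two-stratum fixture: matches hand-coded MH/RBG arithmetic and
  # the established CMH test implementation
  dat2 <- make_fixture_trial(n = 120, seed = 72, binary = TRUE)
  r2 <- cmh_odds_ratio(dat2)
  tabs <- lapply(0:1, function(s) {
    sub <- dat2[dat2$x_strat == s, ]
    matrix(c(sum(sub$t == 1 & sub$y == 1), sum(sub$t == 1 & sub$y == 0),
             sum(sub$t == 0 & sub$y == 1), sum(sub$t == 0 & sub$y == 0)),
           2, 2, byrow = TRUE)
  })
  oracle <- mh_oracle(tabs)
  expect_equal(exp(r2$estimate), oracle$or, tolerance = 1e-10)
  expect_equal(r2$se, oracle$se_log, tolerance = 1e-10)
  arr <- array(unlist(lapply(tabs, t)), dim = c(2, 2, 2))
  ref <- mantelhaen.test(aperm(arr, c(2, 1, 3)), correct = FALSE)
  expect_equal(exp(r2$estimate), unname(ref$estimate), tolerance = 1e-8)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-8)

  # all-degenerate strata are an error
  dd <- dat2; dd$y <- 1L
  expect_error(cmh_odds_ratio(dd), "degenerate")
})

test_that("multiple imputation reduces to the complete-data fit when nothing is missing", {
  dat <- make_fixture_trial(n = 80, seed = 81)
  mi <- multiple_imputation_estimate(dat, "linear", m = 5)
  cc <- fit_continuous(dat, "linear")
  expect_equal(mi$estimate, cc$estimate)
  expect_equal(mi$se, cc$se)
})

test_that("Rubin's rules pooling matches the direct formula", {
  set.seed(91)
  dat <- make_fixture_trial(n = 100, seed = 91)
  dat$y_observed <- runif(100) > 0.3
  mi <- multiple_imputation_estimate(dat, "linear", m = 12)
  ests <- attr(mi, "imputation_estimates")
  ses <- attr(mi, "imputation_ses")
  m <- length(ests)
  W <- mean(ses^2)
  B <- sum((ests - mean(ests))^2) / (m - 1)
  expect_equal(mi$estimate, mean(ests))
  expect_equal(mi$se, sqrt(W + (1 + 1 / m) * B), tolerance = 1e-12)
  # Barnard-Rubin df never exceeds the complete-data residual df
  expect_lt(mi$df, 100 - 3)
  expect_error(multiple_imputation_estimate(
    transform(dat, y_observed = FALSE), "linear", m = 5), "complete cases")
})

test_that("multiple imputation tracks complete-case analysis under a correctly specified MAR model", {
  # missingness depends on x and t only; adjusting linearly is correct, so
  # CC and MI should agree in expectation
  cfg <- scenario_config(shape = "linear", strength = "moderate",
                         beta1 = 0.4, missingness = "mar30", n_reps = 80,
                         m_imputations = 10, seed = 92)
  cc_est <- run_scenario(cfg, methods = "linear")
  cfg_mi <- cfg
  cfg_mi$missing_handler <- "multiple_imputation"
  mi_est <- run_scenario(cfg_mi, methods = "linear")
  s_cc <- summarise_performance(cc_est, 0.4)
  s_mi <- summarise_performance(mi_est, 0.4)
  expect_lt(abs(s_mi$bias - s_cc$bias), 3 * s_cc$mcse_bias)
})

test_that("singular designs are flagged rather than crashing", {
  dat <- make_fixture_trial(n = 30, seed = 93)
  dat$t <- 1L  # no contrast: treatment aliased with the intercept
  r <- fit_continuous(dat, "linear")
  expect_false(r$converged)
})
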