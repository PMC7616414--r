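# Independent oracles used across test files. Each is written directly from
# the defining equations, not from the package's implementation.

# Logistic regression by explicit Newton iteration on the score equations.
irls_logistic_oracle <- function(X, y, maxit = 50, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    score <- drop(t(X) %*% (y - p))
    W <- p * (1 - p)
    info <- t(X) %*% (W * X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, vcov = solve(info))
}

# Mantel-Haenszel common OR and Robins-Breslow-Greenland variance from the
# textbook formulas; `tabs` is a list of 2x2 matrices (rows treatment 1/0,
# columns outcome 1/0).
mh_oracle <- function(tabs) {
  a <- vapply(tabs, function(m) m[1, 1], 0)
  b <- vapply(tabs, function(m) m[1, 2], 0)
  cc <- vapply(tabs, function(m) m[2, 1], 0)
  d <- vapply(tabs, function(m) m[2, 2], 0)
  n <- a + b + cc + d
  or <- sum(a * d / n) / sum(b * cc / n)
  P <- (a + d) / n; Q <- (b + cc) / n
  R <- a * d / n; S <- b * cc / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  list(or = or, se_log = sqrt(v))
}

# Restricted cubic spline nonlinear terms re-derived from the truncated
# power definition, evaluated pointwise (deliberately loop-based).
rcs_oracle <- function(x, knots) {
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  cube <- function(u) if (u > 0) u^3 else 0
  out <- matrix(0, length(x), k - 1)
  for (i in seq_along(x)) {
    out[i, 1] <- x[i]
    for (j in seq_len(k - 2)) {
      out[i, j + 1] <- (cube(x[i] - knots[j]) -
                          cube(x[i] - tk1) * (tk - knots[j]) / (tk - tk1) +
                          cube(x[i] - tk) * (tk1 - knots[j]) / (tk - tk1)) /
        norm
    }
  }
  out
}

# Two-pass sample SD (textbook formula, no stats::sd).
two_pass_sd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

# 3-MC-SE tolerance for comparing a rerun against a printed cell: Monte
# Carlo error on both sides, combined in quadrature.
tol3 <- function(mcse_ours, mcse_paper) 3 * sqrt(mcse_ours^2 + mcse_paper^2)

# Small complete-data trial fixture built in code.
make_fixture_trial <- function(n = 40, seed = 421, binary = FALSE,
                               beta1 = 0.5, beta2 = 0.5) {
  set.seed(seed)
  x <- rnorm(n)
  x_strat <- as.integer(x >= 0)
  t <- randomise_stratified_blocks(x_strat, 4)
  y <- if (binary) {
    rbinom(n, 1, plogis(beta1 * t + beta2 * x))
  } else {
    beta1 * t + beta2 * x + rnorm(n)
  }
  data.frame(id = seq_len(n), x = x, x_strat = x_strat, t = t, y = y,
             y_observed = TRUE)
}
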