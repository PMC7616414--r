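#' The standard fractional-polynomial power set
#'
#' @return The eight candidate powers \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\},
#'   with 0 denoting the natural logarithm.
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# Shift needed to make x strictly positive before applying FP powers.
# Convention: zero when min(x) > 0; otherwise -min(x) + delta with delta the
# smallest non-zero gap between successive order statistics of x.
.fp_shift <- function(x) {
  mn <- min(x)
  if (mn > 0) return(0)
  gaps <- diff(sort(x))
  gaps <- gaps[gaps > 0]
  if (length(gaps) == 0L) {
    stop("cannot shift a constant covariate to positivity", call. = FALSE)
  }
  -mn + min(gaps)
}

# One FP term on the already-shifted positive scale: power 0 means ln.
.fp_term <- function(z, p) if (p == 0) log(z) else z^p

#' Two-term fractional-polynomial basis
#'
#' Builds the two-column FP-2 expansion of a covariate for a pair of powers
#' from the standard set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}. The covariate is
#' first shifted to strict positivity when needed (shift = -min(x) plus the
#' smallest non-zero gap between order statistics, the convention of standard
#' FP software). Power 0 denotes ln(x); a repeated power (p, p) produces the
#' pair (x^p, x^p ln x), so (0, 0) gives (ln x, (ln x)^2).
#'
#' @param x numeric covariate with at least 3 distinct values.
#' @param powers length-2 numeric vector of powers from [fp_powers()].
#' @param meta optional transformation record from a previous call; when
#'   supplied, its shift (and powers) are re-applied to `x` unchanged, which
#'   is how fitted transformations are re-applied to new data.
#' @return An object of class `basis_matrix`: a list with `columns` (n x 2
#'   matrix) and `meta` (`type`, `powers`, `shift`).
#' @examples
#' b <- fp2_basis(c(1, 2, 4), powers = c(1, 2))
#' b$columns
#' @export
fp2_basis <- function(x, powers, meta = NULL) {
  if (!is.null(meta)) {
    powers <- meta$powers
    shift <- meta$shift
  } else {
    if (length(unique(x)) < 3L) {
      stop("FP-2 basis needs a covariate with at least 3 distinct values",
           call. = FALSE)
    }
    shift <- .fp_shift(x)
  }
  if (length(powers) != 2L || !all(powers %in% fp_powers())) {
    stop("`powers` must be two values from the standard FP set ",
         "{-2, -1, -0.5, 0, 0.5, 1, 2, 3}", call. = FALSE)
  }
  powers <- sort(powers)
  z <- x + shift
  c1 <- .fp_term(z, powers[1])
  c2 <- if (powers[1] == powers[2]) c1 * log(z) else .fp_term(z, powers[2])
  structure(list(columns = cbind(fp1 = c1, fp2 = c2),
                 meta = list(type = "fp2", powers = powers, shift = shift)),
            class = "basis_matrix")
}

# All 36 unordered power pairs (28 distinct + 8 repeated), lexicographic.
.fp2_candidates <- function() {
  p <- fp_powers()
  out <- vector("list", 36L)
  k <- 0L
  for (i in seq_along(p)) for (j in i:length(p)) {
    k <- k + 1L
    out[[k]] <- c(p[i], p[j])
  }
  out
}

#' Select the best-fitting FP-2 basis
#'
#' Fits the outcome model (intercept + treatment + two FP terms) for each of
#' the 36 candidate power pairs and returns the basis minimising the
#' deviance (residual sum of squares for gaussian outcomes). Treatment is
#' always retained in the model during selection; ties are broken in favour
#' of the lexicographically smallest power pair, which is the order the
#' candidates are visited in. If every candidate fit fails, the selection
#' falls back to a single linear term with a warning.
#'
#' @param x,y,t covariate, outcome and treatment vectors of equal length.
#' @param family `"gaussian"` (least squares) or `"binomial"` (logistic
#'   maximum likelihood).
#' @param powers optional fixed power pair; when supplied, selection is
#'   skipped and [fp2_basis()] with these powers is returned (use to hold the
#'   transformation constant across replications).
#' @return A `basis_matrix`; its `meta` additionally records the attained
#'   `deviance`.
#' @export
fp2_select <- function(x, y, t, family = c("gaussian", "binomial"),
                       powers = NULL) {
  family <- match.arg(family)
  stopifnot(length(x) == length(y), length(y) == length(t))
  if (!is.null(powers)) {
    return(fp2_basis(x, powers))
  }
  if (length(unique(x)) < 3L) {
    stop("FP-2 selection needs a covariate with at least 3 distinct values",
         call. = FALSE)
  }
  shift <- .fp_shift(x)
  z <- x + shift
  lz <- log(z)
  pset <- fp_powers()
  terms <- vapply(pset, function(p) .fp_term(z, p), numeric(length(z)))
  base <- cbind(1, t)

  best_dev <- Inf
  best_powers <- NULL
  n_fail <- 0L
  for (i in seq_along(pset)) {
    for (j in i:length(pset)) {
      b2 <- if (i == j) terms[, i] * lz else terms[, j]
      X <- cbind(base, terms[, i], b2)
      dev <- tryCatch({
        if (family == "gaussian") {
          fit <- stats::.lm.fit(X, y)
          sum(fit$residuals^2)
        } else {
          fit <- suppressWarnings(
            stats::glm.fit(X, y, family = stats::binomial())
          )
          if (!fit$converged) NA_real_ else fit$deviance
        }
      }, error = function(e) NA_real_)
      if (is.na(dev) || !is.finite(dev)) {
        n_fail <- n_fail + 1L
        next
      }
      if (dev < best_dev) {  # strict: exact ties keep the earlier (lex-smaller) pair
        best_dev <- dev
        best_powers <- c(pset[i], pset[j])
      }
    }
  }
  if (is.null(best_powers)) {
    warning("all 36 FP-2 candidate fits failed; falling back to a linear term",
            call. = FALSE)
    return(structure(list(columns = cbind(fp1 = x),
                          meta = list(type = "linear", powers = 1,
                                      shift = 0, deviance = NA_real_)),
                     class = "basis_matrix"))
  }
  out <- fp2_basis(x, best_powers)
  out$meta$deviance <- best_dev
  out
}

# Harrell's recommended knot percentiles (as proportions) by knot count.
.rcs_percentiles <- list(
  `3` = c(0.10, 0.50, 0.90),
  `4` = c(0.05, 0.35, 0.65, 0.95),
  `5` = c(0.05, 0.275, 0.50, 0.725, 0.95),
  `6` = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95)
)

#' Restricted cubic spline basis
#'
#' Builds the restricted (natural) cubic spline expansion of a covariate in
#' Harrell's truncated-power parameterisation: a linear term plus
#' `n_knots - 2` nonlinear terms, each a combination of cubic truncated
#' powers constrained so that the function is linear beyond the boundary
#' knots. Knots are placed at the standard percentiles of `x` (for 5 knots:
#' 5, 27.5, 50, 72.5, 95). Nonlinear terms are scaled by the squared
#' boundary-knot span, the usual normalisation.
#'
#' @param x numeric covariate.
#' @param n_knots number of knots, 3 to 6 (default 5).
#' @param knots optional explicit knot locations (overrides the percentile
#'   placement; used to re-apply a fitted basis to new data).
#' @return An object of class `basis_matrix` with `n_knots - 1` columns and
#'   `meta` recording `knots`.
#' @examples
#' b <- rcs_basis(rnorm(100))
#' dim(b$columns)  # 100 x 4
#' @export
rcs_basis <- function(x, n_knots = 5L, knots = NULL) {
  if (is.null(knots)) {
    if (!as.character(n_knots) %in% c("3", "4", "5", "6")) {
      stop("`n_knots` must be between 3 and 6", call. = FALSE)
    }
    probs <- .rcs_percentiles[[as.character(n_knots)]]
    knots <- unname(stats::quantile(x, probs, type = 7))
    if (anyDuplicated(knots)) {
      stop("duplicate knots at the requested percentiles; reduce `n_knots` ",
           "or supply distinct knots", call. = FALSE)
    }
  } else {
    knots <- sort(knots)
    if (anyDuplicated(knots)) stop("knots must be distinct", call. = FALSE)
    n_knots <- length(knots)
  }
  k <- length(knots)
  t_last <- knots[k]
  t_pen <- knots[k - 1]
  scale2 <- (t_last - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  cols <- matrix(NA_real_, nrow = length(x), ncol = k - 1L)
  cols[, 1] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    cols[, j + 1L] <- (pos3(x - tj) -
                         pos3(x - t_pen) * (t_last - tj) / (t_last - t_pen) +
                         pos3(x - t_last) * (t_pen - tj) / (t_last - t_pen)) /
      scale2
  }
  colnames(cols) <- c("rcs1", paste0("rcs", 1 + seq_len(k - 2L), "'"))
  structure(list(columns = cols,
                 meta = list(type = "rcs", knots = knots)),
            class = "basis_matrix")
}

#' Re-apply a fitted basis transformation to new covariate values
#'
#' Uses the `meta` record of a `basis_matrix` (FP powers and shift, or RCS
#' knots) to expand new covariate values with exactly the transformation
#' learned from the training data.
#'
#' @param basis a `basis_matrix` (or its `meta` list).
#' @param x new covariate values.
#' @return A numeric matrix with the same columns as the original basis.
#' @export
apply_basis <- function(basis, x) {
  meta <- if (inherits(basis, "basis_matrix")) basis$meta else basis
  switch(meta$type,
         fp2 = fp2_basis(x, meta = meta)$columns,
         rcs = rcs_basis(x, knots = meta$knots)$columns,
         linear = cbind(fp1 = x),
         stop("unknown basis type: ", meta$type, call. = FALSE))
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat("<basis_matrix> type =", x$meta$type,
      "| columns =", ncol(x$columns), "x", nrow(x$columns), "\n")
  if (x$meta$type == "fp2") {
    cat("  powers:", paste(x$meta$powers, collapse = ", "),
        " shift:", format(x$meta$shift, digits = 6), "\n")
  } else if (x$meta$type == "rcs") {
    cat("  knots:", paste(format(x$meta$knots, digits = 4), collapse = ", "),
        "\n")
  }
  invisible(x)
}
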