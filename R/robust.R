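# Robust regression with permutation-based Wald inference.
#
# The M-estimation core (Huber IRLS + heteroskedasticity-consistent
# sandwich Wald + predictor permutation) lives in src/robust.cpp; these
# wrappers build design matrices from tidy data and return tibble-friendly
# result objects.

build_design <- function(data, response, predictor, nuisance = character()) {
  cols <- c(response, predictor, nuisance)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
          class = "stressnets_schema_error")
  }
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 2) abort("need at least two complete observations")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(d[c(predictor, nuisance)]))
  y <- d[[response]]
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient",
          class = "stressnets_design_error")
  }
  if (n <= ncol(X)) {
    abort("more coefficients than observations",
          class = "stressnets_design_error")
  }
  list(X = X, y = y, j = 1L, n = n)  # j: 0-based C++ index of the predictor
}

#' Robust (Huber M-estimation) regression fit
#'
#' Fits a linear model by iteratively reweighted least squares with the
#' Huber weight function and MAD residual scale. With the default tuning
#' constant 1.345 the estimator retains about 95% efficiency under Gaussian
#' errors while bounding the influence of outliers; with `huber_k = Inf` it
#' reduces exactly to ordinary least squares. An intercept is always
#' included.
#'
#' @param data A data frame; rows with missing values in used columns are
#'   dropped (listwise deletion).
#' @param response,predictor Column names of the outcome and the predictor
#'   of interest.
#' @param nuisance Character vector of nuisance covariate columns.
#' @param huber_k Huber tuning constant (default 1.345; `Inf` gives OLS).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param maxit Maximum IRLS iterations.
#' @return A `robust_fit` object with coefficients, IRLS weights, residual
#'   scale, convergence flag and the design used.
#' @export
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' coef(robust_fit(d, "y", "x"))
robust_fit <- function(data, response, predictor, nuisance = character(),
                       huber_k = 1.345, tol = 1e-8, maxit = 200) {
  des <- build_design(data, response, predictor, nuisance)
  fit <- cpp_huber_fit(des$X, des$y, huber_k, tol, maxit)
  if (!fit$converged) {
    warn(sprintf("IRLS did not converge within %d iterations", maxit))
  }
  coefs <- as.numeric(fit$coefficients)
  names(coefs) <- colnames(des$X)
  structure(list(
    coefficients = coefs,
    weights = as.numeric(fit$weights),
    scale = fit$scale,
    converged = fit$converged,
    iterations = fit$iterations,
    design = des,
    huber_k = huber_k,
    response = response,
    predictor = predictor,
    nuisance = nuisance
  ), class = "robust_fit")
}

#' @export
coef.robust_fit <- function(object, ...) object$coefficients

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> %s ~ %s%s (Huber k = %g, n = %d)\n",
              x$response, x$predictor,
              if (length(x$nuisance))
                paste0(" + ", paste(x$nuisance, collapse = " + ")) else "",
              x$huber_k, x$design$n))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.robust_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.robust_fit <- function(x, ...) {
  tibble(n = x$design$n, scale = x$scale, converged = x$converged,
         iterations = x$iterations)
}

#' Sandwich Wald statistic for the predictor of interest
#'
#' Computes `W = b^2 / Var(b)` for the predictor-of-interest coefficient of
#' a robust fit, with a heteroskedasticity-consistent sandwich variance
#' built from the M-estimation estimating equations. Under the null `W` is
#' asymptotically Chi-squared with one degree of freedom; in the OLS limit
#' the variance is the HC0 sandwich. `W` is invariant to rescaling the
#' response or the predictor.
#'
#' @param fit A [robust_fit()] object.
#' @return A single non-negative number.
#' @export
wald_statistic <- function(fit) {
  stopifnot(inherits(fit, "robust_fit"))
  res <- cpp_wald(fit$design$X, fit$design$y, fit$design$j,
                  fit$huber_k, 1e-8, 200)
  res$wald
}

#' Permutation p-value for a robust regression coefficient
#'
#' Tests the predictor of interest by permuting its column across
#' participants while holding the response and nuisance covariates fixed,
#' refitting the robust regression and recomputing the sandwich Wald
#' statistic for each permutation (studentized-statistic robust permutation
#' testing). The p-value uses the add-one estimator
#' `(1 + #\{W_perm >= W_obs\}) / (1 + n_perm)`, which is valid at any finite
#' number of permutations; since `W` is a squared statistic the test is
#' two-sided. `t_equivalent` is the signed square root of `W`, negative
#' when larger predictor values go with smaller outcomes.
#'
#' @inheritParams robust_fit
#' @param n_perm Number of random permutations (ignored when
#'   `exhaustive = TRUE`).
#' @param seed Optional integer seed; recorded in the result.
#' @param exhaustive If `TRUE`, enumerate all `n!` permutations (n <= 8)
#'   and report the exact p-value `mean(W_all >= W_obs)` over the full
#'   permutation group (which contains the identity).
#' @param scheme `"predictor"` (default) permutes the predictor column;
#'   `"freedman_lane"` permutes residuals from the nuisance-only model and
#'   adds them back to the nuisance fit.
#' @param sequential_h If positive, stop permuting once `sequential_h`
#'   permutation statistics have reached the observed one and report the
#'   Besag-Clifford sequential p-value `h / n_done` (a valid p-value whose
#'   significance decisions at thresholds below `h / (n_perm + 1)` agree
#'   with the full run). Useful for large calibration studies; 0 disables.
#' @return A `robust_perm_test` object (also a tibble row via [tidy()]):
#'   estimate, `wald`, `t_equivalent`, `p_permutation`, `n_permutations`,
#'   `n`, `seed`.
#' @export
permutation_pvalue <- function(data, response, predictor,
                               nuisance = character(),
                               n_perm = 10000, seed = NULL,
                               exhaustive = FALSE,
                               scheme = c("predictor", "freedman_lane"),
                               sequential_h = 0,
                               huber_k = 1.345, tol = 1e-8, maxit = 200) {
  scheme <- match.arg(scheme)
  check_count(n_perm, "n_perm")
  des <- build_design(data, response, predictor, nuisance)
  if (!is.null(seed)) set.seed(seed)
  if (exhaustive) {
    if (des$n > 8) abort("exhaustive enumeration only supported for n <= 8")
    perms <- all_permutations(des$n)
    W_all <- cpp_wald_perm_matrix(des$X, des$y, des$j, perms,
                                  huber_k, tol, maxit)
    obs <- cpp_wald(des$X, des$y, des$j, huber_k, tol, maxit)
    W_obs <- obs$wald
    p <- mean(W_all >= W_obs - 1e-12)
    n_used <- nrow(perms)
    est <- obs$estimate
  } else if (scheme == "predictor") {
    res <- cpp_perm_wald(des$X, des$y, des$j, n_perm, huber_k, tol, maxit,
                         as.integer(sequential_h))
    W_obs <- res$wald_obs
    stopped_early <- res$n_done < n_perm
    p <- if (stopped_early) res$n_exceed / res$n_done
         else (1 + res$n_exceed) / (1 + n_perm)
    n_used <- res$n_done
    est <- res$estimate
  } else {
    # Freedman-Lane: permute residuals of the nuisance-only model
    Xn <- des$X[, -(des$j + 1L), drop = FALSE]
    qn <- qr(Xn)
    fitted_n <- qr.fitted(qn, des$y)
    resid_n <- qr.resid(qn, des$y)
    obs <- cpp_wald(des$X, des$y, des$j, huber_k, tol, maxit)
    W_obs <- obs$wald
    W_perm <- vapply(seq_len(n_perm), function(b) {
      y_star <- fitted_n + resid_n[sample.int(des$n)]
      cpp_wald(des$X, y_star, des$j, huber_k, tol, maxit)$wald
    }, numeric(1))
    p <- perm_pvalue(W_obs, W_perm)
    n_used <- n_perm
    est <- obs$estimate
  }
  structure(list(
    estimate = est,
    wald = W_obs,
    t_equivalent = sign(est) * sqrt(W_obs),
    p_permutation = p,
    n_permutations = n_used,
    n = des$n,
    seed = seed,
    scheme = if (exhaustive) "exhaustive" else scheme,
    response = response,
    predictor = predictor
  ), class = "robust_perm_test")
}

#' @export
print.robust_perm_test <- function(x, ...) {
  cat(sprintf(
    "<robust_perm_test> %s ~ %s: estimate %.4g, W = %.3f, t = %.2f, p = %.4g (%s, %d perms, n = %d)\n",
    x$response, x$predictor, x$estimate, x$wald, x$t_equivalent,
    x$p_permutation, x$scheme, x$n_permutations, x$n))
  invisible(x)
}

#' @export
tidy.robust_perm_test <- function(x, ...) {
  tibble(response = x$response, predictor = x$predictor,
         estimate = x$estimate, wald = x$wald,
         t_equivalent = x$t_equivalent,
         p_permutation = x$p_permutation,
         n_permutations = x$n_permutations, n = x$n)
}

#' Bonferroni per-test significance threshold
#'
#' Divides the family-wise false-positive rate by the number of tests. With
#' 28 networks this gives per-test thresholds of 0.0018 for a family-wise
#' alpha of 0.05 and 0.0036 for 0.1 (rounded to four decimals for
#' display).
#'
#' @param alpha_fwe Family-wise alpha in (0, 1).
#' @param m Number of tests in the family.
#' @return The per-test alpha, `alpha_fwe / m` (unrounded).
#' @export
#' @examples
#' round(bonferroni_threshold(0.05, 28), 4)  # 0.0018
bonferroni_threshold <- function(alpha_fwe, m) {
  check_number(alpha_fwe, "alpha_fwe", lower = 1e-12, upper = 1 - 1e-12)
  check_count(m, "m")
  alpha_fwe / m
}
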