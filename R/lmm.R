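# Random-intercept linear mixed models with within-participant sign-flip
# permutation inference, for paired repeated-measures contrasts.
#
# The fitter maximises the profile ML likelihood over the variance ratio
# lambda = sigma_b^2 / sigma_e^2, exploiting the closed form of
# V_i^-1 = I - lambda/(1 + n_i lambda) J for a random intercept, so a fit
# costs microseconds and the permutation test can refit thousands of
# times. ML (not REML) is used so likelihoods are comparable across
# permutations; p-values come from the permutation distribution, not from
# the ML t reference.

lmm_profile <- function(X, y, group) {
  groups <- split(seq_along(y), group)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  Sx <- t(vapply(groups, function(ix)
    colSums(X[ix, , drop = FALSE]), numeric(ncol(X))))
  Sy <- vapply(groups, function(ix) sum(y[ix]), numeric(1))
  ni <- lengths(groups)
  N <- length(y)

  eval_lambda <- function(lambda) {
    ci <- lambda / (1 + ni * lambda)
    A <- XtX - crossprod(Sx * sqrt(ci))
    b <- Xty - colSums(Sx * (ci * Sy))
    beta <- solve(A, b)
    quad <- yty - sum(ci * Sy^2) - 2 * sum(beta * b) +
      sum(beta * (A %*% beta))
    sigma2 <- max(quad / N, 1e-300)
    ll <- -0.5 * (N * log(2 * pi * sigma2) + sum(log1p(ni * lambda)) + N)
    list(ll = ll, beta = beta, sigma2 = sigma2, A = A, lambda = lambda)
  }

  opt <- optimize(function(lg) eval_lambda(exp(lg))$ll,
                  interval = c(-15, 15), maximum = TRUE, tol = 1e-9)
  best <- eval_lambda(exp(opt$maximum))
  at_zero <- eval_lambda(0)
  if (at_zero$ll >= best$ll) best <- at_zero
  best
}

#' Fit a random-intercept linear mixed model
#'
#' Maximum-likelihood fit of `response ~ fixed effects + (1 | participant)`
#' for repeated-measures designs. Returns the coefficient and t statistic
#' of the regressor of interest; the t statistic's null distribution is
#' meant to be taken from [permutation_test_repeated()], not from a
#' reference distribution. A boundary fit (zero between-participant
#' variance) degrades gracefully to the independence model and is flagged
#' via `singular`.
#'
#' @param data Long-format data frame, one row per participant-occasion.
#' @param response Response column name.
#' @param interest Column name of the fixed regressor of interest (e.g. a
#'   0/1 stage code, or time in days).
#' @param nuisance Character vector of fixed nuisance covariate columns
#'   (an intercept is always added).
#' @param group Grouping column for the random intercept (default
#'   `"participant_id"`).
#' @return An `lmm_fit` object with `estimate`, `t`, `coefficients`,
#'   `sigma_b`, `sigma_e`, `loglik`, `singular`, `n_groups`.
#' @export
fit_lmm <- function(data, response, interest, nuisance = character(),
                    group = "participant_id") {
  cols <- c(response, interest, nuisance, group)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
          class = "stressnets_schema_error")
  }
  d <- data[complete.cases(data[cols]), cols]
  if (length(unique(d[[group]])) < 2) {
    abort("need at least two participants with complete occasions")
  }
  num <- lapply(c(interest, nuisance), function(cn)
    encode_numeric(d[[cn]], cn))
  X <- cbind(`(Intercept)` = 1, do.call(cbind, num))
  colnames(X) <- c("(Intercept)", interest, nuisance)
  if (qr(X)$rank < ncol(X)) {
    abort("fixed-effect design is rank deficient",
          class = "stressnets_design_error")
  }
  fit <- lmm_profile(X, d[[response]], d[[group]])
  se <- sqrt(fit$sigma2 * diag(solve(fit$A)))
  j <- 2L  # interest column
  tj <- if (se[j] > 0) fit$beta[j] / se[j]
        else if (fit$beta[j] == 0) 0 else sign(fit$beta[j]) * Inf
  structure(list(
    estimate = unname(fit$beta[j]),
    t = unname(tj),
    coefficients = setNames(as.numeric(fit$beta), colnames(X)),
    sigma_b = sqrt(fit$lambda * fit$sigma2),
    sigma_e = sqrt(fit$sigma2),
    loglik = fit$ll,
    singular = fit$lambda == 0,
    n_groups = length(unique(d[[group]])),
    n_obs = nrow(d),
    interest = interest,
    response = response
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> %s ~ %s + (1|participant): estimate %.4g, t = %.2f (%d participants%s)\n",
    x$response, x$interest, x$estimate, x$t, x$n_groups,
    if (x$singular) ", singular fit" else ""))
  invisible(x)
}

#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(sigma_b = x$sigma_b, sigma_e = x$sigma_e, loglik = x$loglik,
         singular = x$singular, n_groups = x$n_groups, n_obs = x$n_obs)
}

# Core permutation engine on a prepared design. Swapping the interest
# regressor's values within a participant relabels that participant's
# occasions; under the null of no occasion effect the relabelings are
# exchangeable. Participant-level covariates are constant within
# participant and therefore unaffected.
lmm_flip_test <- function(d, response, interest, nuisance, group,
                          n_perm, direction, exhaustive) {
  obs <- fit_lmm(d, response, interest, nuisance, group)
  ids <- unique(d[[group]])
  idx_by_id <- split(seq_len(nrow(d)), d[[group]])[as.character(ids)]
  if (!all(lengths(idx_by_id) == 2)) {
    abort("the relabeling test needs exactly two occasions per participant",
          class = "stressnets_design_error")
  }
  base_int <- d[[interest]]
  refit_t <- function(flips) {
    x <- base_int
    for (g in which(flips < 0)) {
      ix <- idx_by_id[[g]]
      x[ix] <- base_int[rev(ix)]
    }
    d2 <- d
    d2[[interest]] <- x
    fit_lmm(d2, response, interest, nuisance, group)$t
  }
  side_p <- function(t_obs, t_perm, add_one = TRUE) {
    cmp <- switch(direction,
      increase = t_perm >= t_obs - 1e-12,
      decrease = t_perm <= t_obs + 1e-12,
      two_sided = abs(t_perm) >= abs(t_obs) - 1e-12)
    if (add_one) (1 + sum(cmp)) / (1 + length(t_perm)) else mean(cmp)
  }
  if (exhaustive) {
    if (length(ids) > 20) abort("exhaustive sign-flip needs <= 20 participants")
    flips <- all_sign_flips(length(ids))
    t_all <- apply(flips, 1, refit_t)
    p <- side_p(obs$t, t_all, add_one = FALSE)
    n_used <- nrow(flips)
  } else {
    t_perm <- vapply(seq_len(n_perm), function(b) {
      refit_t(sample(c(-1, 1), length(ids), replace = TRUE))
    }, numeric(1))
    p <- side_p(obs$t, t_perm)
    n_used <- n_perm
  }
  list(fit = obs, p = p, n_used = n_used)
}

#' Sign-flip permutation test for a repeated-measures contrast
#'
#' Builds the null distribution of the mixed-model t statistic by
#' independently relabeling the two occasions within each participant
#' (2^n possible relabelings, sampled `n_perm` times or enumerated
#' exhaustively), refitting the model for each relabeling. The p-value is
#' one-sided in the stated direction with the add-one estimator (exact
#' enumeration uses the full group, which contains the identity).
#'
#' @inheritParams fit_lmm
#' @param n_perm Number of random relabelings.
#' @param seed Optional integer seed.
#' @param direction `"increase"`, `"decrease"` or `"two_sided"`.
#' @param exhaustive Enumerate all `2^n` relabelings (n <= 20).
#' @return An `lmm_test` object: `estimate`, `t`, `p_permutation`,
#'   `direction`, `n_permutations`, `n_groups`, `seed`, `singular`.
#' @export
permutation_test_repeated <- function(data, response, interest,
                                      nuisance = character(),
                                      group = "participant_id",
                                      n_perm = 10000, seed = NULL,
                                      direction = c("increase", "decrease",
                                                    "two_sided"),
                                      exhaustive = FALSE) {
  direction <- match.arg(direction)
  check_count(n_perm, "n_perm")
  if (!is.null(seed)) set.seed(seed)
  res <- lmm_flip_test(data, response, interest, nuisance, group,
                       n_perm, direction, exhaustive)
  structure(list(
    estimate = res$fit$estimate,
    t = res$fit$t,
    p_permutation = res$p,
    direction = direction,
    n_permutations = res$n_used,
    n_groups = res$fit$n_groups,
    seed = seed,
    singular = res$fit$singular,
    response = response,
    interest = interest
  ), class = "lmm_test")
}

#' @export
print.lmm_test <- function(x, ...) {
  cat(sprintf(
    "<lmm_test> %s ~ %s: estimate %.4g, t = %.2f, one-sided (%s) p = %.4g (%d relabelings, %d participants)\n",
    x$response, x$interest, x$estimate, x$t, x$direction,
    x$p_permutation, x$n_permutations, x$n_groups))
  invisible(x)
}

#' @export
tidy.lmm_test <- function(x, ...) {
  tibble(response = x$response, interest = x$interest,
         estimate = x$estimate, t = x$t,
         p_permutation = x$p_permutation, direction = x$direction,
         n_permutations = x$n_permutations, n_groups = x$n_groups)
}

#' Psychophysiological stage contrasts
#'
#' The four planned contrasts of the stress paradigm: stress exposure
#' should increase perceived stress (rating stages V vs. III) and pulse
#' (stages IV vs. II); stress cessation should decrease both (ratings VII
#' vs. V, pulse VI vs. IV). Each contrast is a mixed model of the two
#' stages with a 0/1 later-stage regressor, nuisance covariates (MS type,
#' task load, sex, age) and a one-sided sign-flip permutation p-value.
#' Participants missing a stage (pulse was recorded for a subset) are
#' dropped from that contrast only.
#'
#' @param psychophys Long table with columns `participant_id`, `stage`
#'   (`"I"`..`"VII"`), `parameter` (`"rating"`/`"pulse"`), `value`.
#' @param cohort Covariate table with `participant_id`, `ms_type`,
#'   `task_load`, `sex`, `age`.
#' @param n_perm,seed,alpha Permutations, seed and significance level.
#' @return A tibble with one row per contrast: parameter, stages,
#'   direction, estimate, t, p and significance flag.
#' @export
stage_contrasts <- function(psychophys, cohort, n_perm = 10000,
                            seed = NULL, alpha = 0.05) {
  contrasts <- tibble(
    parameter = c("rating", "pulse", "rating", "pulse"),
    earlier = c("III", "II", "V", "IV"),
    later = c("V", "IV", "VII", "VI"),
    direction = c("increase", "increase", "decrease", "decrease"),
    label = c("stress_rating", "stress_pulse",
              "cessation_rating", "cessation_pulse"))
  if (!is.null(seed)) set.seed(seed)
  purrr::pmap_dfr(contrasts, function(parameter, earlier, later,
                                      direction, label) {
    d <- psychophys |>
      filter(.data$parameter == !!parameter,
             .data$stage %in% c(earlier, later)) |>
      mutate(later_stage = as.numeric(.data$stage == later)) |>
      left_join(cohort, by = "participant_id")
    complete_ids <- d |>
      filter(!is.na(.data$value)) |>
      dplyr::count(.data$participant_id) |>
      filter(.data$n == 2) |>
      pull(.data$participant_id)
    d <- filter(d, .data$participant_id %in% complete_ids) |>
      arrange(.data$participant_id, .data$later_stage)
    res <- permutation_test_repeated(
      d, "value", "later_stage",
      nuisance = c("ms_type", "task_load", "sex", "age"),
      n_perm = n_perm, direction = direction)
    tidy(res) |>
      mutate(contrast = label, parameter = parameter,
             stages = paste(later, "vs", earlier)) |>
      select(all_of(c("contrast", "parameter", "stages", "direction",
                      "estimate", "t", "p_permutation", "n_groups",
                      "n_permutations"))) |>
      mutate(significant = .data$p_permutation < alpha)
  })
}

#' Longitudinal HRQoL change tests
#'
#' For the total score and each subscale, fits a mixed model of the score
#' on time (0 at T0, the follow-up delay in days at T1) with sex, age and
#' MS type as nuisance covariates and a per-participant random intercept,
#' and tests for worsening (increase, since higher HAQUAMS = worse) with
#' the sign-flip permutation test. The estimate is the worsening slope per
#' day.
#'
#' @param outcomes Wide score table (`participant_id`, `timepoint`,
#'   subscales, `total`).
#' @param cohort Covariates: `participant_id`, `sex`, `age`, `ms_type`,
#'   `followup_days`.
#' @param scales Scales to test (default total + subscales present).
#' @param n_perm,seed,alpha Permutations, seed, significance level.
#' @return A tibble with one row per scale.
#' @export
longitudinal_change <- function(outcomes, cohort,
                                scales = intersect(
                                  c("total", haquams_subscales()),
                                  names(outcomes)),
                                n_perm = 10000, seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(scales, function(sc) {
    if (!sc %in% names(outcomes)) {
      warn(sprintf("scale '%s' absent; skipped", sc))
      return(NULL)
    }
    d <- outcomes |>
      select(all_of(c("participant_id", "timepoint", sc))) |>
      left_join(cohort, by = "participant_id") |>
      mutate(time_days = ifelse(.data$timepoint == "T0", 0,
                                .data$followup_days)) |>
      arrange(.data$participant_id, .data$time_days)
    res <- permutation_test_repeated(
      d, sc, "time_days", nuisance = c("sex", "age", "ms_type"),
      n_perm = n_perm, direction = "increase")
    tidy(res) |>
      mutate(scale = sc) |>
      select(all_of(c("scale", "estimate", "t", "p_permutation",
                      "n_groups", "n_permutations"))) |>
      mutate(significant = .data$p_permutation < alpha)
  })
}
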