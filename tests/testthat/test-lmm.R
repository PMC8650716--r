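test_that("a noise-free contrast is recovered exactly", {
  d <- data.frame(participant_id = rep(1:6, each = 2),
                  occ = rep(c(0, 1), 6))
  d$y <- 2 + 1.5 * d$occ
  fit <- fit_lmm(d, "y", "occ")
  expect_equal(fit$estimate, 1.5, tolerance = 1e-8)
})

test_that("participant-constant offsets are absorbed by the random intercept", {
  set.seed(51)
  d <- make_paired_data(12, effect = 0.7, sd_participant = 0,
                        sd_noise = 0.5)
  base <- fit_lmm(d, "y", "occ", "age")
  d2 <- d
  d2$y <- d2$y + rep(rnorm(12, 0, 5), each = 2)
  shifted <- fit_lmm(d2, "y", "occ", "age")
  expect_equal(shifted$estimate, base$estimate, tolerance = 1e-6)
})

test_that("estimates and t statistics match the lme4 ML oracle", {
  skip_if_not_installed("lme4")
  set.seed(52)
  for (i in 1:3) {
    d <- make_paired_data(15, effect = 0.5, sd_participant = 1.2,
                          sd_noise = 0.8)
    mine <- fit_lmm(d, "y", "occ", "age")
    ref <- lme4::lmer(y ~ occ + age + (1 | participant_id), data = d,
                      REML = FALSE)
    expect_equal(mine$estimate, unname(lme4::fixef(ref)[["occ"]]),
                 tolerance = 1e-5)
    expect_equal(mine$t,
                 unname(coef(summary(ref))["occ", "t value"]),
                 tolerance = 1e-4)
    expect_equal(mine$loglik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-6)
  }
})

test_that("zero between-participant variance degrades to the fixed-effects fit", {
  set.seed(53)
  n <- 15
  d <- data.frame(participant_id = rep(1:n, each = 2),
                  occ = rep(c(0, 1), n))
  # iid noise, no participant effect: the variance ratio hits the boundary
  d$y <- 0.3 * d$occ + rnorm(2 * n)
  fit <- fit_lmm(d, "y", "occ")
  if (fit$singular) {
    ols <- coef(lm(y ~ occ, d))
    expect_equal(fit$estimate, unname(ols[["occ"]]), tolerance = 1e-7)
    expect_equal(fit$sigma_b, 0)
  }
  expect_true(is.finite(fit$t))
})

test_that("exhaustive sign-flip enumeration matches an lme4-refit oracle", {
  skip_if_not_installed("lme4")
  set.seed(54)
  d <- make_paired_data(5, effect = 1, sd_participant = 0.8,
                        sd_noise = 0.6)
  got <- permutation_test_repeated(d, "y", "occ", "age",
                                   exhaustive = TRUE,
                                   direction = "increase")
  expect_equal(got$n_permutations, 32)
  flips <- as.matrix(expand.grid(rep(list(c(1, -1)), 5)))
  t_all <- apply(flips, 1, function(fl) {
    d2 <- d
    for (i in which(fl < 0)) {
      rows <- which(d2$participant_id == sprintf("P%02d", i))
      d2$occ[rows] <- rev(d2$occ[rows])
    }
    ref <- lme4::lmer(y ~ occ + age + (1 | participant_id), data = d2,
                      REML = FALSE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore"))
    unname(coef(summary(ref))["occ", "t value"])
  })
  t_obs <- fit_lmm(d, "y", "occ", "age")$t
  expect_equal(got$p_permutation, mean(t_all >= t_obs - 1e-6),
               tolerance = 1e-6)
})

test_that("uniform positive within-participant change attains the minimal p", {
  d <- data.frame(participant_id = rep(1:8, each = 2),
                  occ = rep(c(0, 1), 8))
  d$y <- rep(rnorm(8), each = 2) + 2 * d$occ
  got <- permutation_test_repeated(d, "y", "occ", exhaustive = TRUE,
                                   direction = "increase")
  expect_equal(got$p_permutation, 1 / 256)
  mc <- permutation_test_repeated(d, "y", "occ", n_perm = 99, seed = 3,
                                  direction = "increase")
  expect_equal(mc$p_permutation, 1 / 100)
})

test_that("the sign-flip test controls size under exchangeable nulls", {
  # Gaussian and heavy-tailed (t3) participant-level noise
  for (noise in list(rnorm, function(n) rt(n, 3))) {
    set.seed(55)
    rejections <- vapply(1:200, function(i) {
      d <- make_paired_data(12, effect = 0, sd_participant = 1,
                            sd_noise = 1, noise = noise)
      p <- permutation_test_repeated(d, "y", "occ", n_perm = 99,
                                     direction = "two_sided")$p_permutation
      p < 0.05
    }, logical(1))
    rate <- mean(rejections)
    # 99% binomial interval around 0.05 at 200 replicates
    expect_gte(rate, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 200))
    expect_lte(rate, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 200))
  }
})

test_that("stage contrasts detect planted stress responses with correct directions", {
  cfg <- sim_config(seed = 3)
  ds <- simulate_cohort(cfg)
  res <- stage_contrasts(ds$psychophys, ds$cohort, n_perm = 199, seed = 8)
  expect_equal(res$direction,
               c("increase", "increase", "decrease", "decrease"))
  expect_true(all(res$significant))
  expect_true(all(res$t[res$direction == "increase"] > 0))
  expect_true(all(res$t[res$direction == "decrease"] < 0))
  # pulse contrasts use only participants with pulse data (21 of 28)
  expect_true(all(res$n_groups[res$parameter == "pulse"] == 21))
})

test_that("identical stage values give a zero contrast", {
  ids <- sprintf("P%02d", 1:8)
  psy <- dplyr::bind_rows(
    tibble::tibble(participant_id = ids, stage = "III",
                   parameter = "rating", value = c(2, 3, 4, 2, 5, 3, 2, 4)),
    tibble::tibble(participant_id = ids, stage = "V",
                   parameter = "rating", value = c(2, 3, 4, 2, 5, 3, 2, 4)))
  cohort <- tibble::tibble(participant_id = ids,
                           ms_type = rep(c("RRMS", "SPMS"), 4),
                           task_load = rnorm(8), sex = c(0, 0, 1, 1, 0, 1, 0, 1),
                           age = 40:47)
  d <- psy |>
    dplyr::mutate(later_stage = as.numeric(stage == "V")) |>
    dplyr::left_join(cohort, by = "participant_id")
  fit <- fit_lmm(d, "value", "later_stage",
                 c("ms_type", "task_load", "sex", "age"))
  expect_equal(fit$estimate, 0, tolerance = 1e-10)
  expect_equal(fit$t, 0, tolerance = 1e-8)
})

test_that("longitudinal tests flag planted worsening and are exchange invariant", {
  cfg <- sim_config(seed = 4, cessation_effect_size = 0,
                    time_slope_per_day = 5e-4, noise_sd_outcome = 0.05)
  ds <- simulate_cohort(cfg)
  res <- longitudinal_change(ds$outcomes, ds$cohort, scales = "total",
                             n_perm = 199, seed = 9)
  expect_true(res$significant[res$scale == "total"])
  expect_gt(res$estimate[1], 0)  # worsening slope per day
  # permuting the participant order of the covariate table changes nothing
  res2 <- longitudinal_change(ds$outcomes, ds$cohort[sample(28), ],
                              scales = "total", n_perm = 199, seed = 9)
  expect_equal(res2$estimate, res$estimate)
  expect_equal(res2$p_permutation, res$p_permutation)
})
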