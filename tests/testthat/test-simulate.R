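test_that("identical config and seed give byte-identical cohorts", {
  cfg <- sim_config(seed = 101)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c_ <- simulate_cohort(sim_config(seed = 102))
  expect_false(identical(a$outcomes, c_$outcomes))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_regions = 10, n_participants = 28),
               class = "stressnets_config_error")
  expect_error(sim_config(followup_days_range = c(100, 50)),
               class = "stressnets_config_error")
  expect_error(sim_config(noise_sd_cbf = -1))
  expect_error(sim_config(target_network = 9, n_latent_networks = 6),
               class = "stressnets_config_error")
})

test_that("the noise-free limit is exactly the planted factor model", {
  cfg <- sim_config(n_participants = 10, n_regions = 40, seed = 103,
                    noise_sd_cbf = 0, global_offset_sd = 0)
  ds <- simulate_cohort(cfg)
  cen <- gm_center(ds$stages$stress)
  planted <- ds$truth$scores$stress %*% t(ds$truth$loadings)
  expect_equal(as.matrix(cen[-1]), planted, ignore_attr = TRUE,
               tolerance = 1e-10)
  # recovered leading components span the planted loading space
  model <- fit_networks(cen)
  k <- cfg$n_latent_networks
  angles <- svd(crossprod(model$loadings[, 1:k], ds$truth$loadings))$d
  expect_lt(max(abs(angles - 1)), 1e-8)  # all principal angles ~ 0
  # with a single planted network the recovered scores correlate |r| = 1
  cfg1 <- sim_config(n_participants = 10, n_regions = 40, seed = 103,
                     n_latent_networks = 1, noise_sd_cbf = 0,
                     global_offset_sd = 0)
  ds1 <- simulate_cohort(cfg1)
  m1 <- fit_networks(gm_center(ds1$stages$stress))
  r <- cor(m1$scores[, 1], ds1$truth$scores$stress[, 1])
  expect_equal(abs(r), 1, tolerance = 1e-10)
})

test_that("stage matrices share index sets and the stress stage is elevated", {
  ds <- simulate_cohort(sim_config(seed = 104))
  ids <- ds$stages$baseline1$participant_id
  expect_identical(ds$stages$stress$participant_id, ids)
  expect_identical(ds$stages$baseline2$participant_id, ids)
  expect_identical(names(ds$stages$stress), names(ds$stages$baseline1))
  expect_false(anyNA(ds$stages$stress))
  # designated-network scores are shifted during stress
  tgt <- ds$truth$config$target_network
  expect_gt(mean(ds$truth$scores$stress[, tgt]) -
              mean(ds$truth$scores$baseline1[, tgt]), 0)
})

test_that("psychophysiological data respect scale ranges and missingness", {
  ds <- simulate_cohort(sim_config(seed = 105))
  psy <- ds$psychophys
  ratings <- psy$value[psy$parameter == "rating"]
  expect_true(all(ratings >= 1 & ratings <= 9))
  expect_true(all(psy$value[psy$parameter == "pulse"] > 0))
  expect_setequal(unique(psy$stage[psy$parameter == "rating"]),
                  c("I", "III", "V", "VII"))
  expect_setequal(unique(psy$stage[psy$parameter == "pulse"]),
                  c("II", "IV", "VI"))
  # study availability pattern: pulse for 21 of 28
  n_pulse <- length(unique(psy$participant_id[psy$parameter == "pulse"]))
  expect_equal(n_pulse, 21)
  # ratings stay in range under an extreme shift
  cohort <- ds$cohort
  shifted <- generate_psychophys(cohort,
                                 rating_means = c(I = 1, III = 5, V = 20,
                                                  VII = -5), seed = 1)
  r2 <- shifted$value[shifted$parameter == "rating"]
  expect_true(all(r2 >= 1 & r2 <= 9))
  expect_error(generate_psychophys(cohort,
                                   pulse_means = c(II = -5, IV = 80,
                                                   VI = 68)),
               class = "stressnets_parameter_error")
})

test_that("zero stage effects and zero noise give identical stages", {
  ds <- simulate_cohort(sim_config(n_participants = 6, n_regions = 10,
                                   seed = 106))
  flat <- generate_psychophys(ds$cohort,
                              rating_means = c(I = 3, III = 3, V = 3,
                                               VII = 3),
                              pulse_means = c(II = 70, IV = 70, VI = 70),
                              participant_sd = c(rating = 0, pulse = 0),
                              noise_sd = c(rating = 0, pulse = 0),
                              n_missing_pulse = 0, seed = 2)
  wide <- tidyr::pivot_wider(flat, names_from = "stage",
                             values_from = "value")
  pulse <- dplyr::filter(wide, parameter == "pulse")
  expect_true(all(pulse$II == pulse$IV & pulse$IV == pulse$VI))
})

test_that("outcomes stay on the instrument scale with a consistent total", {
  ds <- simulate_cohort(sim_config(seed = 107))
  out <- ds$outcomes
  scales <- c("fatigue", "lower_limb", "upper_limb", "social", "mood")
  vals <- as.matrix(out[scales])
  expect_true(all(vals >= 1 & vals <= 5))
  expect_equal(out$total, rowMeans(vals))
  expect_equal(nrow(out), 56)  # 28 participants x 2 timepoints
  # follow-up intervals within the study range
  expect_true(all(ds$cohort$followup_days >= 363 &
                    ds$cohort$followup_days <= 1169))
})

test_that("cohort files round-trip through CSV and a truth sidecar", {
  dir <- withr::local_tempdir()
  ds <- simulate_cohort(sim_config(n_participants = 6, n_regions = 10,
                                   seed = 108))
  write_cohort(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "cohort.csv", "outcomes.csv", "psychophys.csv", "stage_baseline1.csv",
    "stage_stress.csv", "stage_baseline2.csv", "truth.json")))))
  back <- utils::read.csv(file.path(dir, "stage_stress.csv"),
                          check.names = FALSE)
  expect_equal(as.matrix(back[-1]), as.matrix(ds$stages$stress[-1]),
               ignore_attr = TRUE, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$config$seed, 108)
})

test_that("missing baseline-2 participants propagate as missing cessation", {
  ds <- simulate_cohort(sim_config(n_participants = 8, n_regions = 12,
                                   seed = 109), n_missing_baseline2 = 1)
  expect_equal(nrow(ds$stages$baseline2), 7)
  model <- fit_networks(gm_center(ds$stages$stress))
  d <- differential_activity(
    project_stage(gm_center(ds$stages$baseline1), model),
    project_stage(gm_center(ds$stages$stress), model),
    project_stage(gm_center(ds$stages$baseline2), model))
  expect_equal(sum(!stats::complete.cases(d$cessation)), 1)
  expect_false(anyNA(d$exposure))
})
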