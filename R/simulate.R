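# Seeded synthetic-cohort generator emulating the study design: latent
# networks driving regional CBF over three fMRI stages, HAQUAMS outcomes
# with a planted network effect, clinico-demographic covariates, and
# psychophysiological stage responses.

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults emulate the study design:
#' 28 participants (23 RRMS, 5 SPMS expected), 100 atlas regions, six
#' latent networks with geometrically decaying activity variance (so
#' components are identifiable), a stress-stage elevation of the designated
#' network, follow-up intervals of 363--1169 days, and a planted
#' stress-cessation effect of the designated network on the total HAQUAMS
#' change score. Setting both effect sizes to 0 gives a global null.
#'
#' @param n_participants Number of participants (default 28).
#' @param n_regions Number of atlas regions (default 100; must be at least
#'   `n_participants`).
#' @param n_latent_networks Number of planted latent networks (default 6).
#' @param loading_spec `"block"` (default): each network loads on its own
#'   contiguous block of regions with a zero-sum two-sided pattern, giving
#'   orthonormal, mutually disjoint loading vectors; `"random"`: random
#'   orthonormal loadings.
#' @param network_score_sd Standard deviation of the designated (first)
#'   network's activity scores in CBF units (default 8); later networks
#'   decay by `score_decay`.
#' @param score_decay Geometric decay of score SDs across networks
#'   (default 0.8), which separates component variances so the latent
#'   networks are identifiable.
#' @param stress_score_shift Mean elevation of the designated network's
#'   score during the stress stage (default 5).
#' @param target_network Index of the designated network carrying the
#'   planted outcome effect and the stress elevation (default 1).
#' @param target_scale HAQUAMS scale receiving the planted effect
#'   (default `"total"`, meaning every subscale shifts equally).
#' @param exposure_effect_size,cessation_effect_size Standardized slopes of
#'   the HRQoL change on the designated network's exposure and cessation
#'   scores (defaults 0 and 0.8: the planted finding is a
#'   relaxation-network effect on overall HRQoL).
#' @param noise_sd_cbf Regional CBF noise SD in ml/100 g/min (default 1).
#' @param noise_sd_outcome Outcome noise SD on the HAQUAMS scale
#'   (default 0.1).
#' @param global_offset_sd SD of the participant global GM CBF offset
#'   (default 5 ml/100 g/min).
#' @param baseline_cbf Scalar mean GM CBF level (default 50 ml/100 g/min).
#' @param followup_days_range Two-element integer range of follow-up
#'   intervals (default `c(363, 1169)`).
#' @param time_slope_per_day Planted mean worsening of every scale per
#'   follow-up day (default 2e-4, about 0.18 points over a median
#'   interval).
#' @param ms_type_effect Additional worsening for SPMS participants
#'   (default 0.3).
#' @param outlier_fraction,outlier_sd Fraction of participants whose
#'   outcome noise is inflated to `outlier_sd` (defaults 0 and 2), for
#'   robustness studies.
#' @param prop_spms,prop_female Cohort composition (defaults 5/28 and
#'   18/28).
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 28, n_regions = 100,
                       n_latent_networks = 6,
                       loading_spec = c("block", "random"),
                       network_score_sd = 8, score_decay = 0.8,
                       stress_score_shift = 5,
                       target_network = 1, target_scale = "total",
                       exposure_effect_size = 0,
                       cessation_effect_size = 0.8,
                       noise_sd_cbf = 1, noise_sd_outcome = 0.1,
                       global_offset_sd = 5, baseline_cbf = 50,
                       followup_days_range = c(363L, 1169L),
                       time_slope_per_day = 2e-4, ms_type_effect = 0.3,
                       outlier_fraction = 0, outlier_sd = 2,
                       prop_spms = 5 / 28, prop_female = 18 / 28,
                       seed = 1L) {
  loading_spec <- match.arg(loading_spec)
  n_participants <- check_count(n_participants, "n_participants")
  n_regions <- check_count(n_regions, "n_regions")
  n_latent_networks <- check_count(n_latent_networks, "n_latent_networks")
  if (n_regions < n_participants) {
    abort("n_regions must be at least n_participants (the component count equals the participant count only when regions are not limiting)",
          class = "stressnets_config_error")
  }
  if (n_latent_networks > n_participants) {
    abort("cannot plant more networks than participants",
          class = "stressnets_config_error")
  }
  check_number(noise_sd_cbf, "noise_sd_cbf", lower = 0)
  check_number(noise_sd_outcome, "noise_sd_outcome", lower = 0)
  check_number(global_offset_sd, "global_offset_sd", lower = 0)
  check_number(outlier_fraction, "outlier_fraction", 0, 1)
  if (length(followup_days_range) != 2 ||
      followup_days_range[1] > followup_days_range[2]) {
    abort("followup_days_range must be c(min, max) with min <= max",
          class = "stressnets_config_error")
  }
  target_scale <- match.arg(target_scale, c("total", haquams_subscales()))
  target_network <- check_count(target_network, "target_network")
  if (target_network > n_latent_networks) {
    abort("target_network exceeds n_latent_networks",
          class = "stressnets_config_error")
  }
  structure(as.list(environment())[c(
    "n_participants", "n_regions", "n_latent_networks", "loading_spec",
    "network_score_sd", "score_decay", "stress_score_shift",
    "target_network", "target_scale", "exposure_effect_size",
    "cessation_effect_size", "noise_sd_cbf", "noise_sd_outcome",
    "global_offset_sd", "baseline_cbf", "followup_days_range",
    "time_slope_per_day", "ms_type_effect", "outlier_fraction",
    "outlier_sd", "prop_spms", "prop_female", "seed")],
    class = "sim_config")
}

# Planted loading matrix (regions x networks), orthonormal columns with
# zero column sums so per-participant GM centering leaves network signal
# untouched.
planted_loadings <- function(config) {
  p <- config$n_regions; k <- config$n_latent_networks
  if (config$loading_spec == "block") {
    L <- matrix(0, p, k)
    block <- floor(p / k)
    for (j in seq_len(k)) {
      ix <- ((j - 1) * block + 1):(j * block)
      half <- length(ix) %/% 2
      w <- c(rep(1, half), rep(-1, length(ix) - half))
      w <- w - mean(w)
      L[ix, j] <- w / sqrt(sum(w^2))
    }
  } else {
    raw <- matrix(rnorm(p * (k + 1)), p, k + 1)
    raw[, 1] <- 1  # orthogonalize against the constant => zero column sums
    L <- qr.Q(qr(raw))[, -1, drop = FALSE]
  }
  L
}

subscale_t0_means <- function() {
  c(fatigue = 2.25, lower_limb = 1.7, upper_limb = 1.2,
    social = 1.63, mood = 1.69)
}

#' Generate a complete synthetic cohort
#'
#' Draws a cohort from the generative model: per-stage regional CBF
#' matrices `X_stage = S_stage L' + g 1' + baseline + E` with
#' stage-specific latent network scores (the stress stage elevates the
#' designated network's mean; both baseline stages share the resting
#' mean), participant global offsets `g` and i.i.d. CBF noise `E`;
#' HAQUAMS scores at T0 and T1 where the change score carries the planted
#' exposure/cessation effects of the designated network, a per-day time
#' trend, an MS-type effect and Gaussian noise; covariates; and
#' psychophysiological stage data. Everything is deterministic given the
#' config's seed.
#'
#' @param config A [sim_config()].
#' @param n_missing_baseline2 Number of participants whose baseline-2
#'   stage is absent (default 0; the study had 1 of 28).
#' @return A `cohort_dataset` list: `cohort` (covariates), `stages`
#'   (tibbles `baseline1`, `stress`, `baseline2`), `outcomes` (wide score
#'   table), `psychophys` (long table), `truth` (planted parameters for
#'   recovery tests).
#' @export
simulate_cohort <- function(config = sim_config(),
                            n_missing_baseline2 = 0) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants; p <- config$n_regions
  k <- config$n_latent_networks
  ids <- sprintf("P%02d", seq_len(n))
  regions <- sprintf("region_%03d", seq_len(p))

  # covariates
  cohort <- tibble(
    participant_id = ids,
    sex = rbinom(n, 1, config$prop_female),
    age = round(runif(n, 27, 61)),
    ms_type = ifelse(runif(n) < config$prop_spms, "SPMS", "RRMS"),
    disease_duration = round(pmin(pmax(
      exp(rnorm(n, log(3491), 0.8)), 271), 12250)),
    task_load = rnorm(n),
    followup_days = round(runif(n, config$followup_days_range[1],
                                config$followup_days_range[2])))

  # latent structure
  L <- planted_loadings(config)
  score_sd <- config$network_score_sd *
    config$score_decay^(seq_len(k) - 1)
  draw_scores <- function(shift_target = 0) {
    S <- matrix(rnorm(n * k), n, k) %*% diag(score_sd, k, k)
    S[, config$target_network] <- S[, config$target_network] + shift_target
    S
  }
  S_b1 <- draw_scores()
  S_stress <- draw_scores(config$stress_score_shift)
  S_b2 <- draw_scores()
  g <- rnorm(n, 0, config$global_offset_sd)

  make_stage <- function(S) {
    E <- matrix(rnorm(n * p, 0, config$noise_sd_cbf), n, p)
    X <- S %*% t(L) + g + config$baseline_cbf + E
    colnames(X) <- regions
    activity_tibble(X, ids)
  }
  stages <- list(baseline1 = make_stage(S_b1),
                 stress = make_stage(S_stress),
                 baseline2 = make_stage(S_b2))
  if (n_missing_baseline2 > 0) {
    drop <- sample(ids, n_missing_baseline2)
    stages$baseline2 <- filter(stages$baseline2,
                               !.data$participant_id %in% drop)
  }

  # planted differential activity of the designated network
  exposure <- S_stress[, config$target_network] - S_b1[, config$target_network]
  cessation <- S_b2[, config$target_network] - S_stress[, config$target_network]
  z <- function(x) (x - mean(x)) / sd(x)

  # outcomes
  subs <- haquams_subscales()
  mu0 <- subscale_t0_means()
  t0 <- sapply(subs, function(s)
    pmin(pmax(rnorm(n, mu0[[s]], 0.5), 1), 5))
  noise_sd <- rep(config$noise_sd_outcome, n)
  if (config$outlier_fraction > 0) {
    contaminated <- runif(n) < config$outlier_fraction
    noise_sd[contaminated] <- config$outlier_sd
  }
  planted <- config$exposure_effect_size * z(exposure) +
    config$cessation_effect_size * z(cessation)
  base_trend <- config$time_slope_per_day * cohort$followup_days +
    config$ms_type_effect * (cohort$ms_type == "SPMS")
  delta <- sapply(subs, function(s) {
    eff <- if (config$target_scale %in% c("total", s)) planted else 0
    base_trend + eff + rnorm(n, 0, noise_sd)
  })
  t1 <- pmin(pmax(t0 + delta, 1), 5)
  wide <- function(m, tp) {
    out <- as_tibble(m)
    out$participant_id <- ids
    out$timepoint <- tp
    out$total <- rowMeans(m)
    out[c("participant_id", "timepoint", subs, "total")]
  }
  outcomes <- bind_rows(wide(t0, "T0"), wide(t1, "T1")) |>
    arrange(.data$participant_id, .data$timepoint)

  psychophys <- generate_psychophys(cohort)

  truth <- list(
    config = config,
    loadings = L,
    score_sd = score_sd,
    scores = list(baseline1 = S_b1, stress = S_stress, baseline2 = S_b2),
    global_offset = g,
    exposure_score = exposure,
    cessation_score = cessation,
    planted_outcome_effect = planted,
    base_trend = base_trend)

  structure(list(cohort = cohort, stages = stages, outcomes = outcomes,
                 psychophys = psychophys, truth = truth),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "<cohort_dataset> %d participants x %d regions, %d latent networks (seed %d)\n",
    cfg$n_participants, cfg$n_regions, cfg$n_latent_networks, cfg$seed))
  cat(sprintf("  planted effects: exposure %.2f, cessation %.2f on %s\n",
              cfg$exposure_effect_size, cfg$cessation_effect_size,
              cfg$target_scale))
  invisible(x)
}

#' Generate psychophysiological stage data
#'
#' Perceived-stress ratings on the 9-point scale at the four rating stages
#' (I, III, V, VII) and pulse rates at the three fMRI stages (II, IV, VI),
#' with a planted increase under stress and a decrease after its
#' cessation, participant random intercepts and occasion noise. Ratings
#' are generated on a latent continuous scale, then rounded and clipped to
#' 1--9. Pulse can be made missing for a subset of participants
#' (missing completely at random), mirroring the study's 21-of-28
#' availability.
#'
#' @param cohort Covariate table with `participant_id` (only the ids are
#'   used).
#' @param rating_means Named stage means for ratings (stages I, III, V,
#'   VII).
#' @param pulse_means Named stage means for pulse in bpm (stages II, IV,
#'   VI); must be positive.
#' @param participant_sd Named SDs of the participant random intercepts
#'   (`rating`, `pulse`).
#' @param noise_sd Named occasion noise SDs (`rating`, `pulse`).
#' @param n_missing_pulse Participants without pulse data; default scales
#'   the study's 7-of-28 proportionally.
#' @param seed Optional seed (omit when called inside [simulate_cohort()],
#'   which already seeds the stream).
#' @return Long tibble: `participant_id`, `stage`, `parameter`, `value`.
#' @export
generate_psychophys <- function(cohort,
                                rating_means = c(I = 2.5, III = 2.5,
                                                 V = 4.5, VII = 2),
                                pulse_means = c(II = 70, IV = 80, VI = 68),
                                participant_sd = c(rating = 1, pulse = 8),
                                noise_sd = c(rating = 0.8, pulse = 3),
                                n_missing_pulse = NULL, seed = NULL) {
  if (any(pulse_means <= 0)) {
    abort("pulse stage means must be positive",
          class = "stressnets_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- cohort$participant_id
  n <- length(ids)
  if (is.null(n_missing_pulse)) n_missing_pulse <- round(n * 7 / 28)
  b_rating <- rnorm(n, 0, participant_sd[["rating"]])
  b_pulse <- rnorm(n, 0, participant_sd[["pulse"]])
  ratings <- purrr::imap_dfr(rating_means, function(mu, st) {
    latent <- mu + b_rating + rnorm(n, 0, noise_sd[["rating"]])
    tibble(participant_id = ids, stage = st, parameter = "rating",
           value = pmin(pmax(round(latent), 1), 9))
  })
  pulse <- purrr::imap_dfr(pulse_means, function(mu, st) {
    tibble(participant_id = ids, stage = st, parameter = "pulse",
           value = pmax(mu + b_pulse + rnorm(n, 0, noise_sd[["pulse"]]),
                        1))
  })
  if (n_missing_pulse > 0) {
    miss <- sample(ids, n_missing_pulse)
    pulse <- filter(pulse, !.data$participant_id %in% miss)
  }
  bind_rows(ratings, pulse) |>
    arrange(.data$parameter, .data$stage, .data$participant_id)
}

#' Generate item-level HAQUAMS responses consistent with subscale scores
#'
#' Produces an integer item table (long format) whose per-subscale means
#' approximate the given subscale scores, for exercising the item-level
#' scoring path.
#'
#' @param scores Wide score table (`participant_id`, `timepoint`,
#'   subscale columns).
#' @param item_sd SD of the latent item deviation around the subscale
#'   score.
#' @param seed Optional seed.
#' @return Long tibble: `participant_id`, `timepoint`, `subscale`,
#'   `item_index`, `value` (integers 1--5).
#' @export
simulate_haquams_items <- function(scores, item_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- haquams_item_counts()
  long <- tidyr::pivot_longer(
    scores[c("participant_id", "timepoint", names(counts))],
    cols = all_of(names(counts)),
    names_to = "subscale", values_to = "score")
  purrr::pmap_dfr(long, function(participant_id, timepoint, subscale,
                                 score) {
    m <- counts[[subscale]]
    tibble(participant_id = participant_id, timepoint = timepoint,
           subscale = subscale, item_index = seq_len(m),
           value = as.integer(pmin(pmax(round(
             score + rnorm(m, 0, item_sd)), 1), 5)))
  })
}

#' Write a cohort dataset to disk
#'
#' Writes the covariate table, outcomes and psychophysiological data as
#' UTF-8 CSV with header row, the three stage matrices as CSV with regions
#' as columns, and the planted-truth record as a JSON sidecar.
#'
#' @param dataset A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(dataset$cohort, file.path(dir, "cohort.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(dataset$outcomes, file.path(dir, "outcomes.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(dataset$psychophys, file.path(dir, "psychophys.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  for (st in names(dataset$stages)) {
    write.csv(dataset$stages[[st]],
              file.path(dir, paste0("stage_", st, ".csv")),
              row.names = FALSE, fileEncoding = "UTF-8")
  }
  truth <- dataset$truth
  truth$config <- unclass(truth$config)
  truth$loadings <- NULL  # large; reconstructable from config + seed
  truth$scores <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
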