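# Screening of clinico-demographic markers and the key network->HRQoL
# prediction analysis.

# Encode a two-level character/factor/logical column as 0/1 for the design
# matrix; numeric columns pass through.
encode_numeric <- function(x, name) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  lev <- sort(unique(as.character(x[!is.na(x)])))
  if (length(lev) > 2) {
    abort(sprintf("column '%s' has more than two levels", name))
  }
  as.numeric(match(as.character(x), lev) - 1)
}

#' Screen clinico-demographic and radiographic markers
#'
#' Tests the prognostic value of each marker for the longitudinal change in
#' overall HRQoL in a separate robust regression per marker, with the T0
#' total score and the follow-up interval in days (plus intercept) as
#' nuisance covariates. Inference is by the permutation Wald test;
#' significance is judged two-sided at `alpha` without multiplicity
#' correction (each marker answers its own substantive question).
#'
#' @param data A data frame with one row per participant containing the
#'   response, nuisance and marker columns. Two-level character/factor
#'   markers (e.g. MS type) are dummy-coded 0/1.
#' @param markers Character vector of marker column names (the study
#'   screened nine: sex, age, education, clinical disability, annualized
#'   relapse rate, T2 lesion load, MS type, disease duration, GM fraction).
#' @param response Column with the HRQoL change score (default
#'   `"delta_total"`).
#' @param t0,interval Nuisance columns: T0 total score and follow-up days.
#' @param n_perm Permutations per marker.
#' @param seed Integer seed for the permutation draws.
#' @param alpha Two-sided significance level per marker.
#' @return A tibble with one row per marker: estimate, Wald statistic,
#'   signed t-equivalent, permutation p-value and significance flag.
#' @export
screen_markers <- function(data, markers,
                           response = "delta_total",
                           t0 = "total_t0", interval = "followup_days",
                           n_perm = 10000, seed = NULL, alpha = 0.05) {
  missing_cols <- setdiff(c(markers, response, t0, interval), names(data))
  if (length(missing_cols)) {
    abort(paste("missing marker/covariate columns:",
                paste(missing_cols, collapse = ", ")),
          class = "stressnets_schema_error")
  }
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(markers, function(mk) {
    d <- data
    d[[mk]] <- encode_numeric(d[[mk]], mk)
    res <- permutation_pvalue(d, response, mk, nuisance = c(t0, interval),
                              n_perm = n_perm)
    tidy(res) |>
      mutate(marker = mk, significant = .data$p_permutation < alpha) |>
      select(all_of(c("marker", "estimate", "wald", "t_equivalent",
                      "p_permutation", "significant", "n",
                      "n_permutations")))
  })
}

#' Predict HRQoL change from differential network activity
#'
#' The key analysis: for each neural process (stress exposure, stress
#' cessation), each latent network and each requested HAQUAMS scale, a
#' robust regression of the longitudinal change score on the differential
#' network activity with nuisance covariates (intercept, T0 score of that
#' scale, follow-up days, cognitive task load, disease type) and a
#' permutation Wald p-value. Family-wise error is controlled by Bonferroni
#' across the networks within each process-by-scale family: the total score
#' is tested at `alpha_fwe_primary` (default 0.05) and the subscales at
#' `alpha_fwe_subscale` (default 0.1). Participants without baseline-2
#' scores drop out of cessation analyses only; degenerate (zero-variance)
#' differential columns are reported as non-testable cells.
#'
#' @param differentials A [differential_activity()] object.
#' @param outcomes Wide score table with rows per participant and timepoint
#'   (columns `participant_id`, `timepoint`, subscales, `total`), as
#'   produced by [score_haquams()] or [simulate_cohort()].
#' @param cohort Per-participant covariate table with `participant_id`,
#'   `followup_days`, `task_load` and `ms_type`.
#' @param scales Scales to analyse; default the total plus all five
#'   subscales.
#' @param n_perm Permutations per cell.
#' @param seed Integer seed.
#' @param alpha_fwe_primary,alpha_fwe_subscale Family-wise thresholds for
#'   the total-score and subscale families.
#' @param sequential_h Optional Besag-Clifford early-stopping count passed
#'   to [permutation_pvalue()]; 0 (default) runs every permutation.
#' @return A tibble of class `hrql_prediction` with one row per
#'   process x network x scale: estimate, `wald`, `t_equivalent`,
#'   `p_permutation`, `p_fwe`, `significant`, `n`, `note`.
#' @export
predict_hrql_from_networks <- function(differentials, outcomes, cohort,
                                       scales = c("total",
                                                  haquams_subscales()),
                                       n_perm = 10000, seed = NULL,
                                       alpha_fwe_primary = 0.05,
                                       alpha_fwe_subscale = 0.1,
                                       sequential_h = 0) {
  stopifnot(inherits(differentials, "differential_activity"))
  check_number(alpha_fwe_primary, "alpha_fwe_primary", 1e-12, 1 - 1e-12)
  check_number(alpha_fwe_subscale, "alpha_fwe_subscale", 1e-12, 1 - 1e-12)
  nets <- differentials$networks
  m <- length(nets)
  deltas <- haquams_deltas(outcomes)
  t0_scores <- filter(outcomes, .data$timepoint == "T0") |>
    select(all_of(c("participant_id", scales))) |>
    rename_with_suffix(scales, "_t0")
  cov <- cohort |>
    select(all_of(c("participant_id", "followup_days", "task_load",
                    "ms_type"))) |>
    mutate(ms_type = encode_numeric(.data$ms_type, "ms_type"))
  base <- deltas |>
    left_join(t0_scores, by = "participant_id") |>
    left_join(cov, by = "participant_id")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (process in c("exposure", "cessation")) {
    scores <- differentials[[process]]
    for (scale_name in scales) {
      alpha_fwe <- if (scale_name == "total") alpha_fwe_primary
                   else alpha_fwe_subscale
      for (net in nets) {
        d <- base |>
          left_join(scores[c("participant_id", net)],
                    by = "participant_id")
        cell <- tryCatch(
          permutation_pvalue(
            d, response = paste0("delta_", scale_name), predictor = net,
            nuisance = c(paste0(scale_name, "_t0"), "followup_days",
                         "task_load", "ms_type"),
            n_perm = n_perm, sequential_h = sequential_h),
          stressnets_design_error = function(e) NULL)
        rows[[length(rows) + 1L]] <- if (is.null(cell)) {
          tibble(process = process, network = net, scale = scale_name,
                 estimate = NA_real_, wald = NA_real_,
                 t_equivalent = NA_real_, p_permutation = NA_real_,
                 n = NA_integer_, alpha_fwe = alpha_fwe,
                 note = "non-testable: degenerate design")
        } else {
          tibble(process = process, network = net, scale = scale_name,
                 estimate = cell$estimate, wald = cell$wald,
                 t_equivalent = cell$t_equivalent,
                 p_permutation = cell$p_permutation,
                 n = cell$n, alpha_fwe = alpha_fwe, note = NA_character_)
        }
      }
    }
  }
  out <- bind_rows(rows) |>
    mutate(p_fwe = pmin(1, m * .data$p_permutation),
           significant = !is.na(.data$p_fwe) & .data$p_fwe < .data$alpha_fwe,
           n_permutations = n_perm, n_networks = m, seed = seed %||% NA_integer_)
  class(out) <- c("hrql_prediction", class(out))
  out
}

rename_with_suffix <- function(tbl, cols, suffix) {
  names(tbl)[match(cols, names(tbl))] <- paste0(cols, suffix)
  tbl
}
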