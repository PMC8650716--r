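#' HAQUAMS subscale item counts
#'
#' The Hamburg Quality of Life Questionnaire in Multiple Sclerosis (HAQUAMS)
#' has five subscales with fixed item counts: fatigue (4), lower limb
#' mobility (5), upper limb mobility (5), social functions (6) and
#' mood-related symptoms (8). Items are rated on an ordinal 1--5 scale where
#' higher values indicate worse HRQoL.
#'
#' @return A named integer vector of item counts per subscale.
#' @export
#' @examples
#' haquams_item_counts()
haquams_item_counts <- function() {
  c(fatigue = 4L, lower_limb = 5L, upper_limb = 5L,
    social = 6L, mood = 8L)
}

haquams_subscales <- function() names(haquams_item_counts())

#' Score one HAQUAMS subscale
#'
#' A subscale score is the unweighted mean of its item responses. The item
#' count must match the instrument's definition for that subscale and all
#' responses must lie in \[1, 5\]. Any missing item renders the subscale
#' missing (no imputation).
#'
#' @param items Numeric vector of item responses (ordinal 1--5).
#' @param subscale One of `"fatigue"`, `"lower_limb"`, `"upper_limb"`,
#'   `"social"`, `"mood"`.
#' @return The subscale score, a number in \[1, 5\] (or `NA` if any item is
#'   missing).
#' @export
#' @examples
#' score_subscale(c(2, 3, 4, 3), "fatigue")  # 3
score_subscale <- function(items, subscale) {
  counts <- haquams_item_counts()
  subscale <- match.arg(subscale, names(counts))
  if (length(items) != counts[[subscale]]) {
    abort(sprintf(
      "subscale '%s' requires %d items, got %d",
      subscale, counts[[subscale]], length(items)),
      class = "stressnets_schema_error")
  }
  if (any(!is.na(items) & (items < 1 | items > 5))) {
    abort("item responses must lie in [1, 5]",
          class = "stressnets_validation_error")
  }
  if (anyNA(items)) return(NA_real_)
  mean(items)
}

#' HAQUAMS total score
#'
#' The total score for overall HRQoL is the arithmetic mean across the five
#' subscale scores. Low scores indicate high HRQoL.
#'
#' @param subscale_scores Numeric vector of exactly five subscale scores.
#' @return The total score.
#' @export
#' @examples
#' total_score(c(2, 3, 1, 4, 5))  # 3
total_score <- function(subscale_scores) {
  if (length(subscale_scores) != 5) {
    abort("exactly five subscale scores are required",
          class = "stressnets_schema_error")
  }
  mean(subscale_scores)
}

#' Longitudinal HAQUAMS change score
#'
#' Change between the follow-up and baseline visits, `T1 - T0`. Because
#' higher HAQUAMS scores correspond to lower HRQoL, positive changes denote
#' worsening.
#'
#' @param score_t1,score_t0 Scores at follow-up (T1) and baseline (T0).
#' @return `score_t1 - score_t0`.
#' @export
#' @examples
#' delta_score(1.94, 1.77)  # 0.17, a slight worsening
delta_score <- function(score_t1, score_t0) {
  if (anyNA(score_t1) || anyNA(score_t0)) {
    abort("both timepoints must be present to compute a change score",
          class = "stressnets_missing_error")
  }
  score_t1 - score_t0
}

#' Score a long table of HAQUAMS item responses
#'
#' Takes item-level responses in long format and returns one row per
#' participant and timepoint with the five subscale scores and the total.
#' Item counts are validated per subscale; a subscale with any missing item
#' is scored `NA` and its total is then `NA` too.
#'
#' @param items A data frame with columns `participant_id`, `timepoint`
#'   (`"T0"`/`"T1"`), `subscale`, `item_index`, `value`.
#' @return A tibble with columns `participant_id`, `timepoint`, the five
#'   subscale scores, and `total`.
#' @export
score_haquams <- function(items) {
  required <- c("participant_id", "timepoint", "subscale", "item_index",
                "value")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
          class = "stressnets_schema_error")
  }
  if (!all(items$subscale %in% haquams_subscales())) {
    abort("unknown subscale name", class = "stressnets_schema_error")
  }
  scored <- items |>
    group_by(.data$participant_id, .data$timepoint, .data$subscale) |>
    summarise(score = score_subscale(
      .data$value[order(.data$item_index)],
      .data$subscale[[1]]), .groups = "drop")
  wide <- tidyr::pivot_wider(scored, names_from = "subscale",
                             values_from = "score")
  missing_sub <- setdiff(haquams_subscales(), names(wide))
  if (length(missing_sub)) {
    abort(paste("subscale(s) absent from input:",
                paste(missing_sub, collapse = ", ")),
          class = "stressnets_schema_error")
  }
  wide |>
    mutate(total = purrr::pmap_dbl(
      across(all_of(haquams_subscales())),
      ~ total_score(c(...)))) |>
    select(all_of(c("participant_id", "timepoint", haquams_subscales(),
                    "total"))) |>
    arrange(.data$participant_id, .data$timepoint)
}

#' Longitudinal change table from scored HAQUAMS data
#'
#' Computes `T1 - T0` per participant for the total score and each subscale.
#'
#' @param scores A wide score table as returned by [score_haquams()] or the
#'   `outcomes` element of [simulate_cohort()].
#' @return A tibble with one row per participant and one `delta_*` column
#'   per scale.
#' @export
haquams_deltas <- function(scores) {
  scales <- c(haquams_subscales(), "total")
  have <- intersect(scales, names(scores))
  t0 <- filter(scores, .data$timepoint == "T0")
  t1 <- filter(scores, .data$timepoint == "T1")
  joined <- left_join(t0, t1, by = "participant_id",
                      suffix = c("_t0", "_t1"))
  if (anyNA(joined[paste0(have, "_t1")])) {
    abort("participants missing the T1 visit",
          class = "stressnets_missing_error")
  }
  out <- tibble(participant_id = joined$participant_id)
  for (s in have) {
    out[[paste0("delta_", s)]] <-
      delta_score(joined[[paste0(s, "_t1")]], joined[[paste0(s, "_t0")]])
  }
  out
}
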