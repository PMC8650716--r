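# End-to-end orchestration: simulate -> networks -> predict -> lmm ->
# report, fully seeded and logged.

#' Pipeline configuration
#'
#' Bundles the simulation config, permutation counts, family-wise
#' thresholds and per-stage seeds for [run_pipeline()]. Every stochastic
#' stage has its own recorded seed so any number in the report can be
#' reproduced.
#'
#' @param sim A [sim_config()] for the synthetic cohort.
#' @param n_perm Permutations per test (default 10000).
#' @param alpha_fwe_primary Family-wise alpha for the total score
#'   (default 0.05).
#' @param alpha_fwe_subscale Family-wise alpha for the subscales
#'   (default 0.1).
#' @param alpha Per-test alpha for the psychophysiological and
#'   longitudinal analyses (default 0.05).
#' @param scales HAQUAMS scales analysed in the network prediction step.
#' @param seed_predict,seed_lmm Seeds for the permutation stages.
#' @param n_missing_baseline2 Participants lacking the baseline-2 stage.
#' @param out_dir Optional directory; when set, result tables are written
#'   as CSV and the provenance as JSON.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), n_perm = 10000,
                            alpha_fwe_primary = 0.05,
                            alpha_fwe_subscale = 0.1, alpha = 0.05,
                            scales = c("total", haquams_subscales()),
                            seed_predict = 2001L, seed_lmm = 2002L,
                            n_missing_baseline2 = 0, out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  check_number(alpha_fwe_primary, "alpha_fwe_primary", 1e-12, 1 - 1e-12)
  check_number(alpha_fwe_subscale, "alpha_fwe_subscale", 1e-12, 1 - 1e-12)
  check_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  check_count(n_perm, "n_perm")
  structure(list(sim = sim, n_perm = n_perm,
                 alpha_fwe_primary = alpha_fwe_primary,
                 alpha_fwe_subscale = alpha_fwe_subscale, alpha = alpha,
                 scales = scales, seed_predict = seed_predict,
                 seed_lmm = seed_lmm,
                 n_missing_baseline2 = n_missing_baseline2,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation; per-participant GM centering of
#' the three stage matrices; network extraction from the stress stage;
#' projection of both baselines; differential activity; the network ->
#' HRQoL-change prediction with permutation Wald tests and Bonferroni
#' control; the four psychophysiological stage contrasts; and the
#' longitudinal HRQoL tests. Any stage failure halts with a diagnostic
#' naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` (see [make_report()]).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }
  dataset <- stage("simulate",
    simulate_cohort(config$sim,
                    n_missing_baseline2 = config$n_missing_baseline2))
  centered <- stage("center", lapply(dataset$stages, gm_center))
  model <- stage("networks", fit_networks(centered$stress))
  diffs <- stage("differential", differential_activity(
    project_stage(centered$baseline1, model),
    model_scores_tibble(model),
    project_stage(centered$baseline2, model)))
  predictions <- stage("predict", predict_hrql_from_networks(
    diffs, dataset$outcomes, dataset$cohort, scales = config$scales,
    n_perm = config$n_perm, seed = config$seed_predict,
    alpha_fwe_primary = config$alpha_fwe_primary,
    alpha_fwe_subscale = config$alpha_fwe_subscale))
  contrasts <- stage("lmm_stages", stage_contrasts(
    dataset$psychophys, dataset$cohort, n_perm = config$n_perm,
    seed = config$seed_lmm, alpha = config$alpha))
  longitudinal <- stage("lmm_longitudinal", longitudinal_change(
    dataset$outcomes, dataset$cohort, n_perm = config$n_perm,
    seed = config$seed_lmm + 1L, alpha = config$alpha))
  report <- make_report(
    predictions = predictions, contrasts = contrasts,
    longitudinal = longitudinal, model = model, config = config)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

model_scores_tibble <- function(model) {
  activity_tibble(model$scores, model$participants)
}

#' Assemble a run report from result tables
#'
#' Collects the result tables with provenance (seeds, problem sizes,
#' Bonferroni thresholds, package version) into a `run_report` whose print
#' method gives a human-readable summary. Regeneration from the same
#' tables is idempotent.
#'
#' @param predictions Network prediction table from
#'   [predict_hrql_from_networks()] (may be `NULL`).
#' @param contrasts Stage-contrast table from [stage_contrasts()].
#' @param longitudinal Longitudinal table from [longitudinal_change()].
#' @param model The fitted [fit_networks()] model.
#' @param config The [pipeline_config()] used.
#' @return A `run_report` list with `tables`, `provenance` and
#'   `thresholds`.
#' @export
make_report <- function(predictions = NULL, contrasts = NULL,
                        longitudinal = NULL, model = NULL,
                        config = NULL) {
  m <- if (!is.null(predictions)) predictions$n_networks[1]
       else if (!is.null(model)) ncol(model$loadings) else NA_integer_
  thresholds <- if (!is.na(m) && !is.null(config)) {
    tibble(family = c("total", "subscales"),
           alpha_fwe = c(config$alpha_fwe_primary,
                         config$alpha_fwe_subscale),
           n_tests = m,
           alpha_per_test = round(
             c(bonferroni_threshold(config$alpha_fwe_primary, m),
               bonferroni_threshold(config$alpha_fwe_subscale, m)), 4))
  } else tibble()
  structure(list(
    tables = list(predictions = predictions, contrasts = contrasts,
                  longitudinal = longitudinal),
    thresholds = thresholds,
    provenance = list(
      package_version = as.character(utils::packageVersion("stressnets")),
      config = config,
      n_networks = m,
      generated = if (!is.null(config)) config$sim$seed else NA)
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== stressnets run report ==\n")
  if (nrow(x$thresholds)) {
    cat("Bonferroni per-test thresholds:\n")
    for (i in seq_len(nrow(x$thresholds))) {
      cat(sprintf("  %s family: alpha_FWE = %g over %d networks -> %.4f\n",
                  x$thresholds$family[i], x$thresholds$alpha_fwe[i],
                  x$thresholds$n_tests[i], x$thresholds$alpha_per_test[i]))
    }
  }
  pred <- x$tables$predictions
  if (!is.null(pred)) {
    sig <- filter(pred, .data$significant)
    cat(sprintf("Network prediction: %d cells tested (n = %s participants)\n",
                nrow(pred), paste(unique(stats::na.omit(pred$n)),
                                  collapse = "/")))
    if (nrow(sig)) {
      for (i in seq_len(nrow(sig))) {
        cat(sprintf("  %s x %s x %s: t = %.2f, p_FWE = %.4g\n",
                    sig$process[i], sig$network[i], sig$scale[i],
                    sig$t_equivalent[i], sig$p_fwe[i]))
      }
    } else cat("  no significant network effects\n")
  }
  for (nm in c("contrasts", "longitudinal")) {
    tbl <- x$tables[[nm]]
    if (is.null(tbl)) next
    sig <- filter(tbl, .data$significant)
    cat(sprintf("%s: %d/%d significant\n", nm, nrow(sig), nrow(tbl)))
  }
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    tbl <- report$tables[[nm]]
    if (is.null(tbl)) next
    write.csv(tbl, file.path(dir, paste0(nm, ".csv")), row.names = FALSE,
              fileEncoding = "UTF-8")
  }
  prov <- report$provenance
  if (!is.null(prov$config)) {
    prov$config <- unclass(prov$config)
    prov$config$sim <- unclass(prov$config$sim)
  }
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
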