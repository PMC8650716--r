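# Latent stress-network extraction from regional CBF.
#
# Regional activity tables are tibbles with a `participant_id` column and
# one numeric column per atlas region (participants as rows).

activity_matrix <- function(tbl) {
  if (!"participant_id" %in% names(tbl)) {
    abort("regional activity tables need a `participant_id` column",
          class = "stressnets_schema_error")
  }
  m <- as.matrix(tbl[setdiff(names(tbl), "participant_id")])
  if (!is.numeric(m)) abort("region columns must be numeric")
  rownames(m) <- as.character(tbl$participant_id)
  m
}

activity_tibble <- function(m, participant_id) {
  bind_cols(tibble(participant_id = participant_id),
            as_tibble(m, .name_repair = "minimal"))
}

#' Mean regional CBF from a voxel image
#'
#' Averages in-mask voxel values within each region of a labeled
#' parcellation, the standard region-of-interest reduction of a CBF map.
#' Regions whose intersection with the mask is empty are dropped with a
#' warning.
#'
#' @param image Numeric 3D array of voxel CBF (ml/100 g/min).
#' @param parcellation Integer 3D array of region labels (0 = background).
#' @param mask Logical 3D array restricting the computation, e.g. from
#'   [build_gm_mask()]. Defaults to all voxels.
#' @return A tibble with columns `region` and `mean_cbf`.
#' @export
region_means <- function(image, parcellation, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  check_same_grid(list(dim(image), dim(parcellation), dim(mask)))
  keep <- mask & parcellation != 0
  labs <- parcellation[keep]
  vals <- image[keep]
  all_regions <- sort(unique(parcellation[parcellation != 0]))
  means <- tapply(vals, factor(labs, levels = all_regions), mean)
  dropped <- all_regions[is.na(means)]
  if (length(dropped)) {
    warn(sprintf("%d region(s) have no in-mask voxels and were dropped",
                 length(dropped)))
  }
  tibble(region = all_regions[!is.na(means)],
         mean_cbf = as.numeric(means[!is.na(means)]))
}

#' Center regional CBF by each participant's global gray-matter mean
#'
#' Subtracts from every participant's row its mean across regions (the
#' participant's average overall GM CBF), separately per fMRI stage. This
#' removes global perfusion offsets so that components reflect regional
#' covariation, not global level.
#'
#' @param tbl Regional activity tibble (`participant_id` + region columns),
#'   no missing cells.
#' @return A tibble of the same shape with zero row means; the subtracted
#'   per-participant means are attached as attribute `"centering"`.
#' @export
gm_center <- function(tbl) {
  m <- activity_matrix(tbl)
  if (anyNA(m)) {
    abort("regional activity must not contain missing cells",
          class = "stressnets_validation_error")
  }
  mu <- rowMeans(m)
  out <- activity_tibble(m - mu, tbl$participant_id)
  attr(out, "centering") <- tibble(participant_id = tbl$participant_id,
                                   gm_mean = unname(mu))
  out
}

#' Extract latent neural networks from the centered stress-stage CBF
#'
#' Singular-value decomposition of the participant-centered stress-stage
#' matrix. No additional region-wise (column) centering is applied, so the
#' number of components equals the number of participants whenever there
#' are at least as many regions as participants; each component is treated
#' as one neural network, its loading vector describing how strongly each
#' region participates and its score giving the per-participant network
#' activity. Loading vectors are orthonormal and oriented so that the
#' largest-magnitude loading is positive.
#'
#' @param centered Centered stress-stage table from [gm_center()].
#' @return A `network_model` object with elements `loadings` (regions x
#'   components), `scores` (participants x components), `singular_values`,
#'   `explained_variation`, `participants`, `regions`.
#' @export
fit_networks <- function(centered) {
  m <- activity_matrix(centered)
  n <- nrow(m); p <- ncol(m)
  if (p < n) {
    abort(sprintf(
      "need at least as many regions (%d) as participants (%d)", p, n),
      class = "stressnets_config_error")
  }
  sv <- svd(m, nu = n, nv = n)
  # fix the arbitrary SVD sign: largest-|loading| entry positive
  flip <- apply(sv$v, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v, 2, flip, `*`)
  scores <- sweep(sv$u %*% diag(sv$d, n, n), 2, flip, `*`)
  nets <- paste0("net_", seq_len(n))
  dimnames(loadings) <- list(colnames(m), nets)
  dimnames(scores) <- list(rownames(m), nets)
  structure(list(
    loadings = loadings,
    scores = scores,
    singular_values = sv$d[seq_len(n)],
    explained_variation = sv$d[seq_len(n)]^2 / sum(sv$d^2),
    participants = centered$participant_id,
    regions = colnames(m)
  ), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d networks from %d participants x %d regions\n",
              ncol(x$loadings), nrow(x$scores), nrow(x$loadings)))
  cat(sprintf("  leading components explain %.1f%% / %.1f%% / %.1f%% of variation\n",
              100 * x$explained_variation[1],
              100 * x$explained_variation[2],
              100 * x$explained_variation[3]))
  invisible(x)
}

#' Project a centered stage onto the stress-stage networks
#'
#' Computes per-participant network activity scores for a baseline stage by
#' projecting its centered regional signals onto the stress-stage loading
#' vectors. Projecting the stress stage itself returns the model's own
#' scores.
#'
#' @param centered Centered stage table from [gm_center()].
#' @param model A [fit_networks()] model.
#' @return A tibble: `participant_id` plus one column per network.
#' @export
project_stage <- function(centered, model) {
  m <- activity_matrix(centered)
  if (!identical(colnames(m), model$regions)) {
    abort("stage regions do not match the network model",
          class = "stressnets_alignment_error")
  }
  scores <- m %*% model$loadings
  activity_tibble(scores, centered$participant_id)
}

#' Differential network activity for stress exposure and cessation
#'
#' Stress exposure is the change in network activity from baseline 1 to the
#' stress stage; stress cessation (relaxation) is the change from the
#' stress stage to baseline 2. Participants absent from the baseline-2
#' scores get missing cessation values and are dropped from
#' cessation-based analyses downstream.
#'
#' @param scores_b1,scores_stress,scores_b2 Score tables
#'   (`participant_id` + network columns) from [project_stage()];
#'   `scores_b2` may lack some participants.
#' @return A `differential_activity` object: list of tibbles `exposure` and
#'   `cessation` (participants x networks).
#' @export
differential_activity <- function(scores_b1, scores_stress, scores_b2) {
  nets <- setdiff(names(scores_stress), "participant_id")
  if (!identical(setdiff(names(scores_b1), "participant_id"), nets)) {
    abort("network columns differ across stages",
          class = "stressnets_alignment_error")
  }
  if (!identical(scores_b1$participant_id, scores_stress$participant_id)) {
    abort("participants differ between baseline 1 and stress",
          class = "stressnets_alignment_error")
  }
  exposure <- scores_stress
  exposure[nets] <- scores_stress[nets] - scores_b1[nets]
  b2 <- left_join(scores_stress["participant_id"], scores_b2,
                  by = "participant_id")
  cessation <- scores_stress
  cessation[nets] <- b2[nets] - scores_stress[nets]
  structure(list(exposure = exposure, cessation = cessation,
                 networks = nets),
            class = "differential_activity")
}

#' @export
print.differential_activity <- function(x, ...) {
  cat(sprintf("<differential_activity> %d participants x %d networks",
              nrow(x$exposure), length(x$networks)),
      sprintf("(%d with baseline 2)\n",
              sum(complete.cases(x$cessation))))
  invisible(x)
}

#' Winner-takes-all region-to-network assignment
#'
#' Assigns each atlas region to the network for which its loading has
#' maximal absolute value (the sign encodes direction, not strength of
#' membership). Exact ties resolve to the lower component index.
#'
#' @param model A [fit_networks()] model, or a loadings matrix (regions x
#'   networks).
#' @param signed If `TRUE`, use the signed rather than absolute maximum.
#' @return A tibble with columns `region`, `network` (column index) and
#'   `loading` (the winning loading, signed).
#' @export
winner_takes_all <- function(model, signed = FALSE) {
  loadings <- if (inherits(model, "network_model")) model$loadings else model
  if (!all(is.finite(loadings))) abort("loadings must be finite")
  crit <- if (signed) loadings else abs(loadings)
  win <- apply(crit, 1, which.max)
  tibble(region = rownames(loadings) %||% as.character(seq_len(nrow(loadings))),
         network = as.integer(win),
         loading = loadings[cbind(seq_len(nrow(loadings)), win)])
}

#' @export
tidy.network_model <- function(x, ...) {
  tibble(network = seq_along(x$singular_values),
         singular_value = x$singular_values,
         explained_variation = x$explained_variation)
}

#' @export
glance.network_model <- function(x, ...) {
  tibble(n_participants = nrow(x$scores),
         n_regions = nrow(x$loadings),
         n_networks = ncol(x$loadings),
         top_explained_variation = x$explained_variation[1])
}
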