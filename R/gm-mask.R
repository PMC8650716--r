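# Lesion-aware gray-matter group mask construction.
#
# Voxel maps are plain 3D arrays on a shared grid. Tissue stacks are lists
# with one element per participant, each a named list of GM/WM/CSF
# probability arrays.

check_same_grid <- function(dims) {
  dims <- unique(dims)
  if (length(dims) != 1) {
    abort("all voxel maps must share the same grid",
          class = "stressnets_alignment_error")
  }
  invisible(dims[[1]])
}

grid_dims <- function(maps) {
  check_same_grid(lapply(maps, dim))
}

#' Assign voxels to the tissue class with maximal mean probability
#'
#' Averages GM, WM and CSF probability maps across participants and labels
#' each voxel with the tissue whose across-participant mean probability is
#' maximal. Ties are broken in the priority order GM > WM > CSF, reflecting
#' that the downstream analysis targets gray matter.
#'
#' @param stack A list with one element per participant; each element is a
#'   named list of 3D arrays `gm`, `wm`, `csf` with probabilities in
#'   \[0, 1\] on a common grid.
#' @return An integer 3D array with values 1 (GM), 2 (WM), 3 (CSF), carrying
#'   a `"tissues"` attribute naming the levels.
#' @export
tissue_argmax <- function(stack) {
  if (length(stack) < 1) abort("need at least one participant")
  maps <- unlist(stack, recursive = FALSE)
  dims <- grid_dims(maps)
  rng <- range(unlist(lapply(maps, range)))
  if (rng[1] < 0 || rng[2] > 1) {
    abort("tissue probabilities must lie in [0, 1]",
          class = "stressnets_validation_error")
  }
  mean_of <- function(tissue) {
    Reduce(`+`, lapply(stack, `[[`, tissue)) / length(stack)
  }
  gm <- mean_of("gm"); wm <- mean_of("wm"); csf <- mean_of("csf")
  # ties resolve to the earlier class: GM > WM > CSF
  lab <- array(3L, dims)
  lab[wm >= csf] <- 2L
  lab[gm >= wm & gm >= csf] <- 1L
  attr(lab, "tissues") <- c("gm", "wm", "csf")
  lab
}

# Logical OR of per-patient lesion maps, then 6-connected dilation.
dilate_face6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, axis, by) {
    res <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1L) {
      idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1)
    } else {
      idx_dst[[axis]] <- 1:(d[axis] - 1); idx_src[[axis]] <- 2:d[axis]
    }
    res[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    res
  }
  for (axis in 1:3) {
    if (d[axis] < 2) next
    out <- out | shift(mask, axis, 1L) | shift(mask, axis, -1L)
  }
  out
}

#' Remove lesioned voxels and their face neighbors from a mask
#'
#' Voxels lesioned in at least one patient are removed, together with their
#' six face-adjacent neighbors (Euclidean distance exactly one voxel in
#' index space) to guard against partial-volume effects. Diagonal neighbors
#' (distance sqrt(2) or sqrt(3)) are retained. Out-of-bounds neighbors are
#' ignored.
#'
#' @param gm_mask Logical 3D array of candidate gray-matter voxels.
#' @param lesion_masks List of logical 3D arrays, one per patient.
#' @return A logical 3D array: `gm_mask` with the lesion neighborhood
#'   removed. The count of removed voxels is attached as attribute
#'   `"n_removed"`.
#' @export
lesion_exclusion <- function(gm_mask, lesion_masks) {
  check_same_grid(c(list(dim(gm_mask)), lapply(lesion_masks, dim)))
  any_lesion <- Reduce(`|`, lesion_masks)
  excluded <- dilate_face6(any_lesion)
  out <- gm_mask & !excluded
  attr(out, "n_removed") <- sum(gm_mask & excluded)
  out
}

#' Intersect a mask with fMRI coverage of all participants
#'
#' Retains only voxels covered by every fMRI scan of every participant.
#'
#' @param mask Logical 3D array.
#' @param coverage_masks List of logical 3D arrays (per participant, per
#'   stage).
#' @return Logical 3D array. Warns if the result is empty.
#' @export
coverage_intersection <- function(mask, coverage_masks) {
  check_same_grid(c(list(dim(mask)), lapply(coverage_masks, dim)))
  out <- mask & Reduce(`&`, coverage_masks)
  if (!any(out)) warn("coverage intersection produced an empty mask")
  out
}

#' Build the lesion-aware gray-matter group mask
#'
#' Chains the three steps: tissue argmax over the group-mean probability
#' maps, exclusion of lesioned voxels plus their six face neighbors, and
#' intersection with the fMRI coverage of all participants.
#'
#' @inheritParams tissue_argmax
#' @inheritParams lesion_exclusion
#' @inheritParams coverage_intersection
#' @return A logical 3D array with a `"provenance"` attribute: a tibble of
#'   voxel counts after each step.
#' @export
build_gm_mask <- function(stack, lesion_masks = list(),
                          coverage_masks = list()) {
  labels <- tissue_argmax(stack)
  gm <- labels == 1L
  steps <- tibble(step = "tissue_argmax_gm", n_voxels = sum(gm))
  if (length(lesion_masks)) {
    gm <- lesion_exclusion(gm, lesion_masks)
    steps <- bind_rows(steps,
      tibble(step = "lesion_exclusion", n_voxels = sum(gm)))
  }
  if (length(coverage_masks)) {
    gm <- coverage_intersection(gm, coverage_masks)
    steps <- bind_rows(steps,
      tibble(step = "coverage_intersection", n_voxels = sum(gm)))
  }
  attr(gm, "provenance") <- steps
  attr(gm, "n_removed") <- NULL
  gm
}

#' Read or write a voxel mask as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} preserving the image affine. Masks are
#' exchanged as 0/1 volumes.
#'
#' @param mask Logical 3D array (for writing).
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param template Optional NIfTI image or path supplying the affine.
#' @return `read_mask_nifti()` returns a logical 3D array; `write_mask_nifti()`
#'   returns `path` invisibly.
#' @export
write_mask_nifti <- function(mask, path, template = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("the RNifti package is required for NIfTI I/O")
  }
  img <- if (is.null(template)) RNifti::asNifti(mask * 1L) else
    RNifti::asNifti(mask * 1L, reference = RNifti::asNifti(template))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("the RNifti package is required for NIfTI I/O")
  }
  arr <- as.array(RNifti::readNifti(path))
  arr != 0
}
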