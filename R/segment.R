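# Whole-volume inference and task-specific post-processing.

#' Segment a whole volume
#'
#' Runs the network over every voxel of the processing region — the dilated
#' atlas region of interest in structures mode (the structures lie in the
#' central brain, so this speeds inference up drastically), all brain voxels
#' in lesions mode — and assembles per-voxel class probabilities. Structure
#' labels are the argmax class; lesion masks threshold the lesion
#' probability at `threshold` (>= convention).
#'
#' @param net A trained `patch_cnn`.
#' @param volume The `volume` to segment.
#' @param atlas The co-registered `prior_atlas`.
#' @param threshold Lesion probability threshold (default 0.5; lesions mode
#'   only).
#' @param roi_radius Dilation radius of the atlas ROI (structures mode).
#' @param brain_mask Optional 3D logical brain mask; defaults to non-zero
#'   voxels.
#' @param normalize Normalise the volume intensities first (default TRUE;
#'   set FALSE if already normalised).
#' @param chunk Voxels per forward chunk.
#' @return An object of class `segmentation_result`: `probabilities` (4D,
#'   zero outside the processed region), `labels` (a `label_map`),
#'   `processed_mask`, `mode`, `threshold`.
#' @export
segment_volume <- function(net, volume, atlas, threshold = 0.5,
                           roi_radius = 5, brain_mask = NULL,
                           normalize = TRUE, chunk = 1024L) {
  stopifnot(inherits(net, "patch_cnn"), inherits(volume, "volume"),
            inherits(atlas, "prior_atlas"))
  if (!identical(dim(volume$data), dim(atlas$data)[1:3])) {
    stop("input error: volume and atlas shapes differ")
  }
  if (net$spec$prior_units != atlas$K) {
    stop("input error: atlas channel count does not match the network")
  }
  mode <- net$spec$mode
  if (is.null(brain_mask)) brain_mask <- volume$data != 0
  if (normalize) volume <- normalize_intensity(volume, mask = brain_mask)
  mask <- if (mode == "structures") roi_from_priors(atlas, roi_radius) else brain_mask
  d <- dim(volume$data)
  C <- net$spec$out_classes
  probs4 <- array(0, c(d, C))
  labels <- array(0L, d)
  vox_idx <- which(mask)
  if (length(vox_idx)) {
    vox <- arrayInd(vox_idx, d)
    n <- nrow(vox)
    pm <- matrix(0, n, C)
    for (s in seq(1L, n, by = chunk)) {
      idx <- s:min(n, s + chunk - 1L)
      b <- build_patch_batch(volume, atlas, vox[idx, , drop = FALSE],
                             net$spec$patch_size)
      pm[idx, ] <- net_forward(net, b$X, b$prior)$probs
    }
    for (k in seq_len(C)) {
      ch <- array(0, d)
      ch[vox_idx] <- pm[, k]
      probs4[, , , k] <- ch
    }
    if (mode == "structures") {
      labels[vox_idx] <- max.col(pm) - 1L
    } else {
      labels[vox_idx] <- as.integer(pm[, 2] >= threshold)
    }
  }
  structure(list(probabilities = probs4,
                 labels = as_label_map(labels, volume$spacing,
                                       class_count = max(C, max(labels) + 1L)),
                 processed_mask = mask, mode = mode, threshold = threshold),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", x$mode, " mode, ",
      sum(x$processed_mask), " voxels processed, ",
      sum(x$labels$data != 0L), " foreground voxels\n", sep = "")
  invisible(x)
}

#' Predict method for patch CNNs
#'
#' Convenience wrapper around [segment_volume()].
#'
#' @param object A trained `patch_cnn`.
#' @param volume,atlas The case to segment.
#' @param ... Passed to [segment_volume()].
#' @return A `segmentation_result`.
#' @export
predict.patch_cnn <- function(object, volume, atlas, ...) {
  segment_volume(object, volume, atlas, ...)
}

#' Keep only the largest connected component of one class
#'
#' Spurious voxels away from a structure are removed by retaining, for the
#' given class, only its largest 26-connected component (voxel count); ties
#' are broken deterministically in favour of the component containing the
#' lexicographically smallest (x, y, z) voxel. Other classes are untouched.
#'
#' @param labels A `label_map` (or 3D integer array).
#' @param class_index Class to clean.
#' @return The cleaned `label_map`.
#' @export
keep_largest_component <- function(labels, class_index) {
  arr <- if (inherits(labels, "label_map")) labels$data else labels
  cc <- label_components(arr == class_index)
  ncomp <- max(cc)
  if (ncomp <= 1L) return(labels)
  d <- dim(arr)
  idx <- which(cc != 0L)
  comp <- cc[idx]
  sizes <- tabulate(comp, ncomp)
  pos <- arrayInd(idx, d)
  lexkey <- ((pos[, 1] - 1) * d[2] + (pos[, 2] - 1)) * d[3] + (pos[, 3] - 1)
  minkey <- vapply(seq_len(ncomp), function(k) min(lexkey[comp == k]), numeric(1))
  keep <- order(-sizes, minkey)[1L]
  drop_idx <- idx[comp != keep]
  arr[drop_idx] <- 0L
  if (inherits(labels, "label_map")) {
    labels$data <- arr
    labels
  } else {
    arr
  }
}

#' Filter lesion candidates by size and white-matter membership
#'
#' Lesion candidates are the 26-connected components of the binary mask. A
#' candidate is removed if its physical volume (voxel count times voxel
#' volume) is less than `min_volume_mm3` (strictly; a candidate of exactly
#' the minimum volume is retained), or if it lies outside the white matter:
#' a candidate counts as inside when at least half of its voxels have a WM
#' prior probability of at least `wm_threshold`.
#'
#' @param mask 3D logical candidate mask.
#' @param wm_prior 3D white-matter probability map (same shape).
#' @param spacing Voxel spacing in mm.
#' @param min_volume_mm3 Minimum candidate volume in mm^3 (default 3).
#' @param wm_threshold WM probability threshold (default 0.5).
#' @return Filtered 3D logical mask.
#' @export
filter_lesion_candidates <- function(mask, wm_prior, spacing = c(1, 1, 1),
                                     min_volume_mm3 = 3, wm_threshold = 0.5) {
  stopifnot(identical(dim(mask), dim(wm_prior)))
  cc <- label_components(mask != 0)
  ncomp <- max(cc)
  if (ncomp == 0L) return(array(FALSE, dim(mask)))
  voxvol <- prod(spacing)
  out <- array(FALSE, dim(mask))
  idx <- which(cc != 0L)
  comp <- cc[idx]
  for (k in seq_len(ncomp)) {
    vox_k <- idx[comp == k]
    if (length(vox_k) * voxvol < min_volume_mm3) next
    if (mean(wm_prior[vox_k] >= wm_threshold) < 0.5) next
    out[vox_k] <- TRUE
  }
  out
}
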