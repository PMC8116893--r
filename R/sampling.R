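# 2.5D patch extraction, spatial-prior vectors, and the training-set
# sampling strategies (boundary negatives for structures; balanced and
# cascaded sampling for lesions).
#
# Voxel coordinates are 1-based (x, y, z). Patch windows of size S cover
# offsets `seq_len(S) - 1 - S %/% 2` around the centre voxel (symmetric for
# odd S); out-of-bounds entries are zero-filled, which after z-score
# normalisation corresponds to mean intensity.

patch_offsets <- function(size) seq_len(size) - 1L - size %/% 2L

#' Extract a 2.5D patch sample at one voxel
#'
#' Returns the three orthogonal 2D patches — axial (x-y plane at fixed z),
#' sagittal (y-z plane at fixed x), and coronal (x-z plane at fixed y) —
#' centred on the voxel.
#'
#' @param volume A `volume`.
#' @param voxel Length-3 integer voxel index (1-based).
#' @param size Patch side length (default 32).
#' @return List with `axial`, `sagittal`, `coronal` size-by-size matrices.
#' @export
extract_25d_patch <- function(volume, voxel, size = 32) {
  stopifnot(inherits(volume, "volume"), length(voxel) == 3L)
  d <- dim(volume$data)
  if (any(voxel < 1L) || any(voxel > d)) stop("voxel outside volume")
  off <- patch_offsets(size)
  take_plane <- function(ax1, ax2, fixed_axis) {
    i <- voxel[ax1] + off
    j <- voxel[ax2] + off
    oki <- i >= 1L & i <= d[ax1]
    okj <- j >= 1L & j <= d[ax2]
    out <- matrix(0, size, size)
    if (any(oki) && any(okj)) {
      idx <- vector("list", 3)
      idx[[ax1]] <- i[oki]
      idx[[ax2]] <- j[okj]
      idx[[fixed_axis]] <- voxel[fixed_axis]
      sub <- do.call(`[`, c(list(volume$data), idx, list(drop = FALSE)))
      sub <- aperm(sub, c(ax1, ax2, fixed_axis))
      out[oki, okj] <- matrix(sub, sum(oki), sum(okj))
    }
    out
  }
  list(
    axial = take_plane(1L, 2L, 3L),
    sagittal = take_plane(2L, 3L, 1L),
    coronal = take_plane(1L, 3L, 2L)
  )
}

#' Spatial-prior vector at a voxel
#'
#' The K atlas channel values at one voxel, ordered (background,
#' classes 1..K-1) for structure atlases and (WM, GM, CSF) for tissue
#' atlases.
#'
#' @param atlas A `prior_atlas`.
#' @param voxel Length-3 integer voxel index.
#' @return Numeric vector of length K.
#' @export
prior_vector <- function(atlas, voxel) {
  stopifnot(inherits(atlas, "prior_atlas"), length(voxel) == 3L)
  d <- dim(atlas$data)[1:3]
  if (any(voxel < 1L) || any(voxel > d)) stop("voxel outside atlas")
  atlas$data[voxel[1], voxel[2], voxel[3], ]
}

#' Structure-mode training voxels: all positives, boundary negatives
#'
#' Positives are every voxel of each structure class. Negatives are the
#' background voxels within a Chebyshev distance `margin` of any structure
#' voxel — the hardest region for the classifier, the structure borders.
#'
#' @param label A `label_map` with at least one non-background voxel.
#' @param margin Boundary margin in voxels (default 5).
#' @return List with `positives` (n x 4 matrix: x, y, z, class) and
#'   `negatives` (m x 3 matrix).
#' @export
sample_structures <- function(label, margin = 5) {
  stopifnot(inherits(label, "label_map"))
  fg <- label$data != 0L
  if (!any(fg)) stop("sampling error: label map has no foreground voxels")
  pos_idx <- which(fg)
  pos <- cbind(arrayInd(pos_idx, dim(label$data)), class = label$data[pos_idx])
  ring <- dilate_chebyshev(fg, margin) & !fg
  neg <- arrayInd(which(ring), dim(label$data))
  colnames(pos) <- c("x", "y", "z", "class")
  if (nrow(neg)) colnames(neg) <- c("x", "y", "z")
  list(positives = pos, negatives = neg)
}

#' Lesion-mode stage-1 training voxels: balanced random negatives
#'
#' Positives are all lesion voxels; negatives are an equal-sized uniform
#' seeded sample of non-lesion brain voxels.
#'
#' @param label A `label_map` (class 1 = lesion).
#' @param brain_mask 3D logical array of brain voxels.
#' @param seed Integer seed.
#' @return List with `positives` and `negatives` coordinate matrices.
#' @export
sample_lesions_stage1 <- function(label, brain_mask, seed = 1) {
  stopifnot(inherits(label, "label_map"), identical(dim(brain_mask), dim(label$data)))
  les <- label$data != 0L
  if (!any(les)) stop("sampling error: no lesion voxels")
  pool <- which(brain_mask & !les)
  npos <- sum(les)
  if (length(pool) < npos) {
    stop("sampling error: fewer non-lesion brain voxels (", length(pool),
         ") than lesion voxels (", npos, ")")
  }
  neg_idx <- with_seed(seed, sample(pool, npos))
  pos <- arrayInd(which(les), dim(label$data)); colnames(pos) <- c("x", "y", "z")
  neg <- arrayInd(neg_idx, dim(label$data)); colnames(neg) <- c("x", "y", "z")
  list(positives = pos, negatives = neg)
}

#' Lesion-mode stage-2 training voxels: negatives from stage-1 false positives
#'
#' The false-positive-reduction stage of cascaded training: positives are all
#' lesion voxels, negatives are drawn from voxels the stage-1 network
#' predicted as lesion but that are background in the ground truth. If fewer
#' false positives exist than positives, the deficit is topped up with
#' uniform random non-lesion brain voxels so the sample stays balanced.
#'
#' @param label Ground-truth `label_map`.
#' @param stage1_prediction Stage-1 predicted `label_map` (same shape).
#' @param brain_mask 3D logical array of brain voxels.
#' @param seed Integer seed.
#' @return List with `positives`, `negatives`, and `n_false_positive` (the
#'   number of stage-1 false-positive voxels available).
#' @export
sample_lesions_stage2 <- function(label, stage1_prediction, brain_mask, seed = 1) {
  stopifnot(inherits(label, "label_map"),
            identical(dim(stage1_prediction$data), dim(label$data)))
  les <- label$data != 0L
  if (!any(les)) stop("sampling error: no lesion voxels")
  npos <- sum(les)
  fp <- stage1_prediction$data != 0L & !les
  fp_idx <- which(fp)
  neg_idx <- with_seed(seed, {
    if (length(fp_idx) >= npos) {
      sample(fp_idx, npos)
    } else {
      pool <- which(brain_mask & !les & !fp)
      extra <- min(npos - length(fp_idx), length(pool))
      c(fp_idx, if (extra > 0) sample(pool, extra))
    }
  })
  pos <- arrayInd(which(les), dim(label$data)); colnames(pos) <- c("x", "y", "z")
  neg <- arrayInd(neg_idx, dim(label$data)); colnames(neg) <- c("x", "y", "z")
  list(positives = pos, negatives = neg, n_false_positive = length(fp_idx))
}

#' Cap the negative share of a sampling
#'
#' Uniformly subsamples the negative voxel set so that at most
#' `neg_ratio` negatives remain per positive. On small phantom volumes the
#' boundary ring can outnumber the structure voxels many times over (the
#' objects are only a few voxels in radius), so training sets are rebalanced
#' to a fixed ratio; with `neg_ratio = Inf` the sampling is returned
#' unchanged.
#'
#' @param sampling Output of [sample_structures()] (or any list with
#'   `positives`/`negatives` coordinate matrices).
#' @param neg_ratio Maximum negatives per positive.
#' @param seed Integer seed.
#' @return The sampling with a subsampled `negatives` matrix.
#' @export
balance_sampling <- function(sampling, neg_ratio = 5, seed = 1) {
  n_pos <- nrow(sampling$positives)
  n_neg <- if (length(sampling$negatives)) nrow(sampling$negatives) else 0L
  cap <- if (is.finite(neg_ratio)) as.integer(round(neg_ratio * n_pos)) else n_neg
  if (n_neg > cap) {
    keep <- with_seed(seed, sort(sample.int(n_neg, cap)))
    sampling$negatives <- sampling$negatives[keep, , drop = FALSE]
  }
  sampling
}

#' Random train/validation split
#'
#' Seeded exhaustive disjoint split; the validation share is
#' `round(val_fraction * n)` (75/25 by default).
#'
#' @param n Number of samples (or a vector/list whose length is used).
#' @param val_fraction Validation fraction in (0, 1); default 0.25.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
split_train_val <- function(n, val_fraction = 0.25, seed = 1) {
  if (!is.numeric(n) || length(n) != 1L) n <- length(n)
  n <- as.integer(n)
  if (n < 4L) stop("split error: need at least 4 samples")
  if (val_fraction <= 0 || val_fraction >= 1) stop("val_fraction must be in (0, 1)")
  n_val <- as.integer(round(val_fraction * n))
  n_val <- max(1L, min(n - 1L, n_val))
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n - n_val)]), val = sort(perm[n - n_val + seq_len(n_val)]))
}

#' Region of interest from dilated structure priors
#'
#' Union of the non-background atlas channels thresholded at probability
#' > 0, dilated by a cubic structuring element — the region inside which
#' whole-volume structure segmentation is evaluated.
#'
#' @param atlas A structures-mode `prior_atlas` (channel 1 = background).
#' @param dilation_radius Chebyshev dilation radius in voxels (default 5).
#' @return 3D logical array.
#' @export
roi_from_priors <- function(atlas, dilation_radius = 5) {
  stopifnot(inherits(atlas, "prior_atlas"))
  K <- atlas$K
  if (K < 2L) return(array(FALSE, dim(atlas$data)[1:3]))
  supp <- array(FALSE, dim(atlas$data)[1:3])
  for (k in 2:K) supp <- supp | (atlas$data[, , , k] > 0)
  dilate_chebyshev(supp, dilation_radius)
}

# Vectorised batch construction: three patch matrices (n x S^2, pixels
# column-major within the patch) plus the n x K prior matrix for a set of
# voxels. This is the workhorse behind training and whole-volume inference.
build_patch_batch <- function(volume, atlas, voxels, size) {
  stopifnot(inherits(volume, "volume"))
  if (is.null(dim(voxels))) voxels <- matrix(voxels, nrow = 1)
  n <- nrow(voxels)
  d <- dim(volume$data)
  off <- patch_offsets(size)
  plane <- function(ax1, ax2, fixed_axis) {
    # index arrays (n x S^2): rows samples, patch pixels column-major (i fast)
    i <- outer(voxels[, ax1], off, "+")            # n x S
    j <- outer(voxels[, ax2], off, "+")            # n x S
    f <- voxels[, fixed_axis]                      # n
    ii <- matrix(rep(i, times = size), n, size * size)
    jj <- j[, rep(seq_len(size), each = size)]
    inb <- ii >= 1L & ii <= d[ax1] & jj >= 1L & jj <= d[ax2]
    ic <- pmin(pmax(ii, 1L), d[ax1])
    jc <- pmin(pmax(jj, 1L), d[ax2])
    coord <- matrix(0L, n * size * size, 3)
    coord[, ax1] <- as.vector(ic)
    coord[, ax2] <- as.vector(jc)
    coord[, fixed_axis] <- rep(f, times = size * size)
    lin <- coord[, 1] + (coord[, 2] - 1L) * d[1] + (coord[, 3] - 1L) * d[1] * d[2]
    m <- matrix(volume$data[lin], n, size * size)
    m[!inb] <- 0
    m
  }
  X <- list(axial = plane(1L, 2L, 3L),
            sagittal = plane(2L, 3L, 1L),
            coronal = plane(1L, 3L, 2L))
  prior <- NULL
  if (!is.null(atlas)) {
    da <- dim(atlas$data)
    lin3 <- voxels[, 1] + (voxels[, 2] - 1L) * da[1] + (voxels[, 3] - 1L) * da[1] * da[2]
    prior <- vapply(seq_len(atlas$K), function(k) {
      atlas$data[lin3 + (k - 1L) * da[1] * da[2] * da[3]]
    }, numeric(n))
    if (n == 1L) prior <- matrix(prior, 1)
  }
  list(X = X, prior = prior, voxels = voxels)
}
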