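# Volume containers and NIfTI I/O.
#
# Conventions used throughout the package: voxel indices are 1-based (R
# convention) in axis order (x, y, z) = (sagittal, coronal, axial); spacing is
# the voxel edge length in mm per axis; `affine` maps voxel indices to world
# coordinates in mm and is carried through I/O but never interpreted.

#' Construct a volume
#'
#' A volume is a 3D scalar field with voxel spacing and an (optional) affine
#' orientation. Data are held in double precision.
#'
#' @param data 3D numeric array, each axis of length >= 1.
#' @param spacing Positive length-3 numeric vector of voxel edge lengths (mm).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @return An object of class `volume`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  attributes(data) <- list(dim = unname(dim(data)))
  if (length(dim(data)) != 3L) stop("volume data must have exactly 3 axes")
  if (any(dim(data) < 1L)) stop("each volume axis must have length >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite values")
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "volume")
}

#' Construct a label map
#'
#' Integer class indices per voxel, 0 denoting background; companion to a
#' [as_volume()] volume of the same shape.
#'
#' @param data 3D array of integer class indices in `[0, class_count - 1]`.
#' @param spacing Voxel spacing in mm.
#' @param class_count Number of classes including background.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return An object of class `label_map`.
#' @export
as_label_map <- function(data, spacing = c(1, 1, 1), class_count = NULL,
                         affine = NULL) {
  data <- as.array(data)
  attributes(data) <- list(dim = unname(dim(data)))
  if (length(dim(data)) != 3L) stop("label data must have exactly 3 axes")
  if (any(data != round(data))) stop("label data must be integer-valued")
  storage.mode(data) <- "integer"
  if (is.null(class_count)) class_count <- max(data) + 1L
  class_count <- as.integer(class_count)
  if (class_count < 1L) stop("class_count must be positive")
  if (any(data < 0L) || any(data > class_count - 1L)) {
    stop("label values must lie in [0, class_count - 1]")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = spacing, affine = affine,
                 class_count = class_count),
            class = "label_map")
}

#' Construct a probabilistic prior atlas
#'
#' A 4D field of K per-voxel class probabilities, emulating a registered
#' probabilistic atlas: 15 channels (background + 14 sub-cortical structures)
#' in structures mode, 3 channels (WM, GM, CSF tissue priors) in lesion mode.
#' Per-voxel channel sums may fall slightly short of or exceed 1 (registration
#' is never exactly normalised); sums above 1 + 1e-3 are rejected.
#'
#' @param data 4D numeric array with channels on the fourth axis.
#' @param spacing Voxel spacing in mm.
#' @return An object of class `prior_atlas`.
#' @export
as_prior_atlas <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  attributes(data) <- list(dim = unname(dim(data)))
  if (length(dim(data)) != 4L) stop("prior atlas data must have exactly 4 axes")
  if (any(data < -1e-9) || any(data > 1 + 1e-9)) {
    stop("prior probabilities must lie in [0, 1]")
  }
  sums <- apply(data, c(1, 2, 3), sum)
  if (any(sums > 1 + 1e-3)) stop("per-voxel channel sums must not exceed 1 + 1e-3")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, K = dim(data)[4]),
            class = "prior_atlas")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", x$class_count, " classes, ",
      sum(x$data != 0L), " foreground voxels\n", sep = "")
  invisible(x)
}

#' @export
print.prior_atlas <- function(x, ...) {
  cat("<prior_atlas> ", paste(dim(x$data)[1:3], collapse = " x "),
      " voxels, K = ", x$K, " channels\n", sep = "")
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D scalar volume (or, with `channels = TRUE`, a 4D probability
#' atlas) from a `.nii`/`.nii.gz` file; spacing and orientation are taken
#' from the header and data are cast to doubles.
#'
#' @param path Path to a NIfTI-1 file.
#' @param channels If TRUE, expect a 4D image and return a [as_prior_atlas()].
#' @return A `volume` (or `prior_atlas`).
#' @export
read_volume <- function(path, channels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  if (channels) {
    if (length(dim(data)) != 4L) stop("expected a 4D (multi-channel) image, got ",
                                      length(dim(data)), "D")
    return(as_prior_atlas(data, spacing = pd[1:3]))
  }
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) data <- data[, , , 1]
  if (length(dim(data)) != 3L) stop("expected a 3D image, got ",
                                    length(dim(data)), "D")
  as_volume(data, spacing = pd[1:3], affine = structure(RNifti::xform(img), imagedim = NULL))
}

#' Read a NIfTI-1 label map
#'
#' @param path Path to an integer-valued NIfTI-1 file.
#' @param class_count Optional number of classes; inferred from the data if
#'   omitted.
#' @return A `label_map`.
#' @export
read_label_map <- function(path, class_count = NULL) {
  v <- read_volume(path)
  as_label_map(round(v$data), spacing = v$spacing, class_count = class_count,
               affine = v$affine)
}

#' Write a volume, label map, or prior atlas as NIfTI-1
#'
#' Label maps are written with an integer datatype so voxel values round-trip
#' exactly; volumes and atlases are written in single precision (the working
#' precision for image data).
#'
#' @param volume A `volume`, `label_map`, or `prior_atlas`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (dir.exists(path)) stop("path is a directory: ", path)
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  if (inherits(volume, "label_map")) {
    dtype <- "int32"
  } else if (inherits(volume, c("prior_atlas", "volume"))) {
    dtype <- "float"
  } else {
    stop("write_volume expects a volume, label_map, or prior_atlas")
  }
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  tryCatch(RNifti::writeNifti(img, path, datatype = dtype),
           error = function(e) stop("could not write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Z-score intensity normalisation
#'
#' Rescales a volume to zero mean and unit (population) standard deviation,
#' the standard intensity normalisation applied before patch-based training
#' and inference. Statistics are computed over a mask — by default the
#' non-zero voxels, matching skull-stripped images where background is
#' exactly zero — and the affine transform `(x - mu) / sigma` is applied to
#' the whole volume, so the map is idempotent and absorbs any prior affine
#' intensity change.
#'
#' @param volume A `volume`.
#' @param mask Optional 3D logical array selecting the voxels over which the
#'   statistics are computed.
#' @param nonzero If TRUE (default) and `mask` is NULL, use the non-zero
#'   voxels; if FALSE, use the whole volume.
#' @return A normalised `volume`.
#' @export
normalize_intensity <- function(volume, mask = NULL, nonzero = TRUE) {
  stopifnot(inherits(volume, "volume"))
  x <- volume$data
  if (is.null(mask)) {
    sel <- if (nonzero) x != 0 else rep(TRUE, length(x))
    if (!any(sel)) sel <- rep(TRUE, length(x))
  } else {
    stopifnot(identical(dim(mask), dim(x)))
    sel <- mask != 0
    if (sum(sel) < 2L) stop("mask must select at least 2 voxels")
  }
  v <- x[sel]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (!is.finite(sigma) || sigma < 1e-12) {
    stop("degenerate input: intensity variance is zero over the normalisation mask")
  }
  out <- volume
  out$data <- (x - mu) / sigma
  out
}
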