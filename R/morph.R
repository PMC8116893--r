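# 3D array morphology and smoothing primitives used across the package.
# Volumes at the scale this package targets (tens of voxels per side) make
# plain vectorised R adequate; no compiled code is needed.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the caller's RNG
#' state, so that seeded operations never perturb global random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Shift a 3D array along one axis by `by` voxels, filling vacated entries.
shift_array3 <- function(x, axis, by, fill = 0) {
  d <- dim(x)
  stopifnot(length(d) == 3L, axis %in% 1:3)
  if (by == 0L) return(x)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by > 0) seq(1 + by, n) else seq_len(n + by)
  ix <- rep(list(quote(expr = )), 3L)
  ixs <- ix; ixs[[axis]] <- src
  ixd <- ix; ixd[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), ixd, list(do.call(`[`, c(list(x), ixs, list(drop = FALSE))))))
  out
}

#' Binary dilation with a cubic (Chebyshev) structuring element
#'
#' Dilates a 3D logical mask so the output is TRUE at every voxel within
#' Chebyshev (chessboard) distance `radius` of an input TRUE voxel. The cubic
#' element is separable, so the dilation is applied axis by axis.
#'
#' @param mask 3D logical array.
#' @param radius Non-negative integer radius in voxels.
#' @return 3D logical array of the same shape.
#' @export
dilate_chebyshev <- function(mask, radius) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, radius >= 0)
  mask <- mask != 0
  if (radius == 0L) return(mask)
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (d in seq_len(radius)) {
      acc <- acc | shift_array3(out, axis, d, FALSE) | shift_array3(out, axis, -d, FALSE)
    }
    out <- acc
  }
  out
}

# Truncated (3 sigma), renormalised 1D Gaussian kernel matrix for axis length n.
gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  i <- seq_len(n)
  k <- outer(i, i, function(a, b) {
    d <- abs(a - b)
    ifelse(d <= ceiling(3 * sigma), exp(-(d^2) / (2 * sigma^2)), 0)
  })
  sweep(k, 1L, rowSums(k), "/")
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array with an axis-separable Gaussian kernel truncated at
#' three standard deviations and renormalised, so constants are preserved
#' exactly (including near the array edges).
#'
#' @param x 3D numeric array.
#' @param sigma Standard deviation in voxels; scalar or length-3 vector.
#' @return Smoothed 3D array.
#' @export
gaussian_blur3 <- function(x, sigma) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  sigma <- rep(sigma, length.out = 3L)
  if (all(sigma <= 0)) return(x)
  # axis 1
  if (sigma[1] > 0) {
    x <- array(gauss_kernel_matrix(d[1], sigma[1]) %*% matrix(x, d[1], d[2] * d[3]), d)
  }
  # axis 2
  if (sigma[2] > 0) {
    xp <- aperm(x, c(2, 1, 3))
    xp <- array(gauss_kernel_matrix(d[2], sigma[2]) %*% matrix(xp, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    x <- aperm(xp, c(2, 1, 3))
  }
  # axis 3
  if (sigma[3] > 0) {
    xp <- aperm(x, c(3, 1, 2))
    xp <- array(gauss_kernel_matrix(d[3], sigma[3]) %*% matrix(xp, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
    x <- aperm(xp, c(2, 3, 1))
  }
  x
}

#' Label 26-connected components of a 3D mask
#'
#' @param mask 3D logical array.
#' @return 3D integer array; 0 for background, components numbered from 1 in
#'   first-encounter (column-major) order.
#' @export
label_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  idx <- which(mask != 0)
  out <- array(0L, d)
  if (!length(idx)) return(out)
  n <- length(idx)
  pos <- arrayInd(idx, d)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- offs[, 3] > 0 |
    (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs <- offs[keep, , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    nx <- pos[, 1] + offs[k, 1]; ny <- pos[, 2] + offs[k, 2]; nz <- pos[, 3] + offs[k, 3]
    ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] & nz >= 1L & nz <= d[3]
    nk <- nx + (ny - 1L) * d[1] + (nz - 1L) * d[1] * d[2]
    j <- match(nk[ok], idx)
    hit <- !is.na(j)
    ii <- which(ok)[hit]; jj <- j[hit]
    for (e in seq_along(ii)) {
      a <- find_root(ii[e]); b <- find_root(jj[e])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find_root, integer(1))
  labs <- match(roots, unique(roots))
  out[idx] <- labs
  out
}

#' Empirical Wasserstein-1 distance between two value samples
#'
#' Computes the 1-Wasserstein (earth mover's) distance between the empirical
#' distributions of two numeric samples via quantile functions on a common
#' probability grid (exact when the samples have equal size).
#'
#' @param a,b Numeric vectors.
#' @return Non-negative scalar.
#' @export
wasserstein1 <- function(a, b) {
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (length(a) == length(b)) return(mean(abs(a - b)))
  n <- max(length(a), length(b))
  p <- (seq_len(n) - 0.5) / n
  qa <- stats::quantile(a, p, names = FALSE, type = 7)
  qb <- stats::quantile(b, p, names = FALSE, type = 7)
  mean(abs(qa - qb))
}
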