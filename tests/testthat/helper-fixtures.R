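# Shared in-code fixtures for the test suite; everything is generated
# programmatically and seeded.

# A random volume with strictly positive intensities (no zero background),
# convenient when whole-volume normalisation statistics are wanted.
toy_volume <- function(d = c(12, 12, 12), seed = 1, spacing = c(1, 1, 1)) {
  hmadapt:::with_seed(seed, as_volume(array(stats::runif(prod(d), 0.1, 1), d),
                                      spacing = spacing))
}

# A random labelled patch batch matching a network spec.
toy_batch <- function(spec, n = 6, seed = 1, labelled = TRUE) {
  hmadapt:::with_seed(seed, {
    P <- spec$patch_size^2
    list(X = list(axial = matrix(stats::rnorm(n * P), n),
                  sagittal = matrix(stats::rnorm(n * P), n),
                  coronal = matrix(stats::rnorm(n * P), n)),
         prior = matrix(stats::runif(n * spec$prior_units), n),
         y = if (labelled) sample.int(spec$out_classes, n, replace = TRUE))
  })
}

# A minimal architecture for fast gradient/loss tests.
micro_spec <- function(mode = "structures", ...) {
  network_spec(mode = mode, patch_size = 5, conv_channels = c(3, 4), kernel = 3,
               path_fc = 6, head_fc = 7,
               prior_units = if (mode == "structures") 4L else 3L,
               out_classes = if (mode == "structures") 3L else 2L, ...)
}

# Brute-force 26-connected component labelling by breadth-first search;
# independent oracle for label_components().
bf_components <- function(mask) {
  d <- dim(mask)
  out <- array(0L, d)
  lab <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  for (start in which(mask != 0)) {
    if (out[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    out[start] <- lab
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      pos <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        p <- pos + offs[k, ]
        if (any(p < 1) || any(p > d)) next
        li <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (mask[li] != 0 && out[li] == 0L) {
          out[li] <- lab
          queue <- c(queue, li)
        }
      }
    }
  }
  out
}

# Brute-force Chebyshev dilation oracle.
bf_dilate <- function(mask, radius) {
  d <- dim(mask)
  out <- array(FALSE, d)
  fg <- which(mask != 0)
  pos <- arrayInd(fg, d)
  for (i in seq_len(nrow(pos))) {
    xr <- max(1, pos[i, 1] - radius):min(d[1], pos[i, 1] + radius)
    yr <- max(1, pos[i, 2] - radius):min(d[2], pos[i, 2] + radius)
    zr <- max(1, pos[i, 3] - radius):min(d[3], pos[i, 3] + radius)
    out[xr, yr, zr] <- TRUE
  }
  out
}

# Exact rank-matching oracle for equal-size tie-free multisets.
rank_match_oracle <- function(source, target) {
  sort(target)[rank(source)]
}
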