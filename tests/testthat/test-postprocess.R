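# Connected components, morphology, and segmentation post-processing.

test_that("component labelling matches a breadth-first-search oracle", {
  set.seed(31)
  for (rep in 1:4) {
    mask <- array(stats::runif(8^3) < 0.25, c(8, 8, 8))
    got <- label_components(mask)
    want <- bf_components(mask)
    # same partition (labels may be numbered differently)
    expect_equal(max(got), max(want))
    if (max(got) > 0) {
      key <- paste(got[mask], want[mask])
      expect_equal(length(unique(key)), max(got))
    }
    expect_true(all((got != 0) == (mask != 0)))
  }
})

test_that("Chebyshev dilation matches the brute-force oracle", {
  set.seed(17)
  for (r in c(1, 2, 5)) {
    mask <- array(stats::runif(10^3) < 0.05, c(10, 10, 10))
    expect_identical(dilate_chebyshev(mask, r), bf_dilate(mask, r))
  }
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  expect_identical(dilate_chebyshev(m, 0), m)
})

test_that("keep_largest_component retains exactly the largest component", {
  d <- c(12, 12, 12)
  lab <- array(0L, d)
  lab[2:6, 2:3, 2] <- 1L               # 10 voxels
  lab[9:11, 9, 9] <- 1L                # 3 voxels
  lm <- as_label_map(lab, class_count = 2)
  out <- keep_largest_component(lm, 1L)
  expect_equal(sum(out$data == 1L), 10L)
  expect_true(all(out$data[9:11, 9, 9] == 0L))
  # idempotent; single component untouched
  expect_identical(keep_largest_component(out, 1L)$data, out$data)

  # other classes are untouched
  lab2 <- lab; lab2[5:7, 8:9, 5] <- 2L
  out2 <- keep_largest_component(as_label_map(lab2, class_count = 3), 1L)
  expect_equal(sum(out2$data == 2L), 6L)

  # absent class is a no-op
  expect_identical(keep_largest_component(lm, 3L)$data, lm$data)
})

test_that("size ties break toward the lexicographically smallest voxel", {
  d <- c(12, 12, 12)
  lab <- array(0L, d)
  lab[8:10, 8, 8] <- 1L   # later in (x,y,z) order, 3 voxels
  lab[2:4, 2, 2] <- 1L    # contains (2,2,2), 3 voxels
  out <- keep_largest_component(as_label_map(lab, class_count = 2), 1L)
  expect_true(all(out$data[2:4, 2, 2] == 1L))
  expect_true(all(out$data[8:10, 8, 8] == 0L))
})

test_that("lesion filtering removes small and extra-WM candidates only", {
  d <- c(20, 20, 20)
  mask <- array(FALSE, d)
  mask[2:3, 2, 2] <- TRUE                 # 2 voxels = 2 mm^3 (too small)
  mask[8:12, 8, 8] <- TRUE                # 5 voxels, inside WM
  mask[15:19, 15:16, 15] <- TRUE          # 10 voxels, outside WM
  wm <- array(0, d)
  wm[1:13, 1:13, 1:13] <- 0.9
  out <- filter_lesion_candidates(mask, wm, spacing = c(1, 1, 1),
                                  min_volume_mm3 = 3)
  expect_equal(sum(out), 5L)
  expect_true(all(out[8:12, 8, 8]))

  # a 1-voxel candidate at spacing (1,1,3) has volume 3 mm^3: retained
  m1 <- array(FALSE, d); m1[5, 5, 5] <- TRUE
  out1 <- filter_lesion_candidates(m1, wm, spacing = c(1, 1, 3),
                                   min_volume_mm3 = 3)
  expect_true(out1[5, 5, 5])
  # ... but is removed at 1 mm^3 voxels
  out1b <- filter_lesion_candidates(m1, wm, spacing = c(1, 1, 1),
                                    min_volume_mm3 = 3)
  expect_false(any(out1b))

  # empty input, empty output
  expect_false(any(filter_lesion_candidates(array(FALSE, d), wm)))
})

test_that("post-processing never adds voxels and is monotone in the size threshold", {
  set.seed(23)
  d <- c(16, 16, 16)
  mask <- array(stats::runif(prod(d)) < 0.08, d)
  wm <- array(stats::runif(prod(d)), d)
  prev <- mask
  for (mv in c(1, 3, 9, 27)) {
    out <- filter_lesion_candidates(mask, wm, min_volume_mm3 = mv)
    expect_true(all(out <= mask))   # subset of input
    expect_true(all(out <= prev))   # shrinks as the threshold rises
    prev <- out
  }
  lab <- array(as.integer(mask), d)
  out <- keep_largest_component(as_label_map(lab, class_count = 2), 1L)
  expect_true(all(out$data <= lab))
})

test_that("whole-volume segmentation respects ROI, argmax, and threshold rules", {
  # a network with all-zero weights and a biased classifier emits a fixed
  # class: every ROI voxel gets that class, everything else stays background
  spec <- network_spec("structures", patch_size = 5, conv_channels = 2,
                       path_fc = 3, head_fc = 4, prior_units = 3,
                       out_classes = 3)
  net <- build_network(spec, seed = 1)
  net$weights <- hmadapt:::tree_map(net$weights, function(x) x * 0)
  net$weights$out$b <- c(0, 5, 0)  # always class index 1
  d <- c(14, 14, 14)
  arr <- array(0, c(d, 3))
  arr[6:9, 6:9, 6:9, 2] <- 0.8
  arr[, , , 1] <- 1 - apply(arr[, , , 2:3, drop = FALSE], c(1, 2, 3), sum)
  at <- as_prior_atlas(arr)
  v <- toy_volume(d, seed = 2)
  seg <- segment_volume(net, v, at, roi_radius = 2)
  roi <- roi_from_priors(at, 2)
  expect_true(all(seg$labels$data[roi] == 1L))
  expect_true(all(seg$labels$data[!roi] == 0L))
  expect_identical(seg$processed_mask, roi)
  # probabilities sum to 1 inside the processed region
  ps <- apply(seg$probabilities, c(1, 2, 3), sum)
  expect_true(all(abs(ps[roi] - 1) < 1e-5))
  expect_true(all(ps[!roi] == 0))

  # lesions mode: a classifier reading the WM prior channel produces
  # controllable probabilities; the mask applies the >= threshold convention
  specl <- network_spec("lesions", patch_size = 5, conv_channels = 2,
                        path_fc = 3, head_fc = integer(0))
  netl <- build_network(specl, seed = 1)
  netl$weights <- hmadapt:::tree_map(netl$weights, function(x) x * 0)
  # logit(lesion) = 4 * prior_1 - 2: p = 0.5 exactly at prior_1 = 0.5
  netl$weights$out$W[3 * specl$path_fc + 1, 2] <- 4
  netl$weights$out$b <- c(0, -2)
  arrl <- array(0, c(d, 3))
  arrl[5, 5, 5, 1] <- 0.25   # p < 0.5
  arrl[6, 5, 5, 1] <- 0.50   # p = 0.5 -> positive (>= rule)
  arrl[7, 5, 5, 1] <- 0.75   # p > 0.5
  atl <- as_prior_atlas(arrl)
  segl <- segment_volume(netl, v, atl, threshold = 0.5,
                         brain_mask = array(TRUE, d))
  expect_equal(sum(segl$labels$data), 2L)
  expect_equal(segl$labels$data[6, 5, 5], 1L)
  expect_equal(segl$labels$data[7, 5, 5], 1L)
  expect_equal(segl$labels$data[5, 5, 5], 0L)

  # shape mismatches are input errors
  expect_error(segment_volume(net, toy_volume(c(10, 10, 10)), at), "shapes differ")
})
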