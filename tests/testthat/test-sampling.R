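# 2.5D patch extraction, prior vectors, and the sampling strategies.

test_that("patches match direct-indexing and brute-force crop oracles", {
  # constant volume -> constant patches
  vc <- as_volume(array(3.5, c(20, 20, 20)))
  p <- extract_25d_patch(vc, c(10, 10, 10), size = 9)
  expect_true(all(vapply(p, function(m) all(m == 3.5), logical(1))))

  # gradient along z: the axial (fixed-z) patch is constant at that z
  d <- c(32, 32, 16)
  x <- array(0, d)
  for (z in seq_len(d[3])) x[, , z] <- z
  v <- as_volume(x)
  p <- extract_25d_patch(v, c(16, 16, 7), size = 9)
  expect_true(all(p$axial == 7))
  # sagittal/coronal patches vary along their z axis instead
  expect_equal(p$sagittal[1, ], as.numeric(3:11))

  # interior voxel: all three patches equal brute-force crops
  set.seed(8)
  v2 <- as_volume(array(stats::rnorm(18^3), c(18, 18, 18)))
  vox <- c(9, 8, 10); s <- 5; off <- -2:2
  p2 <- extract_25d_patch(v2, vox, size = s)
  expect_equal(p2$axial, v2$data[vox[1] + off, vox[2] + off, vox[3]])
  expect_equal(p2$sagittal, v2$data[vox[1], vox[2] + off, vox[3] + off])
  expect_equal(p2$coronal, v2$data[vox[1] + off, vox[2], vox[3] + off])

  # corner voxel: zero padding outside, brute-force crop inside
  pc <- extract_25d_patch(v2, c(1, 1, 1), size = 5)
  expect_true(all(pc$axial[1:2, ] == 0))
  expect_true(all(pc$axial[, 1:2] == 0))
  expect_equal(pc$axial[3:5, 3:5], v2$data[1:3, 1:3, 1])

  expect_error(extract_25d_patch(v2, c(0, 5, 5)), "outside")
  expect_error(extract_25d_patch(v2, c(5, 5, 19)), "outside")
})

test_that("batch extraction agrees with single-voxel extraction", {
  set.seed(3)
  v <- as_volume(array(stats::rnorm(16^3), c(16, 16, 16)))
  at <- as_prior_atlas(array(stats::runif(16^3 * 4, 0, 0.25), c(16, 16, 16, 4)))
  vox <- rbind(c(8, 8, 8), c(1, 16, 3), c(16, 1, 16), c(2, 9, 14))
  b <- hmadapt:::build_patch_batch(v, at, vox, size = 7)
  for (i in seq_len(nrow(vox))) {
    single <- extract_25d_patch(v, vox[i, ], size = 7)
    expect_equal(as.vector(single$axial), b$X$axial[i, ])
    expect_equal(as.vector(single$sagittal), b$X$sagittal[i, ])
    expect_equal(as.vector(single$coronal), b$X$coronal[i, ])
    expect_equal(prior_vector(at, vox[i, ]), b$prior[i, ])
  }
})

test_that("prior vectors pass through atlas channels in order", {
  d <- c(6, 6, 6)
  arr <- array(0, c(d, 3))
  arr[2, 3, 4, 2] <- 1
  at <- as_prior_atlas(arr)
  expect_equal(prior_vector(at, c(2, 3, 4)), c(0, 1, 0))
  expect_error(prior_vector(at, c(0, 3, 4)), "outside")
  # channel counts follow the task: 15 for structures, 3 for tissue priors
  expect_equal(as_prior_atlas(array(1 / 15, c(4, 4, 4, 15)))$K, 15L)
  expect_equal(as_prior_atlas(array(1 / 3, c(4, 4, 4, 3)))$K, 3L)
})

test_that("boundary negatives follow the Chebyshev-margin definition", {
  d <- c(30, 30, 30)
  lab <- array(0L, d)
  lab[14:16, 14:16, 14:16] <- 1L  # 3^3 cube deep inside
  lm <- as_label_map(lab, class_count = 2)
  s <- sample_structures(lm, margin = 5)
  expect_equal(nrow(s$positives), 27L)
  expect_equal(nrow(s$negatives), 13^3 - 3^3)  # 2170

  # all negatives within Chebyshev distance 5 of a positive; none overlap
  pos <- s$positives[, 1:3, drop = FALSE]
  cheb <- apply(s$negatives, 1, function(v) {
    min(apply(abs(sweep(pos, 2, v)), 1, max))
  })
  expect_true(all(cheb >= 1 & cheb <= 5))

  expect_equal(nrow(sample_structures(lm, margin = 0)$negatives), 0L)
  expect_error(sample_structures(as_label_map(array(0L, d), class_count = 2)),
               "sampling error")
})

test_that("touching structures of different classes are never negatives", {
  d <- c(20, 20, 20)
  lab <- array(0L, d)
  lab[8:10, 8:10, 8:10] <- 1L
  lab[11:13, 8:10, 8:10] <- 2L  # face-adjacent to class 1
  lm <- as_label_map(lab, class_count = 3)
  s <- sample_structures(lm, margin = 5)
  expect_equal(sum(s$positives[, "class"] == 1), 27L)
  expect_equal(sum(s$positives[, "class"] == 2), 27L)
  lin_pos <- s$positives[, 1] + (s$positives[, 2] - 1) * d[1] +
    (s$positives[, 3] - 1) * d[1] * d[2]
  lin_neg <- s$negatives[, 1] + (s$negatives[, 2] - 1) * d[1] +
    (s$negatives[, 3] - 1) * d[1] * d[2]
  expect_length(intersect(lin_pos, lin_neg), 0L)
})

test_that("stage-1 lesion sampling is balanced, seeded, and guarded", {
  d <- c(20, 20, 20)
  lab <- array(0L, d)
  lab[5:9, 5:8, 5:9] <- 1L  # 100 lesion voxels
  lm <- as_label_map(lab, class_count = 2)
  brain <- array(TRUE, d)
  s <- sample_lesions_stage1(lm, brain, seed = 7)
  expect_equal(nrow(s$positives), 100L)
  expect_equal(nrow(s$negatives), 100L)
  s2 <- sample_lesions_stage1(lm, brain, seed = 7)
  expect_identical(s$negatives, s2$negatives)
  s3 <- sample_lesions_stage1(lm, brain, seed = 8)
  expect_false(identical(s$negatives, s3$negatives))
  # negatives never hit lesion voxels
  lin_neg <- s$negatives[, 1] + (s$negatives[, 2] - 1) * d[1] +
    (s$negatives[, 3] - 1) * d[1] * d[2]
  expect_true(all(lab[lin_neg] == 0L))
  # lesions covering the whole brain leave no negatives to draw
  expect_error(sample_lesions_stage1(lm, lab == 1L, seed = 1), "sampling error")
})

test_that("stage-2 negatives come from stage-1 false positives, topped up if scarce", {
  d <- c(20, 20, 20)
  lab <- array(0L, d)
  lab[5:9, 5:8, 5:9] <- 1L  # 100 positives
  lm <- as_label_map(lab, class_count = 2)
  brain <- array(TRUE, d)

  # 40 false positives -> all used, 60 drawn from elsewhere
  pred <- lab
  pred[12:15, 12:13, 12:16] <- 1L  # 4*2*5 = 40 FP voxels
  pm <- as_label_map(pred, class_count = 2)
  s <- sample_lesions_stage2(lm, pm, brain, seed = 3)
  expect_equal(s$n_false_positive, 40L)
  expect_equal(nrow(s$negatives), 100L)
  lin <- function(m) m[, 1] + (m[, 2] - 1) * d[1] + (m[, 3] - 1) * d[1] * d[2]
  fp_lin <- which(pred != 0L & lab == 0L)
  expect_true(all(fp_lin %in% lin(s$negatives)))

  # >= 100 false positives -> exactly 100 negatives, all FPs
  pred2 <- lab
  pred2[12:16, 12:16, 12:16] <- 1L  # 125 FPs
  s2 <- sample_lesions_stage2(lm, as_label_map(pred2, class_count = 2), brain,
                              seed = 3)
  expect_equal(nrow(s2$negatives), 100L)
  expect_true(all(lin(s2$negatives) %in% which(pred2 != 0L & lab == 0L)))

  # perfect stage-1 prediction -> fallback to random brain negatives
  s3 <- sample_lesions_stage2(lm, lm, brain, seed = 3)
  expect_equal(s3$n_false_positive, 0L)
  expect_equal(nrow(s3$negatives), 100L)
  expect_true(all(lab[lin(s3$negatives)] == 0L))
})

test_that("train/validation splits are exhaustive, disjoint, and seeded", {
  s <- split_train_val(100, 0.25, seed = 1)
  expect_length(s$train, 75L)
  expect_length(s$val, 25L)
  expect_identical(sort(c(s$train, s$val)), 1:100)

  s8 <- split_train_val(8, 0.25, seed = 2)
  expect_length(s8$train, 6L)
  expect_length(s8$val, 2L)

  expect_identical(split_train_val(40, 0.25, seed = 9),
                   split_train_val(40, 0.25, seed = 9))
  expect_error(split_train_val(3), "at least 4")
  expect_error(split_train_val(10, 0), "val_fraction")
})

test_that("the atlas ROI is the dilated support of the non-background channels", {
  d <- c(15, 15, 15)
  arr <- array(0, c(d, 3))
  arr[7:9, 7:9, 7:9, 2] <- 0.9
  arr[, , , 1] <- 1 - apply(arr[, , , 2:3, drop = FALSE], c(1, 2, 3), sum)
  at <- as_prior_atlas(arr)
  roi2 <- roi_from_priors(at, dilation_radius = 2)
  expected <- array(FALSE, d); expected[5:11, 5:11, 5:11] <- TRUE
  expect_identical(roi2, expected)
  roi0 <- roi_from_priors(at, dilation_radius = 0)
  expect_equal(sum(roi0), 27L)
  # empty atlas support -> empty ROI
  arr0 <- array(0, c(d, 3)); arr0[, , , 1] <- 1
  expect_equal(sum(roi_from_priors(as_prior_atlas(arr0), 5)), 0L)
})

test_that("balancing caps the negative share reproducibly", {
  d <- c(30, 30, 30)
  lab <- array(0L, d); lab[14:16, 14:16, 14:16] <- 1L
  s <- sample_structures(as_label_map(lab, class_count = 2), margin = 5)
  b <- balance_sampling(s, neg_ratio = 5, seed = 2)
  expect_equal(nrow(b$negatives), 135L)  # 5 * 27 positives
  expect_identical(balance_sampling(s, 5, seed = 2)$negatives, b$negatives)
  expect_identical(balance_sampling(s, Inf, seed = 2)$negatives, s$negatives)
})
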