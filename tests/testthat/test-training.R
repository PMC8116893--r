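# Supervised training, early stopping, cascaded lesion training, and the
# transductive adaptation loop.

make_separable_samples <- function(spec, n = 60, seed = 2) {
  hmadapt:::with_seed(seed, {
    P <- spec$patch_size^2
    y <- rep(1:2, length.out = n)
    centre <- ifelse(y == 1, -1, 1)
    X <- lapply(1:3, function(p) {
      matrix(stats::rnorm(n * P, mean = centre, sd = 0.3), n)
    })
    names(X) <- c("axial", "sagittal", "coronal")
    list(X = X, prior = matrix(1 / spec$prior_units, n, spec$prior_units),
         y = y)
  })
}

test_that("training solves a separable problem and is fully deterministic", {
  spec <- micro_spec("lesions")
  samples <- make_separable_samples(spec)
  cfg <- train_config(batch_size = 16, max_epochs = 20, patience = 10, seed = 3)
  fit <- train_initial(build_network(spec, seed = 3), samples, cfg)
  expect_gte(fit$state$best_val_accuracy, 0.95)
  expect_lte(fit$state$epoch, 20L)

  fit2 <- train_initial(build_network(spec, seed = 3), samples, cfg)
  expect_identical(fit$state$history, fit2$state$history)
  expect_identical(fit$weights, fit2$weights)
})

test_that("early stopping halts patience epochs after the best epoch", {
  spec <- micro_spec("lesions")
  samples <- make_separable_samples(spec)
  cfg <- train_config(batch_size = 16, max_epochs = 40, patience = 4, seed = 5)
  fit <- train_initial(build_network(spec, seed = 5), samples, cfg)
  st <- fit$state
  if (st$epoch < cfg$max_epochs) {
    expect_equal(st$epoch, st$best_epoch + cfg$patience)
    expect_equal(st$epochs_since_best, cfg$patience)
  }
  # best-epoch weights are restored: validation accuracy of the returned
  # network equals the recorded best
  expect_equal(max(st$history$val_accuracy), st$best_val_accuracy)
  expect_error(train_initial(build_network(spec, 1),
                             list(X = samples$X, prior = samples$prior, y = NULL)),
               "training error")
})

test_that("cascaded lesion training draws stage-2 negatives from stage-1 errors", {
  sc <- phantom_scene(shape = c(20, 20, 20), mode = "lesions", n_lesions = 3,
                      seed = 11)
  ph <- render_phantom(sc)
  spec <- tiny_network_spec("lesions")
  cfg <- train_config(batch_size = 32, max_epochs = 6, patience = 3, seed = 4)
  fit <- train_cascaded(spec, ph$volume, ph$label, ph$atlas, ph$brain_mask, cfg)
  expect_s3_class(fit, "cascade_fit")
  expect_true(any(fit$stage1_prediction$labels$data != 0L))
  # the stage-2 negative set contains every stage-1 false positive up to the
  # balance cap
  d <- dim(ph$label$data)
  fp <- which(fit$stage1_prediction$labels$data != 0L & ph$label$data == 0L)
  neg <- fit$stage2_sampling$negatives
  neg_lin <- neg[, 1] + (neg[, 2] - 1) * d[1] + (neg[, 3] - 1) * d[1] * d[2]
  npos <- nrow(fit$stage2_sampling$positives)
  expect_equal(nrow(neg), npos)
  if (length(fp) >= npos) {
    expect_true(all(neg_lin %in% fp))
  } else {
    expect_true(all(fp %in% neg_lin))
  }
  # the stage-2 network segments the training image sensibly end to end
  seg2 <- segment_volume(fit$stage2, ph$volume, ph$atlas,
                         brain_mask = ph$brain_mask)
  expect_s3_class(seg2, "segmentation_result")
})

test_that("with lambda = 0 the target case has no effect on adaptation", {
  sc <- phantom_scene(shape = c(24, 24, 24), seed = 6)
  pair <- make_domain_pair(sc, 1, 2,
                           shift = domain_shift(gamma = 1.8, seed = 2), seed = 6)
  spec <- tiny_network_spec("structures")
  svol <- normalize_intensity(pair$source[[1]]$volume,
                              mask = pair$source[[1]]$brain_mask)
  sampling <- balance_sampling(sample_structures(pair$source[[1]]$label, 5),
                               neg_ratio = 3, seed = 1)
  samples <- assemble_samples(svol, pair$source[[1]]$atlas, sampling,
                              spec$patch_size)
  base <- train_initial(build_network(spec, seed = 6), samples,
                        train_config(batch_size = 64, max_epochs = 4,
                                     patience = 2, seed = 6))
  cfg <- train_config(learning_rate = 1e-4, max_epochs = 2, patience = 1,
                      seed = 9)
  a1 <- adapt_transductive(base, pair$source[[1]], pair$target[[1]],
                           align = hist_align_config(lambda_weight = 0),
                           config = cfg)
  a2 <- adapt_transductive(base, pair$source[[1]], pair$target[[2]],
                           align = hist_align_config(lambda_weight = 0),
                           config = cfg)
  expect_identical(a1$weights, a2$weights)

  # with lambda > 0 the target does steer the optimisation
  b1 <- adapt_transductive(base, pair$source[[1]], pair$target[[1]],
                           align = hist_align_config(lambda_weight = 1),
                           config = cfg)
  b2 <- adapt_transductive(base, pair$source[[1]], pair$target[[2]],
                           align = hist_align_config(lambda_weight = 1),
                           config = cfg)
  expect_false(identical(b1$weights, b2$weights))
  expect_true(all(is.finite(b1$state$history$hist)))
  expect_true(all(b1$state$history$hist >= 0))
  # the logged breakdown satisfies total = ce + lambda * hist
  expect_equal(b1$state$history$total,
               b1$state$history$ce + 1 * b1$state$history$hist,
               tolerance = 1e-9)
})

test_that("the adaptation interface rejects labelled targets and task mismatches", {
  sc <- phantom_scene(shape = c(24, 24, 24), seed = 6)
  pair <- make_domain_pair(sc, 1, 1, domain_shift(), seed = 3)
  spec <- tiny_network_spec("structures")
  net <- build_network(spec, seed = 1)
  tgt_labelled <- c(pair$target[[1]], list(label = pair$target_truth[[1]]))
  expect_error(adapt_transductive(net, pair$source[[1]], tgt_labelled),
               "must not carry labels")
  net_wrong <- build_network(tiny_network_spec("lesions"), seed = 1)
  expect_error(adapt_transductive(net_wrong, pair$source[[1]], pair$target[[1]]),
               "adaptation error")
})
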