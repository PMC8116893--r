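# Supervised initial training, cascaded lesion training, and the
# transductive adaptation loop.

# --- weight-tree utilities and Adam -----------------------------------------

tree_map <- function(a, f) {
  if (is.list(a)) lapply(a, tree_map, f = f) else f(a)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) Map(function(x, y) tree_map2(x, y, f), a, b) else f(a, b)
}

tree_grad_norm <- function(g) {
  s <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else s <<- s + sum(x^2)
    invisible(NULL)
  }
  walk(g)
  sqrt(s)
}

adam_init <- function(weights) {
  list(m = tree_map(weights, function(x) x * 0),
       v = tree_map(weights, function(x) x * 0),
       t = 0L)
}

adam_update <- function(weights, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- tree_map2(state$m, state$v, function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  weights <- tree_map2(weights, step, function(w, s) w - lr * s)
  list(weights = weights, state = state)
}

# --- configuration and sample assembly --------------------------------------

#' Training configuration
#'
#' Defaults follow the reference training protocol: batches of 128, up to
#' 200 epochs, early stopping with patience 20 on validation accuracy, Adam
#' with learning rate 1e-2 (reduce to 1e-4 for the adaptation phase to avoid
#' rapid weight updates on an already-trained network).
#'
#' @param batch_size Mini-batch size for supervised training.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without a validation
#'   accuracy increase); must be below `max_epochs`.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed for the split, shuffling, and sampling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 128, max_epochs = 200, patience = 20,
                         learning_rate = 1e-2, seed = 1) {
  stopifnot(patience < max_epochs, learning_rate > 0, batch_size >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Assemble labelled patch samples from sampled voxels
#'
#' Builds the 2.5D patch matrices and prior vectors for the voxel sets
#' produced by the sampling functions. Class coding is 1-based with class 1
#' = background: structure class c maps to c + 1; lesion voxels map to 2.
#'
#' @param volume A (normalised) `volume`.
#' @param atlas The matching `prior_atlas`.
#' @param sampling Output of [sample_structures()], [sample_lesions_stage1()]
#'   or [sample_lesions_stage2()].
#' @param patch_size Patch side length (from the network spec).
#' @return List with `X` (three n x S^2 patch matrices), `prior` (n x K),
#'   `y` (integer labels), `voxels`.
#' @export
assemble_samples <- function(volume, atlas, sampling, patch_size) {
  pos <- sampling$positives
  neg <- sampling$negatives
  ycls <- if (ncol(pos) >= 4L) pos[, 4] + 1L else rep(2L, nrow(pos))
  vox <- rbind(pos[, 1:3, drop = FALSE],
               if (length(neg)) neg[, 1:3, drop = FALSE])
  y <- c(ycls, rep(1L, if (length(neg)) nrow(neg) else 0L))
  b <- build_patch_batch(volume, atlas, vox, patch_size)
  list(X = b$X, prior = b$prior, y = as.integer(y), voxels = vox)
}

subset_samples <- function(samples, idx) {
  list(X = lapply(samples$X, function(m) m[idx, , drop = FALSE]),
       prior = samples$prior[idx, , drop = FALSE],
       y = if (!is.null(samples$y)) samples$y[idx])
}

predict_probs <- function(net, samples, chunk = 1024L) {
  n <- nrow(samples$prior)
  out <- matrix(0, n, net$spec$out_classes)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    sub <- subset_samples(samples, idx)
    out[idx, ] <- net_forward(net, sub$X, sub$prior)$probs
  }
  out
}

# --- supervised training ----------------------------------------------------

#' Supervised training with early stopping
#'
#' Minimises categorical cross-entropy with Adam over mini-batches, using a
#' seeded 75/25 train/validation split; stops when validation accuracy has
#' not increased for `patience` consecutive epochs and restores the
#' best-validation weights. Fully deterministic given `config$seed`.
#'
#' @param net A `patch_cnn` (freshly built or pre-trained).
#' @param samples Labelled samples from [assemble_samples()].
#' @param config A [train_config()].
#' @param val_fraction Validation fraction (default 0.25).
#' @return The trained `patch_cnn`, with `$state` (epoch counts, best
#'   validation accuracy, per-epoch history data frame).
#' @export
train_initial <- function(net, samples, config = train_config(),
                          val_fraction = 0.25) {
  stopifnot(inherits(net, "patch_cnn"))
  if (is.null(samples$y) || !length(samples$y)) stop("training error: no labelled samples")
  if (max(samples$y) > net$spec$out_classes) {
    stop("training error: label exceeds the network's class count")
  }
  n <- length(samples$y)
  split <- split_train_val(n, val_fraction, config$seed)
  tr <- subset_samples(samples, split$train)
  va <- subset_samples(samples, split$val)
  n_tr <- length(split$train)

  weights <- net$weights
  opt <- adam_init(weights)
  best <- list(acc = -Inf, weights = weights, epoch = 0L)
  since_best <- 0L
  hist_rows <- vector("list", config$max_epochs)
  net_tmp <- net

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n_tr)
      losses <- c()
      for (s in seq(1L, n_tr, by = config$batch_size)) {
        idx <- perm[s:min(n_tr, s + config$batch_size - 1L)]
        sub <- subset_samples(tr, idx)
        net_tmp$weights <- weights
        fw <- net_forward(net_tmp, sub$X, sub$prior, keep_cache = TRUE)
        cg <- ce_loss_grad(fw$probs, sub$y)
        g <- net_backward(net_tmp, fw$cache, cg$dlogits)
        upd <- adam_update(weights, g, opt, config$learning_rate)
        weights <- upd$weights
        opt <- upd$state
        losses <- c(losses, cg$loss)
      }
      net_tmp$weights <- weights
      acc <- mean(max.col(predict_probs(net_tmp, va)) == va$y)
      if (acc > best$acc) {
        best <- list(acc = acc, weights = weights, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      hist_rows[[epoch]] <- data.frame(epoch = epoch,
                                       train_loss = mean(losses),
                                       val_accuracy = acc)
      if (since_best >= config$patience) break
    }
  })
  net$weights <- best$weights
  net$state <- list(epoch = max(vapply(Filter(Negate(is.null), hist_rows),
                                       function(r) r$epoch, numeric(1))),
                    best_epoch = best$epoch,
                    best_val_accuracy = best$acc,
                    epochs_since_best = since_best,
                    history = do.call(rbind, Filter(Negate(is.null), hist_rows)))
  net
}

#' Two-stage cascaded lesion training
#'
#' Stage 1 trains on all lesion voxels against an equal number of random
#' non-lesion brain voxels; the stage-1 network then segments the same
#' training image and stage 2 retrains from scratch with negatives drawn
#' from the stage-1 false positives — a false-positive-reduction step. The
#' stage-2 network is the deliverable.
#'
#' @param spec A lesions-mode `network_spec`.
#' @param volume,label,atlas,brain_mask One training case (volume is
#'   normalised internally).
#' @param config A [train_config()].
#' @param threshold Lesion probability threshold for the intermediate
#'   stage-1 segmentation (default 0.5).
#' @return A list of class `cascade_fit` with `stage1`, `stage2` (trained
#'   `patch_cnn`s), `stage1_prediction`, and `stage2_sampling`.
#' @export
train_cascaded <- function(spec, volume, label, atlas, brain_mask,
                           config = train_config(), threshold = 0.5) {
  stopifnot(inherits(spec, "network_spec"), spec$mode == "lesions")
  voln <- normalize_intensity(volume, mask = brain_mask)
  s1 <- sample_lesions_stage1(label, brain_mask, seed = config$seed)
  samples1 <- assemble_samples(voln, atlas, s1, spec$patch_size)
  net1 <- train_initial(build_network(spec, seed = config$seed), samples1, config)
  pred1 <- segment_volume(net1, voln, atlas, threshold = threshold,
                          brain_mask = brain_mask, normalize = FALSE)
  if (!any(pred1$labels$data != 0L)) {
    stop("cascade error: the stage-1 network predicted no lesion voxels; ",
         "check training convergence (best val accuracy ",
         signif(net1$state$best_val_accuracy, 3), ")")
  }
  s2 <- sample_lesions_stage2(label, pred1$labels, brain_mask,
                              seed = config$seed + 1L)
  samples2 <- assemble_samples(voln, atlas, s2, spec$patch_size)
  cfg2 <- config
  cfg2$seed <- config$seed + 1L
  net2 <- train_initial(build_network(spec, seed = cfg2$seed), samples2, cfg2)
  structure(list(stage1 = net1, stage2 = net2, stage1_prediction = pred1,
                 stage2_sampling = s2),
            class = "cascade_fit")
}

#' @export
print.cascade_fit <- function(x, ...) {
  cat("<cascade_fit> two-stage lesion model\n")
  cat("  stage-1 false-positive voxels: ", x$stage2_sampling$n_false_positive,
      "\n", sep = "")
  print(x$stage2)
  invisible(x)
}

# --- transductive adaptation ------------------------------------------------

#' Transductive domain adaptation of a pre-trained network
#'
#' Jointly optimises segmentation cross-entropy on the labelled source case
#' and the histogram-alignment loss between source and target activation
#' distributions, at a reduced learning rate. Each step draws one source
#' batch and one target batch of `align$match_batch` samples; the target
#' batch contributes only its activation distribution (its labels are never
#' read — the target case must not carry any). Early stopping monitors
#' held-out source validation accuracy, since no target labels exist.
#'
#' One source and one target image suffice: the histogram loss compares
#' feature distributions pooled over batches, for which a single volume
#' provides ample samples.
#'
#' @param net A pre-trained `patch_cnn` for the same task.
#' @param source_case List with `volume`, `label`, `atlas` (and, lesions
#'   mode, `brain_mask`).
#' @param target_case List with `volume`, `atlas` (and `brain_mask`);
#'   passing a `label` is an error by design.
#' @param align A [hist_align_config()].
#' @param config A [train_config()]; the default uses learning rate 1e-4.
#' @param boundary_margin Structure-mode boundary-negative margin.
#' @param neg_ratio Maximum boundary negatives per positive in the source
#'   sample (see [balance_sampling()]); `Inf` keeps all.
#' @return The adapted `patch_cnn` with `$state$history` carrying per-epoch
#'   cross-entropy and histogram loss aggregates.
#' @export
adapt_transductive <- function(net, source_case, target_case,
                               align = hist_align_config(),
                               config = train_config(learning_rate = 1e-4,
                                                     max_epochs = 10,
                                                     patience = 3),
                               boundary_margin = 5, neg_ratio = 5) {
  stopifnot(inherits(net, "patch_cnn"), inherits(align, "hist_align_config"))
  if (!is.null(target_case$label)) {
    stop("adaptation error: the target case must not carry labels ",
         "(transductive adaptation is unsupervised on the target)")
  }
  if (net$spec$prior_units != source_case$atlas$K ||
      net$spec$prior_units != target_case$atlas$K) {
    stop("adaptation error: atlas channel count does not match the network")
  }
  taps <- if (is.null(align$taps)) net$spec$taps else align$taps

  src_brain <- if (!is.null(source_case$brain_mask)) source_case$brain_mask else
    source_case$volume$data != 0
  tgt_brain <- if (!is.null(target_case$brain_mask)) target_case$brain_mask else
    target_case$volume$data != 0
  svol <- normalize_intensity(source_case$volume, mask = src_brain)
  tvol <- normalize_intensity(target_case$volume, mask = tgt_brain)

  # Two sampling laws serve two roles. The cross-entropy anchor uses the
  # same labelled sampler as initial training, so with lambda = 0 (or an
  # identity shift) adaptation reduces to fine-tuning on the training
  # distribution and leaves a converged model where it is. The histogram
  # loss instead needs source and target batches drawn by the SAME spatial
  # law — otherwise it aligns the difference between two sampling schemes
  # rather than the domain shift — and the only law available without
  # target labels is atlas-driven: the boundary sampler applied to each
  # domain's atlas-argmax pseudo-labels (structures), or uniform brain
  # voxels (lesions).
  ce_sampling <- if (net$spec$mode == "structures") {
    balance_sampling(sample_structures(source_case$label, margin = boundary_margin),
                     neg_ratio, seed = config$seed)
  } else {
    sample_lesions_stage1(source_case$label, src_brain, seed = config$seed)
  }
  samples <- assemble_samples(svol, source_case$atlas, ce_sampling,
                              net$spec$patch_size)
  n <- length(samples$y)
  split <- split_train_val(n, 0.25, config$seed)
  tr <- subset_samples(samples, split$train)
  va <- subset_samples(samples, split$val)
  n_tr <- length(split$train)

  pseudo_pool <- function(atlas, spacing) {
    am <- apply(atlas$data, c(1, 2, 3), which.max) - 1L
    pseudo <- as_label_map(array(as.integer(am), dim(am)), spacing = spacing,
                           class_count = atlas$K)
    ps <- balance_sampling(sample_structures(pseudo, margin = boundary_margin),
                           neg_ratio, seed = config$seed)
    rbind(ps$positives[, 1:3, drop = FALSE], ps$negatives)
  }
  if (net$spec$mode == "structures") {
    src_hist_pool <- pseudo_pool(source_case$atlas, source_case$volume$spacing)
    tgt_pool <- pseudo_pool(target_case$atlas, target_case$volume$spacing)
  } else {
    src_hist_pool <- arrayInd(which(src_brain), dim(source_case$volume$data))
    tgt_pool <- arrayInd(which(tgt_brain), dim(target_case$volume$data))
  }
  mb <- align$match_batch
  P <- net$geom$P

  weights <- net$weights
  opt <- adam_init(weights)
  best <- list(acc = -Inf, weights = weights, epoch = 0L)
  since_best <- 0L
  hist_rows <- list()
  net_tmp <- net

  with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n_tr)
      ce_acc <- c(); hist_acc <- c()
      for (s in seq(1L, n_tr, by = mb)) {
        idx <- perm[s:min(n_tr, s + mb - 1L)]
        sub <- subset_samples(tr, idx)
        nce <- length(idx)
        net_tmp$weights <- weights
        use_hist <- align$lambda_weight > 0
        if (use_hist) {
          # source histogram batch rides the same forward pass as the CE
          # batch: CE gradients flow into the first nce rows, alignment
          # gradients into the remaining mb rows
          sv <- src_hist_pool[sample.int(nrow(src_hist_pool), mb,
                                         replace = nrow(src_hist_pool) < mb), ,
                              drop = FALSE]
          sb <- build_patch_batch(svol, source_case$atlas, sv,
                                  net$spec$patch_size)
          X <- Map(rbind, sub$X, sb$X)
          prior <- rbind(sub$prior, sb$prior)
        } else {
          X <- sub$X
          prior <- sub$prior
        }
        ntot <- nrow(prior)
        fw <- net_forward(net_tmp, X, prior,
                          taps = if (use_hist) taps else character(0),
                          keep_cache = TRUE)
        cg <- ce_loss_grad(fw$probs[seq_len(nce), , drop = FALSE], sub$y)
        dlogits <- matrix(0, ntot, ncol(fw$probs))
        dlogits[seq_len(nce), ] <- cg$dlogits
        dacts <- list()
        hl_total <- 0
        if (use_hist) {
          tv <- tgt_pool[sample.int(nrow(tgt_pool), mb,
                                    replace = nrow(tgt_pool) < mb), , drop = FALSE]
          tb <- build_patch_batch(tvol, target_case$atlas, tv, net$spec$patch_size)
          tw <- net_forward(net_tmp, tb$X, tb$prior, taps = taps)
          hist_rows_of <- function(a) {
            if (nrow(a) == ntot) a[(nce + 1L):ntot, , drop = FALSE]
            else a[(nce * P + 1L):(ntot * P), , drop = FALSE]
          }
          hl <- histogram_loss(lapply(fw$acts, hist_rows_of), tw$acts, align,
                               want_grads = TRUE)
          hl_total <- hl$total
          dacts <- Map(function(a, gmat) {
            z <- a * 0
            if (nrow(a) == ntot) {
              z[(nce + 1L):ntot, ] <- align$lambda_weight * gmat
            } else {
              z[(nce * P + 1L):(ntot * P), ] <- align$lambda_weight * gmat
            }
            z
          }, fw$acts, hl$grads)
        }
        g <- net_backward(net_tmp, fw$cache, dlogits, dacts)
        upd <- adam_update(weights, g, opt, config$learning_rate)
        weights <- upd$weights
        opt <- upd$state
        ce_acc <- c(ce_acc, cg$loss)
        hist_acc <- c(hist_acc, hl_total)
      }
      net_tmp$weights <- weights
      acc <- mean(max.col(predict_probs(net_tmp, va)) == va$y)
      if (acc > best$acc) {
        best <- list(acc = acc, weights = weights, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, ce = mean(ce_acc), hist = mean(hist_acc),
        lambda = align$lambda_weight,
        total = mean(ce_acc) + align$lambda_weight * mean(hist_acc),
        val_accuracy = acc)
      if (since_best >= config$patience) break
    }
  })
  net$weights <- best$weights
  net$state <- list(epoch = length(hist_rows),
                    best_epoch = best$epoch,
                    best_val_accuracy = best$acc,
                    epochs_since_best = since_best,
                    history = do.call(rbind, hist_rows),
                    adapted = TRUE)
  net
}
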