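# The 2.5D patch CNN: three convolutional paths (one per orthogonal view),
# a spatial-prior branch concatenated before the fully connected head, and a
# softmax classifier. Implemented directly on BLAS matrix operations
# (im2col convolution) with hand-written reverse-mode gradients, which keeps
# the package self-contained and is fast enough at the patch sizes used here.
#
# Activations are stored sample-major: conv activations as (n * P) x C
# matrices (P = patch pixels, row = (sample - 1) * P + pixel), fully
# connected activations as n x F matrices. Named "tap" layers expose their
# post-ReLU activations for the histogram-alignment loss; the classifier
# layer can never be tapped.

#' Specify a patch-CNN architecture
#'
#' Defaults follow the reference architecture: 32 x 32 patches, five
#' convolution layers per path followed by one fully connected layer per
#' path, prior vector of length 15 and 15 output classes in structures mode
#' (3 and 2 in lesions mode), and two fully connected head layers before the
#' classifier. The default tap layers — where activations are exposed for
#' distribution alignment — are the last three convolution layers of each
#' path plus every fully connected layer except the classifier.
#'
#' @param mode `"structures"` or `"lesions"`.
#' @param patch_size Patch side length S.
#' @param conv_channels Integer vector of channel counts, one per
#'   convolution layer per path.
#' @param kernel Odd convolution kernel size (same padding, stride 1).
#' @param path_fc Units in the per-path fully connected layer.
#' @param head_fc Integer vector of head fully connected layer sizes.
#' @param prior_units Length K of the spatial-prior vector.
#' @param out_classes Number of output classes.
#' @param taps Character vector of tap layer names; defaults as described.
#'   Valid names are `p<path>c<layer>`, `p<path>fc`, and `hfc<j>`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(mode = c("structures", "lesions"),
                         patch_size = 32,
                         conv_channels = c(32, 32, 64, 64, 128),
                         kernel = 3,
                         path_fc = 256,
                         head_fc = c(512, 256),
                         prior_units = NULL,
                         out_classes = NULL,
                         taps = NULL) {
  mode <- match.arg(mode)
  if (is.null(prior_units)) prior_units <- if (mode == "structures") 15L else 3L
  if (is.null(out_classes)) out_classes <- if (mode == "structures") 15L else 2L
  stopifnot(patch_size >= kernel, kernel %% 2 == 1, length(conv_channels) >= 1,
            prior_units >= 1, out_classes >= 2)
  n_conv <- length(conv_channels)
  conv_names <- as.vector(t(outer(1:3, seq_len(n_conv),
                                  function(p, l) paste0("p", p, "c", l))))
  fc_names <- paste0("p", 1:3, "fc")
  head_names <- if (length(head_fc)) paste0("hfc", seq_along(head_fc)) else character(0)
  valid <- c(conv_names, fc_names, head_names)
  if (is.null(taps)) {
    last_convs <- max(1L, n_conv - 2L):n_conv
    taps <- c(as.vector(t(outer(1:3, last_convs, function(p, l) paste0("p", p, "c", l)))),
              fc_names, head_names)
  }
  if (!all(taps %in% valid)) {
    stop("invalid tap layer(s): ", paste(setdiff(taps, valid), collapse = ", "),
         " (the classifier cannot be tapped)")
  }
  structure(list(mode = mode, patch_size = as.integer(patch_size),
                 conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), path_fc = as.integer(path_fc),
                 head_fc = as.integer(head_fc),
                 prior_units = as.integer(prior_units),
                 out_classes = as.integer(out_classes),
                 taps = taps, layer_names = valid),
            class = "network_spec")
}

#' A reduced architecture for desk-scale experiments
#'
#' A small instance of the same architecture (9 x 9 patches, three
#' convolution layers per path) used throughout the package's phantom
#' experiments, where volumes are a few tens of voxels per side and
#' structures a few voxels in radius.
#'
#' @param mode `"structures"` or `"lesions"`.
#' @param prior_units,out_classes As in [network_spec()]; defaults match the
#'   phantom scenes (5 classes in structures mode).
#' @param ... Further overrides passed to [network_spec()].
#' @return A `network_spec`.
#' @export
tiny_network_spec <- function(mode = c("structures", "lesions"),
                              prior_units = NULL, out_classes = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "structures") {
    if (is.null(prior_units)) prior_units <- 5L
    if (is.null(out_classes)) out_classes <- 5L
  }
  network_spec(mode = mode, patch_size = 9, conv_channels = c(8, 8, 8),
               kernel = 3, path_fc = 24, head_fc = 32,
               prior_units = prior_units, out_classes = out_classes, ...)
}

conv_geom <- function(S, k) {
  pad <- (k - 1L) %/% 2L
  Sp <- S + 2L * pad
  P <- S * S
  ij <- expand.grid(i = seq_len(S), j = seq_len(S))  # i fastest: column-major pixels
  ip <- (ij$i + pad) + (ij$j + pad - 1L) * Sp
  d <- expand.grid(di = -pad:pad, dj = -pad:pad)
  nidx <- matrix(0L, P, k * k)
  for (t in seq_len(k * k)) {
    nidx[, t] <- (ij$i + pad + d$di[t]) + (ij$j + pad + d$dj[t] - 1L) * Sp
  }
  list(S = S, P = P, Sp = Sp, Ppad = Sp * Sp, k2 = k * k, ip = ip, nidx = nidx)
}

he_init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)

#' Build a patch CNN
#'
#' Instantiates trainable weights (He initialisation, seeded) for a
#' [network_spec()]. The returned object is the model: training functions
#' update its weights in place-by-copy and attach their history, and
#' [predict.patch_cnn()] / [segment_volume()] run whole-volume inference.
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `patch_cnn`.
#' @export
build_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  geom <- conv_geom(spec$patch_size, spec$kernel)
  with_seed(seed, {
    conv <- lapply(1:3, function(p) {
      cin <- 1L
      lapply(seq_along(spec$conv_channels), function(l) {
        cout <- spec$conv_channels[l]
        w <- list(W = he_init(geom$k2 * cin, cout), b = numeric(cout))
        cin <<- cout
        w
      })
    })
    c_last <- spec$conv_channels[length(spec$conv_channels)]
    pfc <- lapply(1:3, function(p) {
      list(W = he_init(geom$P * c_last, spec$path_fc), b = numeric(spec$path_fc))
    })
    dims <- c(3L * spec$path_fc + spec$prior_units, spec$head_fc)
    hfc <- lapply(seq_along(spec$head_fc), function(j) {
      list(W = he_init(dims[j], dims[j + 1L]), b = numeric(dims[j + 1L]))
    })
    out <- list(W = he_init(dims[length(dims)], spec$out_classes),
                b = numeric(spec$out_classes))
    structure(list(spec = spec, geom = geom,
                   weights = list(conv = conv, pfc = pfc, hfc = hfc, out = out),
                   seed = seed, state = NULL),
              class = "patch_cnn")
  })
}

#' @export
print.patch_cnn <- function(x, ...) {
  s <- x$spec
  cat("<patch_cnn> ", s$mode, " mode\n", sep = "")
  cat("  3 paths x [", paste(s$conv_channels, collapse = ", "),
      "] conv (", s$kernel, "x", s$kernel, ") on ", s$patch_size, "x",
      s$patch_size, " patches; path FC ", s$path_fc, "\n", sep = "")
  cat("  prior units ", s$prior_units, "; head FC [",
      paste(s$head_fc, collapse = ", "), "]; ", s$out_classes,
      " output classes\n", sep = "")
  cat("  tap layers: ", paste(s$taps, collapse = ", "), "\n", sep = "")
  cat("  parameters: ", n_parameters(x), "\n", sep = "")
  if (!is.null(x$state)) {
    cat("  trained: ", x$state$epoch, " epochs, best val accuracy ",
        signif(x$state$best_val_accuracy, 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.patch_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$state) && !is.null(object$state$history)) {
    cat("\nTraining history (last rows):\n")
    print(utils::tail(object$state$history, 5))
  }
  invisible(object)
}

n_parameters <- function(net) {
  tot <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else tot <<- tot + length(x)
    invisible(NULL)
  }
  walk(net$weights)
  tot
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

conv_fwd <- function(A, layer, geom, n) {
  Cin <- ncol(A)
  padrows <- rep.int((0:(n - 1L)) * geom$Ppad, rep.int(geom$P, n)) + geom$ip
  Apad <- matrix(0, n * geom$Ppad, Cin)
  Apad[padrows, ] <- A
  base <- padrows - geom$ip  # (sample-1) * Ppad, repeated per pixel
  ic <- matrix(0, n * geom$P, geom$k2 * Cin)
  for (t in seq_len(geom$k2)) {
    ic[, (t - 1L) * Cin + seq_len(Cin)] <- Apad[base + geom$nidx[, t], , drop = FALSE]
  }
  Aout <- add_bias(ic %*% layer$W, layer$b)
  Aout <- Aout * (Aout > 0)
  list(A = Aout, ic = ic, Cin = Cin)
}

conv_bwd <- function(dA, cache, layer, geom, n, need_dA = TRUE) {
  dZ <- dA * (cache$A > 0)
  dW <- crossprod(cache$ic, dZ)
  db <- colSums(dZ)
  if (!need_dA) return(list(dA = NULL, dW = dW, db = db))
  dic <- tcrossprod(dZ, layer$W)
  Cin <- cache$Cin
  padrows <- rep.int((0:(n - 1L)) * geom$Ppad, rep.int(geom$P, n)) + geom$ip
  base <- padrows - geom$ip
  dApad <- matrix(0, n * geom$Ppad, Cin)
  for (t in seq_len(geom$k2)) {
    r <- base + geom$nidx[, t]
    dApad[r, ] <- dApad[r, ] + dic[, (t - 1L) * Cin + seq_len(Cin), drop = FALSE]
  }
  list(dA = dApad[padrows, , drop = FALSE], dW = dW, db = db)
}

dense_fwd <- function(A, layer, relu = TRUE) {
  Z <- add_bias(A %*% layer$W, layer$b)
  if (relu) Z <- Z * (Z > 0)
  Z
}

dense_bwd <- function(dA, A_in, A_out, layer, relu = TRUE) {
  dZ <- if (relu) dA * (A_out > 0) else dA
  list(dA = tcrossprod(dZ, layer$W), dW = crossprod(A_in, dZ), db = colSums(dZ))
}

softmax_rows <- function(Z) {
  m <- apply(Z, 1L, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

# Forward pass on a prepared batch (X: list of 3 n x P matrices in view
# order axial, sagittal, coronal; prior: n x K). Returns logits, class
# probabilities, tapped activations, and (optionally) the autodiff cache.
net_forward <- function(net, X, prior, taps = character(0), keep_cache = FALSE) {
  spec <- net$spec; geom <- net$geom; W <- net$weights
  views <- c("axial", "sagittal", "coronal")
  n <- nrow(prior)
  if (n < 1L) stop("empty batch")
  acts <- list()
  cache <- list(paths = vector("list", 3), n = n)
  feats <- vector("list", 3)
  for (p in 1:3) {
    Xp <- X[[views[p]]]
    A <- matrix(as.vector(t(Xp)), ncol = 1L)  # row = (sample-1)*P + pixel
    convs <- vector("list", length(spec$conv_channels))
    for (l in seq_along(spec$conv_channels)) {
      cf <- conv_fwd(A, W$conv[[p]][[l]], geom, n)
      A <- cf$A
      nm <- paste0("p", p, "c", l)
      if (nm %in% taps) acts[[nm]] <- A
      convs[[l]] <- if (keep_cache) cf else NULL
    }
    Cl <- ncol(A)
    flat <- matrix(aperm(array(A, c(geom$P, n, Cl)), c(2, 1, 3)), n, geom$P * Cl)
    f <- dense_fwd(flat, W$pfc[[p]])
    nm <- paste0("p", p, "fc")
    if (nm %in% taps) acts[[nm]] <- f
    cache$paths[[p]] <- list(convs = convs, flat = flat, f = f, Cl = Cl)
    feats[[p]] <- f
  }
  H <- cbind(feats[[1]], feats[[2]], feats[[3]], prior)
  cache$H0 <- H
  cache$hfc <- vector("list", length(spec$head_fc))
  for (j in seq_along(spec$head_fc)) {
    Hn <- dense_fwd(H, W$hfc[[j]])
    nm <- paste0("hfc", j)
    if (nm %in% taps) acts[[nm]] <- Hn
    cache$hfc[[j]] <- list(A_in = H, A_out = Hn)
    H <- Hn
  }
  logits <- dense_fwd(H, W$out, relu = FALSE)
  cache$H_last <- H
  # keep tap order as declared in the network_spec
  acts <- acts[intersect(taps, names(acts))]
  list(logits = logits, probs = softmax_rows(logits), acts = acts,
       cache = if (keep_cache) cache else NULL)
}

#' Forward pass with tapped activations
#'
#' Runs a batch through the network and captures the post-ReLU activations
#' of the configured tap layers. Capturing never alters the forward result.
#'
#' @param net A `patch_cnn`.
#' @param batch A list with `X` (list of `axial`, `sagittal`, `coronal`
#'   n x S^2 patch matrices) and `prior` (n x K matrix), as produced by
#'   the internal batch builder or assembled by the caller.
#' @param taps Tap layer names; defaults to the network spec's taps.
#' @return List with `probs` (n x C class probabilities) and `acts` (named
#'   list of activation matrices in tap order).
#' @export
forward_with_activations <- function(net, batch, taps = net$spec$taps) {
  stopifnot(inherits(net, "patch_cnn"))
  if (is.null(batch$prior) || nrow(batch$prior) < 1L) stop("empty batch")
  fw <- net_forward(net, batch$X, batch$prior, taps = taps)
  list(probs = fw$probs, acts = fw$acts)
}

# Reverse pass. dlogits: n x C gradient at the logits (may be all zero);
# dacts: named list of gradients injected at tap activations (post-ReLU).
# Returns gradients in the same nested structure as net$weights.
net_backward <- function(net, cache, dlogits, dacts = list()) {
  spec <- net$spec; geom <- net$geom; W <- net$weights
  n <- cache$n
  g <- list(conv = lapply(1:3, function(p) vector("list", length(spec$conv_channels))),
            pfc = vector("list", 3), hfc = vector("list", length(spec$head_fc)),
            out = NULL)
  bo <- dense_bwd(dlogits, cache$H_last, NULL, W$out, relu = FALSE)
  g$out <- list(W = bo$dW, b = bo$db)
  dH <- bo$dA
  for (j in rev(seq_along(spec$head_fc))) {
    nm <- paste0("hfc", j)
    if (!is.null(dacts[[nm]])) dH <- dH + dacts[[nm]]
    bh <- dense_bwd(dH, cache$hfc[[j]]$A_in, cache$hfc[[j]]$A_out, W$hfc[[j]])
    g$hfc[[j]] <- list(W = bh$dW, b = bh$db)
    dH <- bh$dA
  }
  Fp <- spec$path_fc
  for (p in 1:3) {
    pc <- cache$paths[[p]]
    df <- dH[, (p - 1L) * Fp + seq_len(Fp), drop = FALSE]
    nm <- paste0("p", p, "fc")
    if (!is.null(dacts[[nm]])) df <- df + dacts[[nm]]
    bp <- dense_bwd(df, pc$flat, pc$f, W$pfc[[p]])
    g$pfc[[p]] <- list(W = bp$dW, b = bp$db)
    Cl <- pc$Cl
    dA <- matrix(aperm(array(bp$dA, c(n, geom$P, Cl)), c(2, 1, 3)), n * geom$P, Cl)
    for (l in rev(seq_along(spec$conv_channels))) {
      nm <- paste0("p", p, "c", l)
      if (!is.null(dacts[[nm]])) dA <- dA + dacts[[nm]]
      bc <- conv_bwd(dA, pc$convs[[l]], W$conv[[p]][[l]], geom, n,
                     need_dA = l > 1L)  # the input itself needs no gradient
      g$conv[[p]][[l]] <- list(W = bc$dW, b = bc$db)
      dA <- bc$dA
    }
  }
  g
}

# Categorical cross-entropy; y: integer class in 1..C. Returns loss and the
# gradient at the logits (mean reduction).
ce_loss_grad <- function(probs, y) {
  n <- nrow(probs)
  p <- pmax(probs[cbind(seq_len(n), y)], 1e-12)
  loss <- -mean(log(p))
  Y <- matrix(0, n, ncol(probs))
  Y[cbind(seq_len(n), y)] <- 1
  list(loss = loss, dlogits = (probs - Y) / n)
}
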