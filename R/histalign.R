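# Feature-distribution histogram matching and the joint adaptation loss.
#
# The alignment loss treats each tapped layer's batch activations as a value
# distribution: the source activations A_i are histogram-matched onto the
# target activations B_i (a monotone CDF/quantile mapping), the matched
# tensor H(A_i, B_i) is held constant with respect to differentiation, and
# the log-cosh distance between A_i and H(A_i, B_i), summed over layers, is
# added to the segmentation cross-entropy with weight lambda. Minimising it
# pushes the network to produce source feature distributions that look like
# the target's, while the cross-entropy term keeps the features usable for
# classification.

#' Configuration of the histogram-alignment loss
#'
#' @param lambda_weight Non-negative weight of the histogram loss in the
#'   total objective (default 1, the recommended operating point; the method
#'   is insensitive within roughly 1 +/- 0.6).
#' @param match_batch Batch size over which layer activations are pooled for
#'   matching (default 32). Matching per batch rather than per sample is
#'   required: single-sample histograms vary too much across brain locations.
#' @param bins Number of quantile knots of the CDF interpolation (default
#'   256); with at least as many knots as target values the mapping is the
#'   exact rank mapping.
#' @param taps Optional tap-layer subset; defaults to the network's taps.
#' @param per_channel If TRUE, match each channel of a convolutional tap
#'   separately instead of pooling the whole layer (off by default).
#' @return An object of class `hist_align_config`.
#' @export
hist_align_config <- function(lambda_weight = 1.0, match_batch = 32,
                              bins = 256, taps = NULL, per_channel = FALSE) {
  stopifnot(lambda_weight >= 0, bins >= 2, match_batch >= 2)
  structure(list(lambda_weight = lambda_weight,
                 match_batch = as.integer(match_batch),
                 bins = as.integer(bins), taps = taps,
                 per_channel = isTRUE(per_channel)),
            class = "hist_align_config")
}

#' Histogram-match one value multiset onto another
#'
#' Monotone CDF-based mapping: each source value is replaced by the
#' target-distribution quantile at its own source-CDF position. The output
#' preserves the source's shape and value ranks; tied source values map to
#' the same target quantile; outputs lie within `[min(target), max(target)]`.
#' For equal-size tie-free inputs with `bins >= length(target)` this reduces
#' to the exact rank mapping `sorted(source)[k] -> sorted(target)[k]`.
#'
#' @param source Numeric vector, matrix, or array of source values.
#' @param target Numeric vector (or array, flattened) of target values.
#' @param bins Number of quantile knots (default 256).
#' @return Matched values with the same shape as `source`.
#' @export
match_histograms <- function(source, target, bins = 256) {
  if (!length(source) || !length(target)) stop("match error: empty input")
  sv <- as.numeric(source)
  st <- sort(as.numeric(target))
  m <- length(st)
  if (m <= bins) {
    p_knots <- (seq_len(m) - 0.5) / m
    q_knots <- st
  } else {
    p_knots <- (seq_len(bins) - 0.5) / bins
    q_knots <- stats::quantile(st, p_knots, names = FALSE, type = 7)
  }
  n <- length(sv)
  p <- (rank(sv, ties.method = "min") - 0.5) / n
  out <- if (length(p_knots) == 1L) {
    rep(q_knots, n)
  } else {
    stats::approx(p_knots, q_knots, xout = p, rule = 2, ties = "ordered")$y
  }
  out <- pmin(pmax(out, st[1]), st[m])
  if (!is.null(dim(source))) dim(out) <- dim(source)
  out
}

#' Log-cosh distance
#'
#' Mean over elements of `log(cosh(a - b))`: quadratic near zero like the
#' mean squared error, linear in the tails and therefore robust to
#' occasional large differences. Computed via
#' `|d| + log(1 + exp(-2|d|)) - log 2`, which never overflows.
#'
#' @param a,b Numeric arrays of identical shape (`b` defaults to zero).
#' @return Non-negative scalar; zero iff `a == b`.
#' @export
logcosh <- function(a, b = 0) {
  if (length(b) > 1L && !identical(dim(a), dim(b)) &&
      length(a) != length(b)) {
    stop("shape mismatch in logcosh")
  }
  d <- abs(a - b)
  mean(d + log1p(exp(-2 * d)) - log(2))
}

# Elementwise gradient of mean log-cosh w.r.t. its first argument.
logcosh_grad <- function(a, b) tanh(a - b) / length(a)

#' Histogram loss over tapped activations
#'
#' For each tap layer, pools the source and target batch activations into
#' value multisets, matches the source onto the target with
#' [match_histograms()], and accumulates the log-cosh distance between the
#' source activations and their matched counterparts. The matched tensors
#' are constants with respect to differentiation (an explicit stop-gradient:
#' the gradient flows only through the source activations, and the target
#' branch receives none), so target samples need no labels.
#'
#' @param source_acts,target_acts Named lists of activation matrices with
#'   the same layer inventory (as returned by [forward_with_activations()]).
#' @param config A [hist_align_config()].
#' @param want_grads If TRUE, also return the per-layer gradients with
#'   respect to the source activations.
#' @return List with `total`, `per_layer` (named numeric vector), and
#'   optionally `grads` (named list, same shapes as `source_acts`).
#' @export
histogram_loss <- function(source_acts, target_acts, config = hist_align_config(),
                           want_grads = FALSE) {
  if (!identical(names(source_acts), names(target_acts))) {
    stop("alignment error: source and target tap-layer inventories differ")
  }
  if (!length(source_acts)) stop("alignment error: no tap layers")
  per_layer <- numeric(length(source_acts))
  names(per_layer) <- names(source_acts)
  grads <- if (want_grads) stats::setNames(vector("list", length(source_acts)),
                                           names(source_acts))
  for (i in seq_along(source_acts)) {
    A <- source_acts[[i]]
    B <- target_acts[[i]]
    if (isTRUE(config$per_channel) && !is.null(dim(A)) && ncol(A) > 1 &&
        ncol(A) == ncol(B)) {
      H <- A
      for (ch in seq_len(ncol(A))) {
        H[, ch] <- match_histograms(A[, ch], B[, ch], config$bins)
      }
    } else {
      H <- match_histograms(A, as.numeric(B), config$bins)
    }
    per_layer[i] <- logcosh(A, H)
    if (want_grads) grads[[i]] <- logcosh_grad(A, H)
  }
  out <- list(total = sum(per_layer), per_layer = per_layer)
  if (want_grads) out$grads <- grads
  out
}

#' Total adaptation objective
#'
#' `L_total = L_ce + lambda * L_hist`.
#'
#' @param ce Cross-entropy loss (finite scalar).
#' @param hist Histogram loss (finite scalar).
#' @param lambda_weight Non-negative weight.
#' @return Scalar total loss.
#' @export
total_loss <- function(ce, hist, lambda_weight = 1.0) {
  if (!is.finite(ce) || !is.finite(hist) || !is.finite(lambda_weight)) {
    stop("numeric error: non-finite loss component")
  }
  ce + lambda_weight * hist
}

#' One-step loss breakdown
#'
#' Bundles the components of a single optimisation step.
#'
#' @param ce,hist,lambda_weight,per_layer_hist Loss components.
#' @return A `loss_breakdown` list with `ce`, `hist`, `lambda_weight`,
#'   `total`, `per_layer_hist`.
#' @export
loss_breakdown <- function(ce, hist, lambda_weight, per_layer_hist = numeric(0)) {
  structure(list(ce = ce, hist = hist, lambda_weight = lambda_weight,
                 total = total_loss(ce, hist, lambda_weight),
                 per_layer_hist = per_layer_hist),
            class = "loss_breakdown")
}
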