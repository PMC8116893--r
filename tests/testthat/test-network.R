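# Architecture construction, forward pass, tapped activations, gradients.

test_that("specs encode the task interfaces and default tap layers", {
  s <- network_spec("structures")
  expect_equal(s$prior_units, 15L)
  expect_equal(s$out_classes, 15L)
  expect_length(s$conv_channels, 5L)
  # last three convs per path + path FCs + head FCs, never the classifier
  expect_setequal(s$taps,
                  c(t(outer(1:3, 3:5, function(p, l) paste0("p", p, "c", l))),
                    paste0("p", 1:3, "fc"), paste0("hfc", 1:2)))
  expect_length(s$taps, 14L)

  sl <- network_spec("lesions")
  expect_equal(sl$prior_units, 3L)
  expect_equal(sl$out_classes, 2L)

  expect_error(network_spec("structures", taps = "out"), "tap")
  expect_error(network_spec("structures", taps = "p4c1"), "tap")
  expect_error(network_spec("structures", kernel = 4), "kernel")
})

test_that("forward pass yields normalised class probabilities of the right arity", {
  spec <- micro_spec()
  net <- build_network(spec, seed = 2)
  b <- toy_batch(spec, n = 5, seed = 1)
  fw <- forward_with_activations(net, b)
  expect_equal(dim(fw$probs), c(5L, 3L))
  expect_true(all(fw$probs >= 0))
  expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-5))

  specl <- micro_spec("lesions")
  netl <- build_network(specl, seed = 2)
  bl <- toy_batch(specl, n = 4, seed = 2)
  expect_equal(dim(forward_with_activations(netl, bl)$probs), c(4L, 2L))

  expect_error(forward_with_activations(net, list(X = b$X,
                                                  prior = b$prior[0, , drop = FALSE])),
               "empty batch")
})

test_that("weight initialisation and forward passes are deterministic", {
  spec <- micro_spec()
  n1 <- build_network(spec, seed = 7)
  n2 <- build_network(spec, seed = 7)
  expect_identical(n1$weights, n2$weights)
  expect_false(identical(n1$weights, build_network(spec, seed = 8)$weights))
  b <- toy_batch(spec, n = 3, seed = 4)
  expect_identical(forward_with_activations(n1, b)$acts,
                   forward_with_activations(n1, b)$acts)
})

test_that("activation capture never alters the forward result", {
  spec <- micro_spec()
  net <- build_network(spec, seed = 3)
  b <- toy_batch(spec, n = 6, seed = 5)
  p_with <- forward_with_activations(net, b)$probs
  p_without <- hmadapt:::net_forward(net, b$X, b$prior)$probs
  expect_lt(max(abs(p_with - p_without)), 1e-7)

  acts <- forward_with_activations(net, b)$acts
  expect_identical(names(acts), spec$taps)
})

test_that("samples in a batch do not couple: permuting rows permutes outputs", {
  spec <- micro_spec()
  net <- build_network(spec, seed = 1)
  b <- toy_batch(spec, n = 7, seed = 6)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  bp <- list(X = lapply(b$X, function(m) m[perm, , drop = FALSE]),
             prior = b$prior[perm, , drop = FALSE])
  p1 <- forward_with_activations(net, b)$probs
  p2 <- forward_with_activations(net, bp)$probs
  expect_equal(p2, p1[perm, ], tolerance = 1e-12)
})

test_that("the classification loss reaches every trainable parameter", {
  spec <- micro_spec()
  net <- build_network(spec, seed = 9)
  b <- toy_batch(spec, n = 8, seed = 2)
  fw <- hmadapt:::net_forward(net, b$X, b$prior, keep_cache = TRUE)
  cg <- hmadapt:::ce_loss_grad(fw$probs, b$y)
  g <- hmadapt:::net_backward(net, fw$cache, cg$dlogits)
  norms <- c()
  walk <- function(x, nm) {
    if (is.list(x) && !is.null(x$W)) {
      norms[[nm]] <<- sqrt(sum(x$W^2) + sum(x$b^2))
    } else if (is.list(x)) {
      for (i in seq_along(x)) walk(x[[i]], paste0(nm, ".", i))
    }
  }
  walk(g, "g")
  expect_gt(length(norms), 8L)
  expect_true(all(unlist(norms) > 0))
})

test_that("analytic gradients match finite differences on the joint loss", {
  spec <- micro_spec()
  net <- build_network(spec, seed = 3)
  b <- toy_batch(spec, n = 4, seed = 42)
  cfg <- hist_align_config(lambda_weight = 0.7)
  fw <- hmadapt:::net_forward(net, b$X, b$prior, taps = spec$taps,
                              keep_cache = TRUE)
  cg <- hmadapt:::ce_loss_grad(fw$probs, b$y)
  tgt <- lapply(fw$acts, function(a) a * 0.5 + 0.2)
  hl <- histogram_loss(fw$acts, tgt, cfg, want_grads = TRUE)
  g <- hmadapt:::net_backward(net, fw$cache, cg$dlogits,
                              lapply(hl$grads, function(x) 0.7 * x))
  H_frozen <- Map(function(A, B) match_histograms(A, as.numeric(B), cfg$bins),
                  fw$acts, tgt)
  loss_at <- function(nt) {
    f <- hmadapt:::net_forward(nt, b$X, b$prior, taps = spec$taps)
    hmadapt:::ce_loss_grad(f$probs, b$y)$loss +
      0.7 * sum(mapply(function(A, H) logcosh(A, H), f$acts, H_frozen))
  }
  set_entry <- function(tree, path, i, val) {
    if (!length(path)) { tree[i] <- val; return(tree) }
    tree[[path[[1]]]] <- set_entry(tree[[path[[1]]]], path[-1], i, val)
    tree
  }
  eps <- 1e-5
  cases <- list(list(path = list("conv", 1, 1, "W"), i = 7),
                list(path = list("conv", 2, 2, "W"), i = 30),
                list(path = list("pfc", 3, "W"), i = 11),
                list(path = list("hfc", 1, "W"), i = 5),
                list(path = list("out", "W"), i = 4))
  for (cs in cases) {
    w0 <- net$weights
    for (p in cs$path) w0 <- w0[[p]]
    ga <- g
    for (p in cs$path) ga <- ga[[p]]
    n2 <- net
    n2$weights <- set_entry(net$weights, cs$path, cs$i, w0[cs$i] + eps)
    lp <- loss_at(n2)
    n2$weights <- set_entry(net$weights, cs$path, cs$i, w0[cs$i] - eps)
    lm <- loss_at(n2)
    expect_equal(ga[cs$i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})
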