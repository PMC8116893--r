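# Synthetic 3D phantom generation.
#
# The phantoms stand in for skull-stripped, atlas-registered brain MRI: a
# smooth "brain" ellipsoid of background tissue containing either mirrored
# pairs of sub-cortical-structure analogues (structures mode) or sparse bright
# lesion blobs inside a white-matter compartment (lesions mode). A parametric
# domain shift (gamma, linear contrast/brightness, smooth multiplicative bias
# field, additive noise) renders a "target" acquisition of the same anatomy,
# which is what the adaptation method is asked to overcome.

ellipsoid_field <- function(shape, center, radii) {
  a1 <- ((seq_len(shape[1]) - center[1]) / radii[1])^2
  a2 <- ((seq_len(shape[2]) - center[2]) / radii[2])^2
  a3 <- ((seq_len(shape[3]) - center[3]) / radii[3])^2
  outer(outer(a1, a2, "+"), a3, "+")
}

ellipsoid_mask <- function(shape, center, radii) {
  ellipsoid_field(shape, center, radii) <= 1
}

#' Describe a phantom scene
#'
#' Builds the ground-truth geometry and intensity model from which
#' [render_phantom()] rasterises a volume, label map, and prior atlas.
#' In structures mode each of the `n_structure_classes` classes appears once
#' per hemisphere analogue (a mirrored pair of ellipsoids with a
#' class-specific base intensity). In lesions mode the scene carries a
#' three-tissue background (WM, GM, CSF) and `n_lesions` small bright blobs
#' (all class 1) placed inside the white matter.
#'
#' Default intensities are on a nominal [0, 1] scale: background tissue well
#' separated from the structure classes, lesions markedly hyperintense
#' (FLAIR-like). All randomness is driven by `seed`.
#'
#' @param shape Length-3 integer volume shape.
#' @param mode `"structures"` or `"lesions"`.
#' @param spacing Voxel spacing in mm.
#' @param n_structure_classes Number of structure classes (1-4) in structures
#'   mode; the atlas then has `n_structure_classes + 1` channels.
#' @param n_lesions Number of lesion blobs in lesions mode.
#' @param tissue_intensity Mean intensity of background brain tissue
#'   (structures mode).
#' @param texture_amp,texture_scale Amplitude and correlation length (voxels)
#'   of the smooth multiplicative tissue texture.
#' @param noise_sd Standard deviation of additive Gaussian noise inside the
#'   brain.
#' @param edge_smooth Gaussian smoothing (voxels) of the piecewise-constant
#'   intensity model before noise, emulating partial-volume averaging at
#'   tissue interfaces. Partial volume matters: it is what makes boundary
#'   delineation depend on absolute intensity, and hence what lets
#'   gamma-like domain shifts displace apparent boundaries.
#' @param prior_blur Gaussian blur (voxels) applied to class indicators when
#'   fabricating the registered-atlas probabilities.
#' @param seed Integer seed controlling lesion placement and rendering noise.
#' @param objects Optional data frame overriding the default object layout
#'   (columns class, cx, cy, cz, rx, ry, rz, intensity).
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(shape = c(28, 28, 28),
                          mode = c("structures", "lesions"),
                          spacing = c(1, 1, 1),
                          n_structure_classes = 4,
                          n_lesions = 4,
                          tissue_intensity = 0.22,
                          texture_amp = 0.03,
                          texture_scale = 3,
                          noise_sd = 0.02,
                          edge_smooth = 0.7,
                          prior_blur = 0.6,
                          seed = 1,
                          objects = NULL) {
  mode <- match.arg(mode)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  ctr <- (shape + 1) / 2
  sc <- shape / 28
  brain <- list(center = ctr, radii = 0.45 * shape)

  tissues <- NULL
  if (mode == "structures") {
    # a dark ventricle-like CSF compartment plus a few small bright
    # dura/vessel remnants at the rim (both background class). The remnants
    # anchor the top of the dynamic range, as imperfect skull-stripping does
    # in practice; brain tissue then sits in the dark part of the range,
    # where a gamma shift genuinely compresses its contrast
    tissues <- list(csf = list(center = ctr, radii = pmax(c(1.8, 2.6, 2.2) * sc, 1.0),
                               intensity = 0.08),
                    remnants = list(offsets = rbind(c(0, 9.5, 3.0),
                                                    c(2.5, -9.0, -3.5)),
                                    radius = 1.9, intensity = 0.95))
    if (is.null(objects)) {
      stopifnot(n_structure_classes >= 1L, n_structure_classes <= 4L)
      # one object per class, as in real sub-cortical labelling where left
      # and right structures are separate classes: classes 1/2 are a
      # same-intensity left/right pair that only the spatial prior can tell
      # apart; offsets/radii at reference shape 28, scaled per axis
      # contrasts against the 0.35 tissue background mimic the task's
      # difficulty spread: classes 1/2 a weak-contrast pair (thalamus-like,
      # the structures most affected by scanner shifts), class 3 weak and
      # small (pallidum-like), class 4 strong (putamen-like, robust)
      tmpl <- list(
        list(off = c(-5.0, 0.0, 0.0),  r = c(2.8, 2.8, 2.8), I = 0.30),
        list(off = c(5.0, 0.0, 0.0),   r = c(2.8, 2.8, 2.8), I = 0.30),
        list(off = c(-6.0, 5.8, 1.5),  r = c(2.1, 2.1, 2.1), I = 0.26),
        list(off = c(6.0, -5.8, 1.5),  r = c(2.2, 2.4, 2.2), I = 0.36)
      )
      rows <- list()
      for (cls in seq_len(n_structure_classes)) {
        t <- tmpl[[cls]]
        cen <- ctr + t$off * sc
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, cx = cen[1], cy = cen[2], cz = cen[3],
          rx = t$r[1] * sc[1], ry = t$r[2] * sc[2], rz = t$r[3] * sc[3],
          intensity = t$I)
      }
      objects <- do.call(rbind, rows)
    }
  } else {
    csf <- list(center = ctr, radii = pmax(c(2.5, 3.5, 3.0) * sc, 1.2),
                intensity = 0.12)
    wm <- list(center = ctr, radii = 0.62 * brain$radii, intensity = 0.35)
    tissues <- list(csf = csf, wm = wm, gm_intensity = 0.50)
    if (is.null(objects)) {
      objects <- with_seed(seed, {
        # candidate lesion sites: inside WM, outside CSF, away from the rim
        wmm <- ellipsoid_mask(shape, wm$center, wm$radii * 0.85) &
          !ellipsoid_mask(shape, csf$center, csf$radii * 1.4)
        cand <- which(wmm)
        if (length(cand) < n_lesions) stop("scene too small for requested lesions")
        pick <- arrayInd(sample(cand, n_lesions), shape)
        r <- matrix(stats::runif(3 * n_lesions, 1.2, 2.2), ncol = 3)
        data.frame(class = 1L, cx = pick[, 1], cy = pick[, 2], cz = pick[, 3],
                   rx = r[, 1], ry = r[, 2], rz = r[, 3], intensity = 0.85)
      })
    }
  }
  for (i in seq_len(nrow(objects))) {
    o <- objects[i, ]
    if (o$cx - o$rx < 1 || o$cx + o$rx > shape[1] ||
        o$cy - o$ry < 1 || o$cy + o$ry > shape[2] ||
        o$cz - o$rz < 1 || o$cz + o$rz > shape[3]) {
      stop("scene error: object ", i, " extends outside the volume bounds")
    }
  }
  structure(list(shape = shape, mode = mode, spacing = as.numeric(spacing),
                 brain = brain, tissues = tissues, objects = objects,
                 n_structure_classes = if (mode != "structures") 1L
                 else if (nrow(objects)) max(objects$class)
                 else as.integer(n_structure_classes),
                 tissue_intensity = tissue_intensity,
                 texture_amp = texture_amp, texture_scale = texture_scale,
                 noise_sd = noise_sd, edge_smooth = edge_smooth,
                 prior_blur = prior_blur, seed = seed),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat("<phantom_scene> ", x$mode, " mode, ",
      paste(x$shape, collapse = " x "), " voxels, ",
      nrow(x$objects), " objects, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Smooth unit-variance random field, used for texture and bias fields.
smooth_noise_field <- function(shape, sigma) {
  f <- gaussian_blur3(array(stats::rnorm(prod(shape)), shape), sigma)
  s <- stats::sd(as.vector(f))
  if (s < 1e-12) array(0, shape) else (f - mean(f)) / s
}

#' Render a phantom scene
#'
#' Rasterises a scene into an intensity volume (tissue background with
#' multiplicative texture and additive Gaussian noise inside the brain,
#' exact zero outside, as in skull-stripped images), a ground-truth label
#' map, and a prior atlas built by Gaussian-blurring each class indicator and
#' renormalising per voxel — an idealisation of registered atlas
#' probabilities. Fully determined by `scene$seed`.
#'
#' @param scene A [phantom_scene()].
#' @return A list with elements `volume`, `label`, `atlas`, `brain_mask`,
#'   and (lesions mode) `wm_mask`.
#' @export
render_phantom <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  shape <- scene$shape
  brain <- ellipsoid_mask(shape, scene$brain$center, scene$brain$radii)
  base <- array(0, shape)
  wm_mask <- NULL
  if (scene$mode == "structures") {
    base[brain] <- scene$tissue_intensity
    if (!is.null(scene$tissues$csf)) {
      csf <- ellipsoid_mask(shape, scene$tissues$csf$center,
                            scene$tissues$csf$radii) & brain
      base[csf] <- scene$tissues$csf$intensity
    }
    if (!is.null(scene$tissues$remnants)) {
      rm <- scene$tissues$remnants
      sc_ax <- shape / 28
      for (i in seq_len(nrow(rm$offsets))) {
        cen <- scene$brain$center + rm$offsets[i, ] * sc_ax
        blob <- ellipsoid_mask(shape, cen, rep(rm$radius, 3) * min(sc_ax)) & brain
        base[blob] <- rm$intensity
      }
    }
  } else {
    t <- scene$tissues
    gm <- brain
    wmm <- ellipsoid_mask(shape, t$wm$center, t$wm$radii) & brain
    csf <- ellipsoid_mask(shape, t$csf$center, t$csf$radii) & brain
    base[gm] <- t$gm_intensity
    base[wmm] <- t$wm$intensity
    base[csf] <- t$csf$intensity
    wm_mask <- wmm & !csf
  }

  label <- array(0L, shape)
  for (i in seq_len(nrow(scene$objects))) {
    o <- scene$objects[i, ]
    m <- ellipsoid_mask(shape, c(o$cx, o$cy, o$cz), c(o$rx, o$ry, o$rz))
    clash <- m & label != 0L & label != o$class
    if (any(clash)) stop("scene error: overlapping objects of different classes")
    base[m] <- o$intensity
    label[m] <- as.integer(o$class)
  }

  if (!is.null(scene$edge_smooth) && scene$edge_smooth > 0) {
    base <- gaussian_blur3(base, scene$edge_smooth)
  }
  vol <- with_seed(scene$seed, {
    x <- base
    if (scene$texture_amp > 0) {
      x <- x * (1 + scene$texture_amp * smooth_noise_field(shape, scene$texture_scale))
    }
    if (scene$noise_sd > 0) {
      eta <- array(stats::rnorm(prod(shape), sd = scene$noise_sd), shape)
      x[brain] <- x[brain] + eta[brain]
    }
    x
  })

  K <- if (scene$mode == "structures") scene$n_structure_classes + 1L else 3L
  atlas <- array(0, c(shape, K))
  if (scene$mode == "structures") {
    for (k in 0:(K - 1L)) {
      atlas[, , , k + 1L] <- gaussian_blur3((label == k) * 1, scene$prior_blur)
    }
  } else {
    t <- scene$tissues
    chans <- list(wm = wm_mask, gm = brain & !wm_mask &
                    !(ellipsoid_mask(shape, t$csf$center, t$csf$radii) & brain),
                  csf = ellipsoid_mask(shape, t$csf$center, t$csf$radii) & brain)
    for (k in 1:3) atlas[, , , k] <- gaussian_blur3(chans[[k]] * 1, scene$prior_blur)
  }
  sums <- apply(atlas, c(1, 2, 3), sum)
  renorm <- sums > 1e-6
  for (k in seq_len(K)) {
    ch <- atlas[, , , k]
    ch[renorm] <- ch[renorm] / sums[renorm]
    atlas[, , , k] <- pmin(pmax(ch, 0), 1)
  }

  list(volume = as_volume(vol, scene$spacing),
       label = as_label_map(label, scene$spacing, class_count = K),
       atlas = as_prior_atlas(atlas, scene$spacing),
       brain_mask = brain,
       wm_mask = wm_mask)
}

#' Describe a parametric domain shift
#'
#' The identity shift is `gamma = 1, gain = 1, offset = 0,
#' bias_field_amplitude = 0, extra_noise_sd = 0`.
#'
#' @param gamma Positive gamma exponent applied on a [0, 1] rescale of the
#'   input intensities.
#' @param gain Positive multiplicative contrast factor.
#' @param offset Additive brightness offset.
#' @param bias_field_amplitude Amplitude A of the smooth multiplicative bias
#'   field, which lies in `[1 - A, 1 + A]`.
#' @param bias_field_smoothness Correlation length of the bias field, in mm.
#' @param extra_noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed for the bias field and noise realisations.
#' @return An object of class `domain_shift`.
#' @export
domain_shift <- function(gamma = 1, gain = 1, offset = 0,
                         bias_field_amplitude = 0, bias_field_smoothness = 8,
                         extra_noise_sd = 0, seed = 1) {
  if (gamma <= 0 || gain <= 0) stop("gamma and gain must be positive")
  if (bias_field_amplitude < 0 || extra_noise_sd < 0 || bias_field_smoothness <= 0) {
    stop("bias field amplitude/smoothness and noise sd must be non-negative/positive")
  }
  structure(list(gamma = gamma, gain = gain, offset = offset,
                 bias_field_amplitude = bias_field_amplitude,
                 bias_field_smoothness = bias_field_smoothness,
                 extra_noise_sd = extra_noise_sd, seed = seed),
            class = "domain_shift")
}

#' Apply a parametric domain shift to a volume
#'
#' Computes `gain * B(v) * g(x) + offset + eta`, where `g` applies the gamma
#' exponent on an internal [0, 1] rescale of the intensities (restored
#' afterwards), `B` is a smooth multiplicative bias field in
#' `[1 - A, 1 + A]` with the configured correlation length, and `eta` is
#' i.i.d. Gaussian noise. Deterministic given `shift$seed`.
#'
#' @param volume A `volume`.
#' @param shift A [domain_shift()].
#' @return The shifted `volume`.
#' @export
apply_domain_shift <- function(volume, shift) {
  stopifnot(inherits(volume, "volume"), inherits(shift, "domain_shift"))
  x <- volume$data
  lo <- min(x); hi <- max(x)
  if (shift$gamma != 1 && hi > lo) {
    u <- (x - lo) / (hi - lo)
    x <- lo + (hi - lo) * u^shift$gamma
  }
  with_seed(shift$seed, {
    if (shift$bias_field_amplitude > 0) {
      sig <- shift$bias_field_smoothness / volume$spacing
      f <- smooth_noise_field(dim(x), sig)
      # scale by a robust quantile over the signal region (a bias field is
      # only meaningful where there is signal), then clip, so the nominal
      # amplitude is actually attained across the object, not only at one
      # extreme background voxel
      sel <- volume$data != 0
      if (!any(sel)) sel <- rep(TRUE, length(f))
      q <- stats::quantile(abs(f[sel]), 0.98, names = FALSE)
      if (q > 0) f <- pmin(pmax(f / q, -1), 1)
      x <- x * (1 + shift$bias_field_amplitude * f)
    }
    x <- shift$gain * x + shift$offset
    if (shift$extra_noise_sd > 0) {
      x <- x + array(stats::rnorm(length(x), sd = shift$extra_noise_sd), dim(x))
    }
    x
  }) -> out
  v <- volume
  v$data <- out
  v
}

# Per-case anatomical jitter of a scene template: object positions, radii and
# intensities vary between subjects while the class inventory is preserved.
# The jitter doubles as the residual error of a population atlas registered
# to the case, so its scale (about half a voxel, capped at 1.2) matches good
# non-linear registration at this resolution.
jitter_scene <- function(scene, case_seed,
                         pos_sd = 0.4, radius_jitter = 0.05, intensity_jitter = 0.03) {
  with_seed(case_seed, {
    obj <- scene$objects
    n <- nrow(obj)
    dpos <- matrix(pmin(pmax(stats::rnorm(3 * n, sd = pos_sd), -1.2), 1.2), ncol = 3)
    rmul <- matrix(stats::runif(3 * n, 1 - radius_jitter, 1 + radius_jitter), ncol = 3)
    imul <- stats::runif(n, 1 - intensity_jitter, 1 + intensity_jitter)
    obj$cx <- obj$cx + dpos[, 1]; obj$cy <- obj$cy + dpos[, 2]; obj$cz <- obj$cz + dpos[, 3]
    obj$rx <- obj$rx * rmul[, 1]; obj$ry <- obj$ry * rmul[, 2]; obj$rz <- obj$rz * rmul[, 3]
    obj$intensity <- obj$intensity * imul
    # keep every object inside the volume bounds
    obj$cx <- pmin(pmax(obj$cx, 1 + obj$rx), scene$shape[1] - obj$rx)
    obj$cy <- pmin(pmax(obj$cy, 1 + obj$ry), scene$shape[2] - obj$ry)
    obj$cz <- pmin(pmax(obj$cz, 1 + obj$rz), scene$shape[3] - obj$rz)
    out <- scene
    out$objects <- obj
    out$seed <- case_seed
    out
  })
}

#' Generate paired source/target phantom cases
#'
#' Renders `n_source` labelled source cases and `n_target` unlabelled target
#' cases from per-case jittered copies of one scene template. Target volumes
#' carry the domain shift (re-masked to the brain afterwards, emulating
#' per-image skull-stripping); their ground-truth labels are returned
#' separately under `target_truth` and are intended for evaluation only —
#' the adaptation interface never sees them.
#'
#' @param scene A [phantom_scene()] template.
#' @param n_source,n_target Number of cases per domain (>= 1).
#' @param shift A [domain_shift()] applied to target cases. One seeded
#'   realisation of the bias field is shared by every target case: the
#'   inhomogeneity pattern is the scanner's signature, while anatomy and
#'   tissue noise vary per case.
#' @param seed Integer seed driving the per-case jitter.
#' @param atlas_from `"template"` (default): all cases share the atlas built
#'   from the unjittered scene template — a population atlas, as real
#'   pipelines register, whose residual error per case is that case's
#'   anatomical jitter; the prior then guides the network without making
#'   intensity redundant. `"case"`: each case carries the atlas built from
#'   its own blurred labels (a per-subject atlas, nearly exact).
#' @param template_blur Gaussian blur (voxels) of the template atlas's class
#'   indicators. Population probabilities are diffuse — averaging anatomy
#'   across subjects spreads them over a sizeable fraction of a structure's
#'   radius — so the default is wider than the per-case `prior_blur`.
#' @return A list with `source` (cases with `volume`, `label`, `atlas`),
#'   `target` (cases with `volume`, `atlas`; no labels), `target_truth`
#'   (the held-back target label maps), and `target_pristine` (the
#'   held-back unshifted target volumes, for paired evaluation of the
#'   shift's cost only — like the truth, never an input to adaptation).
#' @export
make_domain_pair <- function(scene, n_source = 1, n_target = 1,
                             shift = domain_shift(), seed = 1,
                             atlas_from = c("template", "case"),
                             template_blur = 1.2) {
  atlas_from <- match.arg(atlas_from)
  stopifnot(inherits(scene, "phantom_scene"), n_source >= 1, n_target >= 1)
  case_seeds <- with_seed(seed, sample.int(2^30, n_source + n_target))
  # a jitter draw that pushes two different-class objects into contact is
  # rejected and deterministically redrawn from a derived seed
  render_case <- function(cs) {
    for (attempt in 0:24) {
      res <- tryCatch(render_phantom(jitter_scene(scene, (cs + attempt * 500009L) %% 2^30)),
                      error = function(e) e)
      if (!inherits(res, "error")) return(res)
    }
    stop("scene error: could not place jittered objects without cross-class overlap")
  }
  source <- lapply(case_seeds[seq_len(n_source)], render_case)
  target_full <- lapply(case_seeds[n_source + seq_len(n_target)], render_case)
  if (atlas_from == "template") {
    tmpl_scene <- scene
    tmpl_scene$prior_blur <- template_blur
    template_atlas <- render_phantom(tmpl_scene)$atlas
    source <- lapply(source, function(cs) { cs$atlas <- template_atlas; cs })
    target_full <- lapply(target_full, function(cs) { cs$atlas <- template_atlas; cs })
  }
  target <- vector("list", n_target)
  truth <- vector("list", n_target)
  pristine <- vector("list", n_target)
  for (i in seq_len(n_target)) {
    tc <- target_full[[i]]
    # the shift is the scanner's signature: one bias-field/noise seed for the
    # whole target domain, while anatomy and tissue noise vary per case
    v <- apply_domain_shift(tc$volume, shift)
    v$data[!tc$brain_mask] <- 0
    target[[i]] <- list(volume = v, atlas = tc$atlas,
                        brain_mask = tc$brain_mask, wm_mask = tc$wm_mask)
    truth[[i]] <- tc$label
    pristine[[i]] <- tc$volume
  }
  list(source = source, target = target, target_truth = truth,
       target_pristine = pristine)
}
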