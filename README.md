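# hmadapt

Transductive domain adaptation for patch-based brain MRI segmentation via
feature-histogram matching.

## The problem

A convolutional segmenter trained on MRI volumes from one scanner degrades
when applied to another: acquisition differences shift brightness, contrast,
and field inhomogeneity, and the network's internal feature distributions no
longer match the data it sees. Annotating images from every new scanner is
rarely possible. `hmadapt` is for researchers who want to study — and apply —
a label-free remedy: the unlabelled target images themselves join the
optimisation (transductive learning), contributing only the *distributions*
of their network activations.

## The method

The segmenter is a voxel-wise 2.5D patch CNN: three orthogonal 2D patches
(axial, sagittal, coronal) per voxel feed three convolutional paths, whose
outputs are concatenated with a spatial-prior vector from a registered
probabilistic atlas before fully connected layers and a softmax. Supervised
training uses boundary-negative sampling for sub-cortical structures and a
two-stage cascade (stage-2 negatives from stage-1 false positives) for
white-matter-hyperintensity lesions.

For adaptation, let $A_i$ and $B_i$ be the batch activations of tap layer
$i$ for source and target samples. The source activations are
histogram-matched onto the target's via a monotone CDF/quantile mapping
$H(A_i, B_i)$, and

$$L_{\text{hist}} = \sum_i^{L} \operatorname{LogCosh}\big(A_i, H(A_i, B_i)\big),
\qquad L_{\text{total}} = L_{ce} + \lambda\,L_{\text{hist}}$$

is minimised at a reduced learning rate, with $H$ held constant under
differentiation (stop-gradient), so no target labels are ever needed. One
source and one target image suffice. Tapped layers are the last three
convolutions of each path plus all fully connected layers except the
classifier; $\lambda = 1$ by default.

A synthetic phantom generator (structures and lesions modes, partial-volume
edges, fabricated atlas priors, parametric scanner shifts: gamma, contrast,
bias field, noise) makes the whole pipeline runnable end to end with no
external data. See the methods vignette (`vignettes/hmadapt-methods.Rmd`)
for the model, the generator's assumptions, and every numerical design
choice.

## Worked example

The end-to-end desk-scale experiment — simulate a source/target scanner
pair, train a baseline, measure the shift's cost, adapt with one unlabelled
target volume, measure the recovery:

```r
library(hmadapt)
res <- run_demo(seed = 2)
round(res$summary, 4)
#>    baseline_source_dsc    baseline_target_dsc     adapted_target_dsc
#>                 0.7570                 0.6145                 0.6559
#>      domain_shift_drop adaptation_improvement
#>                 0.1425                 0.0415
```

Reading: on held-out phantom cases the baseline reaches mean Dice 0.757 in
its own domain; the same anatomies pushed through the simulated scanner
shift (gamma 1.8 plus a 45 % bias field) cost it 0.142 Dice; transductive
adaptation — using a single unlabelled target volume — wins 0.042 back.
`res$metrics` holds the per-case table, and
`res$adapted$state$history` the per-epoch cross-entropy/histogram loss
breakdown.

The pieces are available individually:

```r
scene <- phantom_scene(mode = "lesions", n_lesions = 4, seed = 1)
ph    <- render_phantom(scene)
fit   <- train_cascaded(tiny_network_spec("lesions"), ph$volume, ph$label,
                        ph$atlas, ph$brain_mask)
seg   <- predict(fit$stage2, ph$volume, ph$atlas, brain_mask = ph$brain_mask)
evaluate_case(seg, ph$label)
```

A thin command-line wrapper (`inst/cli/hmadapt`) exposes `simulate`,
`train`, `adapt`, `segment`, `evaluate`, and `demo` subcommands; every run
writes a JSON manifest with its resolved configuration and seed.

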