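---
title: "Joint plaque segmentation and diameter regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint plaque segmentation and diameter regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Carotid atherosclerotic plaques are routinely assessed on B-mode ultrasound,
where the clinically reported quantities are a segmentation of the plaque and
its **long and short diameters** in millimetres. Ultrasound makes both tasks
hard: multiplicative speckle, low plaque/background contrast, blurred edges
and acoustic shadowing below calcifications. `plaquenet` implements a
multi-task convolutional network that performs both tasks jointly from a
shared encoder, together with everything needed to exercise it end to end on
synthetic data: a speckle phantom generator with exactly known ground truth,
a manifest-driven split/augmentation pipeline, the evaluation metric algebra,
and caliper-style morphometry of binary masks.

## The network

The trunk is a U-Net-style encoder–decoder. Each encoder stage applies two
3×3 convolutions (batch norm + rectifier), then a channel-attention block,
then 2× max pooling, doubling the channel count per stage. The decoder
mirrors the encoder with 2×2 transposed convolutions and skip
concatenations; a 1×1 convolution emits per-pixel class scores. A second,
regression branch taps the bottleneck (deepest) features: global average
pooling, one rectified hidden layer, and a linear 2-output layer producing
the long and short diameter.

Interpretation choices that the architecture description leaves open, fixed
here and configurable via `model_config()`:

* **Dual branch**: realized as segmentation head + diameter-regression
  branch over a shared encoder; the "fusion" between the tasks is the shared
  trunk plus the joint loss.
* **Attention placement**: after each encoder stage's convolution block,
  before down-sampling; not in the decoder.
* **Regression tap point**: the bottleneck output, via GAP → FC → FC(2);
  diameters are regressed with a linear output (unbounded above), optionally
  on z-scored targets (`standardize_targets`, default on — Adam converges
  noticeably faster when both loss terms start at comparable scale).
* **Down/up-sampling**: max pooling and learned 2×2 transposed convolution.
* **Batch normalisation** after every convolution; needed for stable
  small-batch training.

### Multi-layer efficient channel attention

Efficient channel attention (ECA) computes channel weights from the globally
pooled channel descriptor with a cheap local 1D convolution and a sigmoid.
The variant here stacks `eca_conv_layers` (default 2) 1D convolutions with a
rectifier between them, extracting descriptor features at more than one
level before the sigmoid. With a single layer it reduces exactly to the
original single-convolution ECA (property-tested against an independent
reference implementation). The kernel length is odd, either fixed or
`"adaptive"`: \(k = |\log_2(C)/2 + 1/2|\) rounded to the nearest odd integer
and clamped to ≥ 3, so the interaction span grows logarithmically with the
channel count. The multi-layer convolutions keep a single-channel
descriptor throughout.

### The joint objective

\[
L = \alpha\,L_\text{seg} + \beta\,L_\text{size},
\qquad
L_\text{seg} = -\frac{1}{P}\sum_p \log p_{y_p},
\qquad
L_\text{size} = \frac{1}{2N}\sum_{i,d} (y_{id} - \hat y_{id})^2 .
\]

Both terms are **means**, not sums, so the weighting is invariant to batch
and image size (the printed form of the cross-entropy bracket in the
original description is a sum; the mean is a deliberate normalisation
choice, recorded here). Fixed weights default to \(\alpha = \beta = 1\).
The automatic balancing mode (`loss_weights(mode = "auto")`) implements
homoscedastic-uncertainty weighting with two learnable log-variances:
\(L = e^{-s_1} L_\text{seg} + s_1 + \tfrac12 e^{-s_2} L_\text{size} +
\tfrac12 s_2\), reporting effective \(\alpha = e^{-s_1}\),
\(\beta = \tfrac12 e^{-s_2}\). A task whose loss stays persistently large
has its weight driven down — the standard learnable balancer, chosen because
the original description names no method. Fixed mode is the default and is
what the deterministic acceptance workflow uses.

## The phantom generator

`generate_sample()` draws one elliptical plaque per image (centre,
orientation, long semi-axis \(a\) uniform over a mm range, aspect ratio
uniform over a range), renders it at `background + contrast` over a smooth
low-frequency echo texture, blurs the edges (Gaussian, in pixels),
multiplies by i.i.d. unit-mean Gamma speckle with shape `looks`
(variance \(1/L\) — the standard multi-look intensity speckle model, chosen
because it has testable moments), and with a configured probability
attenuates a vertical shadow band below the plaque (factor 0.3, linear
feather), emulating calcification shadowing. Ground-truth diameters are the
analytic \(2a, 2b\); the mask is the exact set of pixel centres inside the
generating ellipse, so the simulator and the morphometry oracle close on
each other to within one pixel.

What the phantoms deliberately do **not** model: physically accurate
acoustics (no RF signal, no ray tracing), multi-plaque scenes, vendor image
dialects, probe motion and pulsation artifacts, and inter-observer
annotation noise. Consequences for interpreting results are discussed under
*Limitations*.

Defaults (256×256 px at 0.1 mm/px, semi-axes 2–10 mm) are assumptions — the
clinical resolution and plaque-size distribution of the original study are
not public; they are stated in `phantom_config()` and configurable.

## Pipeline conventions

* **Split**: rows are permuted by seed and assigned
  \(n_\text{train} = \lfloor 7n/10 \rfloor\),
  \(n_\text{val} = \lfloor n/10 \rfloor\), remainder to test — the unique
  simple rounding rule that maps 287 images onto the (200, 28, 59) protocol
  layout.
* **Augmentation**: each training row yields the original plus 7 variants
  (an 8-fold training set), each variant drawing one operation uniformly
  from {elastic, rotate, scale, flip-h, flip-v}; defaults rotation ±15°,
  scale 0.9–1.1, elastic α = 30 px / σ = 6 px. Validation and test rows are
  never touched, and training refuses manifests in which an augmented row
  descends from a held-out parent.
* **Diameters of augmented samples** are re-measured from the transformed
  mask rather than transformed analytically, so elastic deformation (which
  has no closed-form diameter law) is handled uniformly; rotations/flips
  must preserve them and scaling must multiply them by the factor, which is
  property-tested to within 2 px.
* **Interpolation**: bilinear for images, nearest-neighbour for masks.
* **Contrast enhancement**: min–max normalisation (a constant image maps to
  zeros) followed by CLAHE, the standard ultrasound choice; plain histogram
  equalization via `method = "hist"`.

## Morphometry conventions

The clinical "long diameter" is realized as the maximum Feret diameter: the
largest centre-to-centre distance between boundary pixels of the largest
8-connected component (fragmented predictions keep only their largest blob,
because every image carries exactly one plaque). It is computed exactly via
the convex hull of the boundary centres and verified in tests against the
exhaustive \(O(B^2)\) pairwise maximum. The short diameter is the extent
perpendicular to the long-diameter axis. Distances are pixel-centre to
pixel-centre with a one-pixel floor: a 1×10 row of pixels measures 9 × 1
spacings and a single pixel measures one spacing in both directions. A
minimum-area-rectangle alternative is available (`method = "min_rect"`).
Whether the clinical short diameter is perpendicular-to-long or an
independent caliper is not specified anywhere authoritative; the
perpendicular convention is adopted and stated.

## Training harness

Adam (lr 0.001), batch 16, up to 100 epochs with early stopping (patience
15, on validation total loss) and best-on-validation checkpointing;
`run_experiment()` repeats training `repetitions` times (default 10) with
seeds `seed + r` on a **fixed** split — the protocol table shows one fixed
split, so repetitions re-initialize rather than re-split — and aggregates
every metric as mean ± sd (n−1). Micro-averaged confusion pooling is the
default (macro available). The segment-then-measure baseline
(`baseline_unet_measure()`) trains the identical trunk with attention off
and β = 0 — isolating both architectural contributions — then derives
diameters from the predicted masks via morphometry.

## Problem sizes used by tests and the acceptance workflow

The shipped smoke scale (`smoke_phantom_config()`, `smoke_train_config()`)
is 64×64 phantoms at 0.15 mm/px (semi-axes 1.5–3.5 mm, contrast 0.35,
4-look speckle by default, heavy 1-look speckle in the acceptance
experiment), a depth-3 / 8-channel network, batch 16, 12 epochs, 2
repetitions, 180 phantoms split 120/20/40. These sizes are the package's
choice of a desk-scale experiment that a single CPU completes in minutes
while leaving clear margins over the acceptance thresholds (test Dice
≥ 80 %, long-diameter R² ≥ 0.70); the full-scale protocol settings remain
the defaults of `train_config()` and `phantom_config()`.

## Numerical choices

* Softmax cross-entropy clamps probabilities at 1e−12; batch-norm epsilon
  1e−5, momentum 0.1; Adam β₁ = 0.9, β₂ = 0.999, ε = 1e−8.
* He-scaled Gaussian weight initialisation; ECA kernels N(0, 0.1²), zero
  bias (so initial attention ≈ 0.5 everywhere, a neutral starting point).
* Training batches of size 1 are skipped (batch statistics undefined);
  a non-finite loss aborts with a diagnostic rather than continuing.
* All randomness is derived from explicit seeds; a generated sample is a
  pure function of `(config, sample_index)`, and two runs with the same
  seed produce bit-identical training curves (single-threaded BLAS).
* Analytic gradients of every layer are verified against central finite
  differences to 1e−4 relative error in the test suite.

## Known limitations

* **The paired joint-vs-baseline comparison does not favour the joint model
  on these phantoms.** On synthetic single-ellipse data, segmentation stays
  near-perfect even under 1-look speckle (Dice ≈ 92), so Feret measurement
  of the predicted mask is accurate to about one pixel and the
  segment-then-measure baseline attains a *lower* diameter MAE than the
  GAP-feature regression branch (≈ 0.2 mm vs ≈ 0.5 mm). The clinical
  mechanism that motivates joint regression — degraded, fragmented masks
  and annotation variability — is exactly what the phantoms do not model.
  The corresponding acceptance property is asserted as specified and is
  expected to fail on synthetic data; this is a finding about the data
  model, not a defect of either arm. The acceptance report exposes both
  MAEs and the paired win fraction so the comparison is transparent.
* Clinical headline numbers (e.g. MIoU ≈ 89 %, long-diameter MSE ≈ 1 mm²)
  were measured on a private single-centre dataset and are not reproducible
  here; nothing in this package claims to reproduce them.
* The engine is CPU-only and sized for small experiments; at the full
  protocol scale (100 epochs, 1,600 augmented images, 64 base channels) it
  is correct but slow.
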