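# plaquenet

Joint semantic segmentation and size regression of carotid plaques in
B-mode ultrasound images, in R.

Clinical carotid assessment reports two things per plaque: its outline and
its **long/short diameters** in millimetres. Ultrasound makes both hard —
multiplicative speckle, low contrast, blurred edges, acoustic shadowing.
`plaquenet` implements a dual-branch convolutional network that produces
both outputs from one shared encoder:

* a U-Net-style encoder–decoder segmentation trunk with a **multi-layer
  efficient channel attention** block (stacked 1D convolutions over the
  pooled channel descriptor, sigmoid-gated) after every encoder stage, and
* a **diameter-regression branch** from the globally pooled bottleneck
  features,

trained with the weighted joint objective

```
L = α · L_seg + β · L_size ,     L_seg = mean pixel cross-entropy,
                                 L_size = mean squared diameter error (mm²),
```

with fixed weights (default α = β = 1) or homoscedastic-uncertainty
auto-balancing. The whole CNN engine (convolutions via im2col + BLAS,
batch norm, pooling, transposed convolutions, attention, Adam, hand-derived
backprop) lives in the package; the gradients are verified against finite
differences in the test suite.

Because clinical data of this kind is private, the package ships a
**synthetic phantom generator**: one elliptical plaque per image with
exactly known mask and diameters, Gamma multiplicative speckle (`looks`
controls the noise), edge blur, low contrast and optional acoustic-shadow
bands. Around it sit:

* a manifest-driven pipeline: 7:1:2 train/val/test split (287 images map
  to exactly 200/28/59), CLAHE preprocessing, and 8-fold training-set
  augmentation (elastic / rotate / scale / flip) with diameters re-measured
  from the transformed masks;
* the evaluation metric algebra: accuracy, mean IoU, background-excluded
  IoU, Dice (with the identity D = 2I/(1+I) property-tested), and MSE /
  MAE / R² for the diameters;
* **Feret-diameter morphometry** of binary masks (max pairwise boundary
  distance via convex hull, perpendicular extent for the short diameter) —
  both the measurement step of the segment-then-measure baseline and the
  consistency oracle of the generator;
* a training harness: Adam, best-on-validation checkpointing, early
  stopping, repeated runs with mean ± sd aggregation, and the plain-U-Net
  segment-then-measure baseline for the joint-vs-pipeline comparison.

## Worked example

```r
library(plaquenet)

# one synthetic plaque phantom with exactly known ground truth
cfg <- smoke_phantom_config(seed = 42)
s <- generate_sample(cfg, 0L)
print(s)
#> phantom sample phantom_000000: 64 x 64 px at 0.150 mm/px
#>   plaque: long 4.80 mm, short 3.17 mm, 528 mask pixels

# caliper morphometry of the mask closes on the analytic ground truth
measure_diameters(s$mask, s$pixel_spacing_mm)
#> plaque diameters: long 4.708 mm, short 3.116 mm

# the network
model <- build_model(model_config(depth = 3, base_channels = 8))
print(model)
#> dual-branch plaque network: depth 3, base 8 channels, multi-layer ECA (2 x 1D conv)
#>   125708 trainable parameters, 2 classes + 2 diameters
```

The long diameter the generator recorded (4.80 mm = twice the drawn
semi-axis) and the mask measurement (4.71 mm) agree to within one pixel
spacing (0.15 mm) — the closure property tying the simulator to the
measurement oracle.

A full desk-scale experiment — generate phantoms, split, train twice,
evaluate on the held-out test split:

```r
dir <- tempfile()
man <- write_dataset(generate_dataset(smoke_phantom_config(seed = 11), 180), dir)
man <- split_manifest(man, split_spec(c(6, 1, 2), seed = 11))

fit <- plaquenet(man, smoke_train_config(seed = 7))   # one training run
evaluate_model(fit, man)                              # Dice, IoU, MSE/MAE/R2 ...

report <- run_experiment(man, smoke_train_config(seed = 7))  # 2 reps, mean +/- sd
print(report)
```

On 64×64 phantoms with 4-look speckle this reaches test Dice ≈ 93 % and
long-diameter R² ≈ 0.80 in a couple of minutes per repetition on one CPU
(under heavy 1-look speckle: Dice ≈ 92 %, R² ≈ 0.77). `predict()` on a
fitted model returns per-image masks, plaque-probability maps and diameter
predictions in mm; `plot()` draws the training curves.

A thin CLI over the same functions is in `inst/cli/plaquenet.R`
(`generate`, `split`, `augment`, `measure`, `evaluate` subcommands).

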