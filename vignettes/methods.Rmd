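---
title: "attdunet: model, phantoms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{attdunet: model, phantoms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(attdunet)
```

This vignette documents the science and the engineering judgement
calls inside `attdunet`: what the model assumes, which knobs matter,
what the phantom generator does and does not emulate, and where the
numerics could surprise you.

## The segmentation model

The network maps a grayscale image to two-class per-pixel logits
through a densely connected encoder, an attention-equipped decoder and
a scale-fusion head. Its design assumptions are those of breast
ultrasound: a single lesion (or none) per image, darker than its
surroundings on average but embedded in strong multiplicative texture,
with size varying over an order of magnitude — hence dense feature
reuse in the encoder (small datasets), per-pixel gating of skip
connections (background suppression), and explicit multi-scale fusion
at the end (scale variability).

### Dense encoder

Each dense layer applies BN → ReLU → 3×3 convolution (pre-activation
order) to the concatenation of everything produced before it in the
block, emitting `growth_rate` new channels; after `L` layers a block
entered with `C` channels exits with `C + L·growth_rate`. Transitions
compress with a 1×1 convolution to `ceiling(compression · C)` channels
and 2×2 average-pool (odd trailing rows/columns are floor-dropped, so
inputs are required to be divisible by 16 — four halvings). A fifth
dense block without transition forms the bottleneck.

### Attention modules

*Attention gate.* `alpha = sigmoid(psi' relu(Wx'x + Wg'g + b_g) +
b_psi)` computed at the skip feature's grid; when the architecture
hands the gate a coarser gating map it is bilinearly resized to `x`'s
grid first (the gate never subsamples `x`). The intermediate width is
`F_int = max(C_x/2, 1)`. Gate projections are initialized from a
zero-mean normal with sd 0.02 — a gate should start near-neutral
(alpha ≈ 0.5 everywhere, since psi'·(...) ≈ 0), and larger random
projections would randomly suppress half the skip content at step 0.

*Channel attention.* One MLP (`C → max(C/r, 1) → C`), shared between
the average-pooled and max-pooled channel vectors; the two outputs are
summed before the sigmoid. Sharing is deliberate: the two pooled
statistics live in the same feature space, and a shared bottleneck
halves the parameters of what is already the most parameter-dense part
of small models. The residual form `x·beta + x` keeps the module a
strict amplifier (output between `x` and `2x` for non-negative
activations), so an untrained CA cannot destroy signal.

*Scale attention.* The four decoder outputs are resized to input
resolution, compressed to 4 channels each and concatenated into the
16-channel hybrid `F`. The channel branch maps the 16 pooled features
to **4** coefficients — one per scale, not one per channel; each
coefficient scales its scale's 4-channel group. The spatial branch is
3×3 conv → ReLU → 1×1 conv → sigmoid on `F·gamma` (hidden width
`la_mid = 8`): the minimal stack that can produce a per-pixel
coefficient from local context. The output `F + F·gamma +
F·gamma·gamma*` degenerates gracefully: with `gamma ≡ 0` it is exactly
`F`, so the head still sees the raw multi-scale evidence.

The channel branch emits the coefficient vector directly (no residual
re-scaling of `F` inside the branch): the fusion formula consumes
`gamma` as a standalone weight, so a residual form there would
double-count `F`.

### Parameters that matter

| parameter | default | why |
|---|---|---|
| `growth_rate` | 16 (desk: 6) | channels added per dense layer; linear in both compute and capacity |
| `block_layers` | 4,4,4,4 (desk: 2,2,2,2) | dense depth per stage |
| `compression` | 0.5 | transition channel keep-fraction; 1.0 disables compression |
| `reduction_r` | 16 (desk: 4) | CA bottleneck `C/r`, clipped to ≥ 1 unit |
| `decoder_channels` | 128,64,32,16 (desk: 24,16,12,8) | widths of the four decoder levels, deepest first |
| `learning_rate` | 1e-4 | Adam step size; the protocol value, no schedule |
| `batch_size` | 8 | BN statistics get noisy below ~4 |
| `epochs` | 200 (desk preset: 25) | protocol value; desk preset sized for CPU minutes |

The architecture widths are the one place the source protocol is
silent, so they are configuration, not constants: `model_config()`
carries defaults with a plausibly paper-scale footprint, and
`desk_config()` is the preset actually exercised by the test suite,
sized so that three complete 200-phantom trainings fit a 25-minute
single-CPU budget. "Momentum 0.9" for Adam is read as β₁ = 0.9
(β₂ = 0.999, ε = 1e-8); there is no weight decay, no LR schedule and
no early stopping — the best epoch is kept by validation Dice, which
is a usability addition, not part of the optimization.

## Training pipeline

Images are standardized with mean/sd computed **from the training
split only** (stored in the checkpoint and reapplied at inference;
computing them on everything would leak test statistics into
training). Augmentation applies horizontal and vertical flips
independently (p = 0.5 per axis) and, with probability 0.5, an
isotropic rescale drawn from [0.8, 1.25] followed by center
crop/zero-pad back to size — "scaled according to probability" made
concrete; the range is configuration. Masks ride along under the
identical coordinate transform and stay strictly binary (nearest-
neighbor everywhere a mask is resampled). The 80/20 split is a seeded
shuffle with `|train| = round(0.8 n)`; the held-out 20% doubles as the
validation set (the protocol has no third split).

Predictions binarize by argmax over the two softmax channels, ties to
background. Mask PNGs binarize at 0.5 on load.

## The phantom generator

`generate_phantom()` emulates the three properties of breast
ultrasound that drive the architecture, and only those:

1. **a single star-convex lesion** — an ellipse (radius drawn from
   `radius_range`, aspect ratio up to e^±0.4, random orientation)
   whose radius is modulated per angle by a smooth low-order Fourier
   perturbation of amplitude `irregularity` (clamped at 0.3× base
   radius so the region stays star-convex, hence one connected
   component). The exact interior is the ground-truth mask.
2. **darker lesion interior** — the background level `bg_level`
   (0.75) is attenuated by `lesion_contrast` (0.65) inside a slightly
   blurred mask, giving soft margins.
3. **multiplicative speckle** — squared magnitude of a
   Gaussian-smoothed complex Gaussian field (Rayleigh-like intensity),
   averaged over `looks = 4` independent draws (spatial compounding),
   normalized to mean 1, and blended with amplitude
   `speckle_scale = 0.8` (0 = noise-free, 1 = full field); grain size
   is `speckle_corr = 1.5` px. A final Gaussian blur
   (`blur_sigma = 0.8`) stands in for system PSF.

Defaults were chosen once, as a plausibly realistic mid-difficulty
setting: lesions occupy ~2–25% of the image, contrast is strong enough
that an expert would trace them but weak enough that plain
thresholding fails on speckle. What the generator does **not**
emulate: acoustic shadowing and posterior enhancement, probe-geometry
artifacts, multiple or zero lesions, calcifications, and real
annotation noise. A green end-to-end test therefore establishes that
the implementation can learn this family of textures — it says nothing
about clinical performance on real ultrasound, which is exactly why
the paper-scale table numbers are out of the package's acceptance
scope.

## Numerical choices

* **Tensors** are `(H, W, C, N)` arrays — spatial index fastest in
  column-major storage, so the im2col/GEMM convolution kernels run
  copy-free. Convolutions are stride-1, odd-kernel, "same"
  zero-padding.
* **Autodiff** is a linear tape of R environments; backward walks in
  reverse creation order so every node's gradient is complete before
  it propagates. Gradients are verified against central finite
  differences for every primitive in the test suite.
* **Batch norm** uses per-channel batch statistics over (H, W, N) in
  training with momentum-0.1 running averages (unbiased variance
  stored) for evaluation; ε = 1e-5. Evaluating an untrained model uses
  the initial (0, 1) running statistics — harmless, but epoch-0
  metrics are meaningless by construction.
* **Bilinear resize** uses half-pixel centers without corner
  alignment; nearest-neighbor resize maps output pixel *i* to input
  pixel `floor((i + 0.5)·in/out)`.
* **Global max pooling** routes its gradient to the first argmax in
  column-major order on exact ties (measure-zero for real
  activations).
* **Softmax cross-entropy** subtracts the per-pixel max before
  exponentiation and clips probabilities at 1e-12 inside the log.
* **Empty-mask convention**: when prediction and truth are both empty
  (TP+FP+FN = 0) all five metrics return 1 — two raters agreeing on
  "no lesion" is perfect agreement, and no 0/0 arises. PPV/SEN/F1
  return 0 when their denominator vanishes but foreground exists.
* **Metrics are averaged per image**, then across images — not
  computed from pooled counts. Pooling would let large lesions
  dominate, and per-image averaging is the only scheme under which
  Dice and F1 (pointwise identical per confusion table) can differ in
  a reported average, which the evaluation tables this package is
  modelled on do show.
* **Determinism**: everything stochastic (init, shuffling,
  augmentation, phantoms) draws from R's RNG under one seed; two runs
  with the same seed on the same platform produce bit-identical
  histories, checkpoints and PNGs.

## Known limitations

* Single-lesion, two-class segmentation only; no multi-class output,
  no 3D, no deep supervision.
* CPU-only; the desk preset is sized for minutes per run, the
  paper-scale default config trains in hours, not minutes.
* The Adam "one small step strictly decreases the loss" property is
  checked at lr = 1e-5; at the training rate 1e-4 individual steps may
  transiently increase the loss, as usual.
* Checkpoints are RDS files — convenient and exact within R, but not a
  cross-language exchange format.
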