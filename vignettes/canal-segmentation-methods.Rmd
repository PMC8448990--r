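---
title: "Segmenting semicircular canals with an attention-augmented 3D U-Net"
author: "canalseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting semicircular canals with an attention-augmented 3D U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The semicircular canals of the inner ear are three membranous tubes, each
following roughly two-thirds of a circle about 6.5 mm in diameter. On a
temporal-bone CT volume they occupy well under 1% of the voxels, which makes
manual slice-by-slice annotation slow and makes the segmentation task an
extreme class-imbalance problem: a segmenter that predicts "background
everywhere" is 99%+ voxel-accurate and clinically useless.

`canalseg` implements a volumetric encoder--decoder segmenter for this
setting: a 3D U-Net whose skip connections are replaced by attention
modules, trained with the Dice loss on foreground-guaranteed patches, and
applied to whole volumes by overlap-averaged sliding-window inference.
Because clinical CT with voxel-level canal annotations is not freely
redistributable, the package also ships a synthetic phantom generator that
reproduces the documented geometry of the task, so the entire pipeline is
testable end to end on any machine.

## Network architecture

The encoder has `nPool + 1` levels (default 3 poolings, so an 8x
downsampled bottleneck). Each level applies two 3x3x3 convolutions, each
followed by batch normalization and a ReLU; levels are separated by 2x2x2
max pooling. Default channel widths are 32, 64, 128 at the first three
levels. The printed protocol stops there; we continue the doubling pattern
to 256 at the bottleneck, and the widths remain configurable.

Two attention mechanisms replace the usual skip connections:

* **3D spatial squeeze-and-excitation (sSE).** A 3x3x3 convolution squeezes
  the `C`-channel feature map `U0` to a single-channel projection `U1`; the
  sigmoid `sigma(U1)` is a spatial gate in (0, 1) and the output is
  `U2 = sigma(U1) * U0`, broadcast over channels. The gate can attenuate
  but never amplify, which the tests assert elementwise.

* **3D global attention upsample (GAU).** At each decoder stage the
  low-level map `F1` (channels `C_L`) passes through a 1x1x1 convolution +
  BN + ReLU; the high-level map `F2` is globally average-pooled and mapped
  to channel weights `W1`, which gate the low path channelwise (`F3`). `F2`
  is also upsampled by a transposed convolution + BN (`F4`), and the stage
  output is `F5 = F3 + F4`.

The `variant` field of `networkConfig()` selects the wiring:
`baseline_3dunet` (transposed-conv + concatenation decoder), `sse_only`
(gated encoder, baseline decoder), `gau_only` (plain encoder, GAU decoder),
and the three combined arrangements `sequential_spatial_first` (default),
`sequential_channel_first`, and `parallel`. The three combined arrangements
own identical submodules and differ only in wiring, so their parameter
counts are identical — a property the tests check, along with the exact
parameter cost of adding sSE.

### Choices the protocol left open

* **GAU gate path.** The source description does not say how the pooled
  `C_H`-vector is matched to `C_L` channels. We use a 1x1x1 convolution +
  BN + ReLU on the pooled vector, following the pyramid-attention design the
  module descends from.
* **Upsampling anisotropy.** The printed transposed-convolution geometry
  (kernel 1x4x4, stride 1x2x2) cannot restore a depth axis halved by 2x2x2
  pooling. The default `gauUpsampleMode = "isotropic"` uses kernel 4,
  stride 2 on all axes; `"inplane"` keeps the printed in-plane-only
  upsampling and pairs it with 1x2x2 pooling so shapes stay consistent.
* **Bottleneck gating.** The combined arrangements also gate the bottleneck
  features with sSE before the first GAU stage (`sseBottleneck = TRUE`,
  flaggable).
* **Initialization.** Kaiming fan-in for convolutions, identity batch
  norms, and the head bias at `qlogis(0.01)`. The last choice encodes the
  known foreground prior: with under 1% foreground, a head that starts at
  logit 0 predicts probability 0.5 everywhere and the Dice denominator is
  dominated by background for many steps.

## Training

Training minimizes the soft Dice loss
`1 - (2 * sum(p g) + s) / (sum(p) + sum(g) + s)` with smoothing
`s = 1e-5` (the smoothing keeps all-background patches finite; at binary
predictions and `s -> 0` the loss is exactly `1 - DSC`). Patches are
sampled *positively*: the crop origin is drawn uniformly among all
placements whose window contains at least one foreground voxel, computed
exactly with a 3D summed-area table. Without this constraint nearly every
64x64x32 crop of a canal volume would be empty.

The protocol-faithful profile (`trainingConfig()`) uses 64x64x32 patches
(stored as D = 32, H = W = 64), batch size 8, Adam at learning rate 1e-4
with weight decay 5e-4 and first-moment decay 0.97 — the protocol's
"momentum" with Adam is read as Adam's beta1, since Adam has no separate
momentum term; an SGD-with-momentum option is provided. Total steps are
configurable (the protocol does not state them). Validation runs full
sliding-window inference every `validationInterval` steps and retains the
weights with the best mean DSC.

Two numerical details matter on small budgets:

* **Batch-norm recalibration.** With small batches and fast optimization,
  batch-norm running averages lag the weights, and the mismatch compounds
  across layers until evaluation-mode forwards disagree wildly with
  training-mode forwards. `calibrateBatchNorm()` recomputes the running
  statistics as the average of batch statistics under frozen weights; the
  trainer does this before every validation sweep and at the end of
  training.
* **Desk-scale profile.** `trainingConfigSmall()` (16x32x32 patches, batch
  2, learning rate 1e-3) is the configuration used by the package's own
  tests; the larger step size suits runs of a few hundred steps.

Everything is seeded: network initialization, patch sampling, and phantom
generation all derive from explicit integer seeds, and two runs with the
same configuration produce identical loss traces in single-threaded mode.

## Inference

`predictVolume()` slides a patch (default 64x64x32 in X/Y/Z, i.e. D = 32)
with steps of 28 in-plane and 8 along Z — on the 512x512x64 clinical grid
this gives 17 x 17 x 5 = 1445 windows — accumulating raw logits and a
per-voxel count matrix. Averaged logits pass through a sigmoid and a 0.5
threshold (configurable). The stated order is ambiguous about whether
accumulation happens before or after the sigmoid; logits-first is the
default and `average = "probabilities"` provides the alternative. Axes not
aligned with the stride get one final window clamped to the volume edge, so
every voxel is covered at least once.

## Evaluation metrics

* **DSC** `= 2|P n G| / (|P| + |G|)` — voxel overlap.
* **AVD** — the maximum of the two directed mean nearest-neighbor
  distances between the voxel sets, in mm.
* **ASD** — surface distances pooled symmetrically over both masks'
  surface voxels and divided by the total surface count.

A *surface voxel* is a foreground voxel with at least one face-adjacent
(6-connectivity) neighbor that is background or outside the grid — the
most common convention; the source does not define one. Distances are
Euclidean in physical mm; at the 1 mm isotropic spacing of the target
protocol they equal voxel units. Empty masks (or empty surfaces) raise
errors rather than returning sentinels, because a silent 0 or infinity
corrupts case averages. All three metrics are validated against
brute-force set-enumeration oracles on randomized grids, and AVD/ASD scale
linearly with the voxel spacing while DSC is spacing-invariant.

## The phantom generator

`generatePhantom()` emulates what is documented about the clinical data:
512x512x64 voxels at 1 mm spacing, three canals per side, each a tube of
radius 1 mm following two-thirds of a 6.5 mm circle, with the three arc
planes near-orthogonal and randomly jittered; a brighter bone-like shell
(1.5 mm) surrounds each lumen, and additive Gaussian noise (sd 15) covers
everything. Intensity levels (background 40, bone 700, lumen 140, arbitrary
units) are free parameters chosen so the lumen-background contrast is
several noise standard deviations — the source reports no intensity
statistics, so these are properties of the phantom, not claims about CT.
The resulting foreground fraction is far below the documented 1% ceiling.

What the phantom does *not* model: real temporal-bone anatomy (ossicles,
cochlea, air cells), CT reconstruction physics, beam hardening, partial
volume effects, or inter-patient anatomical variability. Passing tests on
phantoms therefore demonstrate that the architecture, loss, sampling,
inference, and metrics are implemented correctly and that the network can
learn tubular structures under extreme class imbalance — not that the
reported clinical accuracy transfers.

`smallPhantomSpec()` (48x96x96 voxels) keeps the same canal geometry in a
volume small enough for CPU test runs; `generateDataset()` derives
per-volume seeds from a master seed with default split sizes 26/7/6,
mirroring the clinical study's case layout.

## Problem sizes used by the tests

The package's own test suite and acceptance script run everything at desk
scale, chosen once as the smallest sizes that still exercise each property:
reduced channel widths (8-16-32-64), 16x32x32 patches, 48x96x96 phantoms,
200-step overfitting runs and a 500-step generalization run on 8 training
phantoms. The full-resolution settings remain the defaults of
`networkConfig()`, `trainingConfig()` and `slidingSpec()`.

## Known limitations

* Training on CPU at full protocol scale (full channels, batch 8,
  64x64x32 patches, thousands of steps) is possible but slow; the package
  targets correctness and desk-scale experiments, not GPU throughput.
* Batch norm with batch size 1 and tiny spatial extents (the GAU gate path
  at 1x1x1) degenerates to the beta offset during training; batches of 2+
  avoid this.
* Binary (single-class) segmentation only; no test-time augmentation,
  Gaussian window blending, or connected-component post-processing.
* The AVD/ASD nearest-neighbor search is exact brute force — fine for
  sparse structures like canals, quadratic for dense masks.
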