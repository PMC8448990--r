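# canalseg

Volumetric segmentation of the semicircular canals — the three ~6.5 mm
circular tubes of the inner-ear vestibular system — from CT volumes, for
researchers in medical image analysis who need a fully inspectable,
CPU-runnable implementation of an attention-augmented 3D U-Net pipeline.

The canals occupy well under 1% of a 512×512×64 temporal-bone CT volume, so
the package combines four ingredients tuned to extreme class imbalance:

* **Network.** A 3D U-Net encoder (two 3×3×3 conv + BN + ReLU per level,
  2×2×2 max pooling, channels 32–64–128–256) whose skip connections are
  replaced by attention: 3D *spatial squeeze-and-excitation* gates
  `U2 = σ(U1) ⊙ U0` on the encoder features (with `U1` a 1-channel 3×3×3
  squeeze projection), and cascaded 3D *global-attention-upsample* decoder
  stages `F5 = F3 + F4`, where `F3` is the 1×1×1-transformed low-level map
  gated channelwise by the globally pooled high-level features and `F4` is
  the transposed-conv upsampled high-level map. Six wiring variants
  (baseline U-Net, GAU-only, sSE-only, sequential spatial-first / channel-
  first, parallel) support ablation; spatial-first sequential is the
  default.
* **Training.** Soft Dice loss `1 − (2Σpg + s)/(Σp + Σg + s)`, patches
  sampled only at positions guaranteed to contain foreground, Adam
  (lr 1e-4, β₁ 0.97, weight decay 5e-4) with batch 8 in the
  protocol-faithful profile.
* **Inference.** Overlapping 64×64×32 patches slid 28/28/8 voxels in
  X/Y/Z, logits averaged per voxel by a coverage count matrix, then
  sigmoid and threshold.
* **Metrics.** Dice coefficient (DSC), average Hausdorff distance (AVD,
  mm) and average symmetric surface distance (ASD, mm), each validated
  against brute-force voxel-set oracles.

Clinical canal annotations are not freely available, so the package ships a
**synthetic phantom generator** (tubular two-thirds arcs of 6.5 mm circles,
bone-like shells, Gaussian noise, <1% foreground) that makes the entire
pipeline — including learning — reproducible on any machine. The conv-net
layers themselves (3D convolution and its gradients, transposed conv, batch
norm, pooling) are implemented in the package on compiled im2col/GEMM
kernels with a minimal reverse-mode tape, so there is no deep-learning
framework dependency.

## Worked example

```r
library(canalseg)

# a reduced-width network and a desk-scale phantom dataset
cfg <- networkConfig(encoderChannels = c(8, 16, 32, 64))
net <- buildNetwork(cfg, seed = 1)
net
#> canalseg attention 3D U-Net ('sequential_spatial_first'): channels
#> 8-16-32-64, 3 pooling stage(s), 400,213 parameters

ds <- generateDataset(smallPhantomSpec(), nTrain = 8, nVal = 0, nTest = 2,
                      seed = 99)
ds$train[[1]]
#> LabeledVolume: 48x96x96 voxels @ 1x1x1 mm, foreground 0.0597%

fit <- trainNetwork(cfg, trainingConfigSmall(maxSteps = 500, seed = 7),
                    ds$train)
sl <- slidingSpec(patchSize = c(16, 32, 32), steps = c(8, 16, 16))
evaluateCases(fit$model, ds$test, sl)
#>   case       dsc      avd       asd note
#> 1    1 0.6139089 0.984988 0.7561245
#> 2    2 0.5681342 1.026186 0.8001734
#> 3 mean 0.5910215 1.005587 0.7781489
```

The table mirrors the per-case + mean layout of a clinical evaluation:
after 500 CPU training steps on eight small phantoms the model recovers
about 59% Dice overlap on held-out phantoms with sub-millimetre mean
surface error, versus 0 Dice for an untrained network (its prediction is
empty). (Full-scale
training uses `trainingConfig()` defaults and many more steps.)

The same pipeline is scriptable from a shell via the bundled CLI
(`system.file("scripts", "canalseg", package = "canalseg")`):

```sh
canalseg generate --out data --n-train 8 --n-test 2 --seed 99 --small
canalseg train    --data data --out run  --config desk-config.yaml
canalseg predict  --checkpoint run/checkpoint.rds --in data/test001_img.nii.gz \
                  --out pred/test001.nii.gz --config desk-config.yaml
canalseg evaluate --pred pred --truth truth --out eval
```

Every subcommand writes a JSON run manifest (resolved configs, seeds, input
checksums) beside its outputs. A ready-made desk-scale YAML config ships at
`system.file("extdata", "desk-config.yaml", package = "canalseg")`.

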