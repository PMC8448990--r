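#' @useDynLib canalseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif
NULL

NETWORK_VARIANTS <- c("baseline_3dunet", "gau_only", "sse_only",
                      "sequential_spatial_first", "sequential_channel_first",
                      "parallel")

## ---- PhantomSpec -----------------------------------------------------------

#' Synthetic canal phantom specification
#'
#' Describes a CT-like volume containing semicircular-canal-shaped targets:
#' tubular arcs, each spanning a fraction of a circle, embedded in a noisy
#' background with a bright bone-like shell around the lumen. The defaults
#' emulate the documented clinical acquisition: 512 x 512 x 64 voxels at 1 mm
#' isotropic spacing, canals following roughly two-thirds of a circle of
#' 6.5 mm diameter, and a label foreground fraction well under 1 percent.
#'
#' @slot volumeShape integer(3), voxel counts as (D, H, W) = (slices, rows, columns).
#' @slot spacingMm numeric(3), voxel size in mm per axis.
#' @slot canalDiameterMm diameter of the circle each canal arc follows (mm).
#' @slot arcFraction fraction of a full circle each canal spans, in (0, 1].
#' @slot tubeRadiusMm lumen tube radius (mm).
#' @slot shellMm thickness of the bone-like shell dilated around the lumen (mm).
#' @slot nCanals number of canal arcs per side.
#' @slot bilateral logical; generate a mirrored second canal group.
#' @slot intensityBackground,intensityBone,intensityLumen mean intensities
#'   (arbitrary CT-like units) for background, bone shell, and lumen.
#' @slot noiseSigma standard deviation of the additive Gaussian noise.
#' @slot seed integer RNG seed; all phantom randomness derives from it.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  volumeShape = "integer", spacingMm = "numeric", canalDiameterMm = "numeric",
  arcFraction = "numeric", tubeRadiusMm = "numeric", shellMm = "numeric",
  nCanals = "integer", bilateral = "logical",
  intensityBackground = "numeric", intensityBone = "numeric",
  intensityLumen = "numeric", noiseSigma = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 8L))
    msg <- c(msg, "volumeShape must be 3 voxel counts, all >= 8")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 positive values")
  if (object@arcFraction <= 0 || object@arcFraction > 1)
    msg <- c(msg, "arcFraction must lie in (0, 1]")
  if (object@tubeRadiusMm <= 0) msg <- c(msg, "tubeRadiusMm must be > 0")
  if (object@canalDiameterMm <= 0) msg <- c(msg, "canalDiameterMm must be > 0")
  if (object@nCanals < 0L) msg <- c(msg, "nCanals must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a phantom specification
#'
#' @param volumeShape voxel counts (D, H, W); default matches the clinical
#'   acquisition, 64 slices of 512 x 512.
#' @param spacingMm voxel spacing in mm.
#' @param canalDiameterMm,arcFraction canal arc geometry; defaults 6.5 mm and
#'   2/3 of a full circle.
#' @param tubeRadiusMm,shellMm lumen radius and bone-shell thickness (mm).
#' @param nCanals arcs per side; @param bilateral mirrored second side.
#' @param intensityBackground,intensityBone,intensityLumen intensity means.
#' @param noiseSigma additive Gaussian noise sd.
#' @param seed integer seed.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- smallPhantomSpec(seed = 1)
#' spec
#' @export
phantomSpec <- function(volumeShape = c(64L, 512L, 512L), spacingMm = c(1, 1, 1),
                        canalDiameterMm = 6.5, arcFraction = 2 / 3,
                        tubeRadiusMm = 1.0, shellMm = 1.5, nCanals = 3L,
                        bilateral = TRUE, intensityBackground = 40,
                        intensityBone = 700, intensityLumen = 140,
                        noiseSigma = 15, seed = 1L) {
  new("PhantomSpec", volumeShape = as.integer(volumeShape),
      spacingMm = as.numeric(spacingMm), canalDiameterMm = canalDiameterMm,
      arcFraction = arcFraction, tubeRadiusMm = tubeRadiusMm, shellMm = shellMm,
      nCanals = as.integer(nCanals), bilateral = bilateral,
      intensityBackground = intensityBackground, intensityBone = intensityBone,
      intensityLumen = intensityLumen, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

#' Reduced phantom specification for desk-scale runs
#'
#' Same canal geometry as [phantomSpec()] in a 48 x 96 x 96 volume, sized so
#' correctness experiments run in seconds on one CPU.
#'
#' @param ... overrides passed to [phantomSpec()].
#' @return A [PhantomSpec-class] object.
#' @export
smallPhantomSpec <- function(...) {
  args <- list(...)
  defaults <- list(volumeShape = c(48L, 96L, 96L))
  do.call(phantomSpec, utils::modifyList(defaults, args))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ %s mm, %d canal(s)%s\n",
              paste(object@volumeShape, collapse = "x"),
              paste(object@spacingMm, collapse = "x"),
              object@nCanals, if (object@bilateral) " per side (bilateral)" else ""))
  cat(sprintf("  arc: %.2f of a circle, diameter %.2f mm, lumen radius %.2f mm\n",
              object@arcFraction, object@canalDiameterMm, object@tubeRadiusMm))
  cat(sprintf("  intensities bg/bone/lumen: %g/%g/%g, noise sd %g, seed %d\n",
              object@intensityBackground, object@intensityBone,
              object@intensityLumen, object@noiseSigma, object@seed))
})

## ---- LabeledVolume ---------------------------------------------------------

#' A CT-like intensity volume with aligned binary labels
#'
#' @slot intensities numeric 3D array (D, H, W).
#' @slot labels integer/numeric 3D array of the same shape, values in \{0, 1\}.
#' @slot spacingMm numeric(3) voxel size in mm.
#' @exportClass LabeledVolume
setClass("LabeledVolume", representation(
  intensities = "array", labels = "array", spacingMm = "numeric"))

setValidity("LabeledVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@intensities), dim(object@labels)))
    msg <- c(msg, "intensities and labels must have identical shape")
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "volumes must be 3D (D, H, W)")
  if (!all(object@labels %in% c(0, 1)))
    msg <- c(msg, "labels must take only values 0 and 1")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' @rdname LabeledVolume-class
#' @param intensities,labels aligned 3D arrays (D, H, W).
#' @param spacingMm voxel spacing in mm.
#' @export
labeledVolume <- function(intensities, labels, spacingMm = c(1, 1, 1)) {
  new("LabeledVolume", intensities = intensities, labels = labels,
      spacingMm = as.numeric(spacingMm))
}

setMethod("show", "LabeledVolume", function(object) {
  fg <- mean(object@labels)
  cat(sprintf("LabeledVolume: %s voxels @ %s mm, foreground %.4f%%\n",
              paste(dim(object@intensities), collapse = "x"),
              paste(object@spacingMm, collapse = "x"), 100 * fg))
})

#' Accessors for LabeledVolume
#'
#' @param x a [LabeledVolume-class].
#' @return `intensities()`/`labels3d()` return the 3D arrays; `spacingMm()`
#'   the voxel size in mm.
#' @export
intensities <- function(x) x@intensities

#' @rdname intensities
#' @export
labels3d <- function(x) x@labels

#' @rdname intensities
#' @export
spacingMm <- function(x) x@spacingMm

## ---- NetworkConfig ---------------------------------------------------------

#' Network architecture configuration
#'
#' Selects the encoder widths, pooling depth, and the attention arrangement
#' variant. `sequential_spatial_first` (spatial gate on the encoder features,
#' then the global-attention-upsample fusion) is the default arrangement;
#' `baseline_3dunet` is the plain transposed-conv + concatenation U-Net used
#' as the ablation benchmark.
#'
#' @slot encoderChannels integer vector of per-level channel widths
#'   (length `nPool + 1`); default 32, 64, 128, 256.
#' @slot nPool number of 2x pooling stages (default 3, i.e. 8x downsampling
#'   at the bottleneck).
#' @slot variant one of `baseline_3dunet`, `gau_only`, `sse_only`,
#'   `sequential_spatial_first`, `sequential_channel_first`, `parallel`.
#' @slot gauUpsampleMode `"isotropic"` (4/2/1 transposed conv on all axes,
#'   paired with 2x2x2 pooling) or `"inplane"` (in-plane-only 1x4x4 /
#'   1x2x2 upsampling paired with 1x2x2 pooling, leaving depth untouched).
#' @slot sseBottleneck logical; apply the spatial gate to the bottleneck
#'   features before the first decoder fusion.
#' @exportClass NetworkConfig
setClass("NetworkConfig", representation(
  encoderChannels = "integer", nPool = "integer", variant = "character",
  gauUpsampleMode = "character", sseBottleneck = "logical"))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (length(object@encoderChannels) != object@nPool + 1L)
    msg <- c(msg, "encoderChannels must have length nPool + 1")
  if (any(object@encoderChannels < 1L)) msg <- c(msg, "channel widths must be >= 1")
  if (!object@variant %in% NETWORK_VARIANTS)
    msg <- c(msg, paste("variant must be one of:", paste(NETWORK_VARIANTS, collapse = ", ")))
  if (!object@gauUpsampleMode %in% c("isotropic", "inplane"))
    msg <- c(msg, "gauUpsampleMode must be 'isotropic' or 'inplane'")
  if (length(msg)) msg else TRUE
})

#' @rdname NetworkConfig-class
#' @param encoderChannels,nPool,variant,gauUpsampleMode,sseBottleneck see slots.
#' @return A [NetworkConfig-class] object.
#' @examples
#' networkConfig(encoderChannels = c(8, 16, 32, 64))
#' @export
networkConfig <- function(encoderChannels = c(32L, 64L, 128L, 256L), nPool = 3L,
                          variant = "sequential_spatial_first",
                          gauUpsampleMode = "isotropic", sseBottleneck = TRUE) {
  new("NetworkConfig", encoderChannels = as.integer(encoderChannels),
      nPool = as.integer(nPool), variant = variant,
      gauUpsampleMode = gauUpsampleMode, sseBottleneck = sseBottleneck)
}

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: variant '%s', channels %s, %d pooling stage(s), upsample '%s'\n",
              object@variant, paste(object@encoderChannels, collapse = "-"),
              object@nPool, object@gauUpsampleMode))
})

#' Supported attention-arrangement variants
#' @return Character vector of valid `variant` names for [networkConfig()].
#' @export
networkVariants <- function() NETWORK_VARIANTS

## ---- SlidingSpec -----------------------------------------------------------

#' Sliding-window inference specification
#'
#' Patch geometry for overlap-averaged whole-volume prediction. Defaults
#' follow the documented protocol: 64 x 64 x 32 patches (X, Y, Z) slid with
#' steps of 28 in-plane and 8 along Z. Internally the package stores volumes
#' as (D, H, W) = (Z, Y, X); `slidingSpec()` takes that internal order.
#'
#' @slot patchSize integer(3) patch voxels (D, H, W).
#' @slot steps integer(3) per-axis strides (D, H, W).
#' @slot threshold probability threshold for binarization, in (0, 1).
#' @exportClass SlidingSpec
setClass("SlidingSpec", representation(
  patchSize = "integer", steps = "integer", threshold = "numeric"))

setValidity("SlidingSpec", function(object) {
  msg <- character()
  if (any(object@steps < 1L) || any(object@steps > object@patchSize))
    msg <- c(msg, "steps must satisfy 0 < step <= patch size on every axis")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname SlidingSpec-class
#' @param patchSize,steps,threshold see slots.
#' @return A [SlidingSpec-class] object.
#' @export
slidingSpec <- function(patchSize = c(32L, 64L, 64L), steps = c(8L, 28L, 28L),
                        threshold = 0.5) {
  new("SlidingSpec", patchSize = as.integer(patchSize), steps = as.integer(steps),
      threshold = threshold)
}

setMethod("show", "SlidingSpec", function(object) {
  cat(sprintf("SlidingSpec: patch %s, steps %s, threshold %.2f\n",
              paste(object@patchSize, collapse = "x"),
              paste(object@steps, collapse = "/"), object@threshold))
})

## ---- TrainingConfig --------------------------------------------------------

#' Training configuration
#'
#' Patch-based Dice-loss training settings. Defaults follow the documented
#' protocol: 64 x 64 x 32 patches (stored internally as D = 32, H = W = 64),
#' batch size 8, Adam with learning rate 1e-4, first-moment decay 0.97 and
#' weight decay 5e-4. `trainingConfigSmall()` gives a desk-scale profile.
#'
#' @slot patchSize integer(3) training patch (D, H, W).
#' @slot batchSize patches per optimization step.
#' @slot learningRate,weightDecay,beta1,beta2 optimizer settings.
#' @slot optimizer `"adam"` (default) or `"sgd"` (momentum = beta1).
#' @slot maxSteps number of optimization steps.
#' @slot validationInterval steps between validation sweeps (0 = none).
#' @slot smooth Dice-loss smoothing constant.
#' @slot seed integer seed controlling init, sampling, and shuffling.
#' @exportClass TrainingConfig
setClass("TrainingConfig", representation(
  patchSize = "integer", batchSize = "integer", learningRate = "numeric",
  weightDecay = "numeric", beta1 = "numeric", beta2 = "numeric",
  optimizer = "character", maxSteps = "integer", validationInterval = "integer",
  smooth = "numeric", seed = "integer"))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@smooth < 0) msg <- c(msg, "smooth must be >= 0")
  if (!object@optimizer %in% c("adam", "sgd"))
    msg <- c(msg, "optimizer must be 'adam' or 'sgd'")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainingConfig-class
#' @param patchSize,batchSize,learningRate,weightDecay,beta1,beta2,optimizer,maxSteps,validationInterval,smooth,seed see slots.
#' @return A [TrainingConfig-class] object.
#' @export
trainingConfig <- function(patchSize = c(32L, 64L, 64L), batchSize = 8L,
                           learningRate = 1e-4, weightDecay = 5e-4,
                           beta1 = 0.97, beta2 = 0.999, optimizer = "adam",
                           maxSteps = 1000L, validationInterval = 100L,
                           smooth = 1e-5, seed = 1L) {
  new("TrainingConfig", patchSize = as.integer(patchSize),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      weightDecay = weightDecay, beta1 = beta1, beta2 = beta2,
      optimizer = optimizer, maxSteps = as.integer(maxSteps),
      validationInterval = as.integer(validationInterval), smooth = smooth,
      seed = as.integer(seed))
}

#' @rdname TrainingConfig-class
#' @param ... overrides passed to [trainingConfig()].
#' @export
trainingConfigSmall <- function(...) {
  args <- list(...)
  defaults <- list(patchSize = c(16L, 32L, 32L), batchSize = 2L, maxSteps = 200L,
                   validationInterval = 0L, learningRate = 1e-3)
  do.call(trainingConfig, utils::modifyList(defaults, args))
}

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf("TrainingConfig: patch %s, batch %d, %s lr %g (b1 %.2f, wd %g), %d step(s)\n",
              paste(object@patchSize, collapse = "x"), object@batchSize,
              object@optimizer, object@learningRate, object@beta1,
              object@weightDecay, object@maxSteps))
})
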