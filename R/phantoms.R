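# Synthetic canal phantoms.
#
# The generator emulates the documented statistics of the clinical CT data:
# volume size and spacing, tubular targets following ~2/3 of a 6.5 mm circle,
# three near-orthogonal canals per side, and a foreground fraction far below
# 1 percent. Geometry details (orientation jitter, shell thickness, intensity
# levels) are free parameters of the phantom, not claims about clinical data.
#
# Coordinates: voxel index (d, h, w) is 0-based in the geometry; the world
# position of a voxel center is (index + 0.5) * spacing, so rasterization
# tests voxel centers unambiguously.

unit3 <- function(v) v / sqrt(sum(v * v))

#' Centerline of one synthetic canal arc
#'
#' Samples points densely (spacing at most half the lumen radius) along a
#' circular arc of diameter `canalDiameterMm` spanning `arcFraction` of a full
#' circle. The arc plane follows one of three mutually near-orthogonal base
#' orientations, cycled by `canalIndex` and randomly jittered; bilateral specs
#' place indices `nCanals .. 2*nCanals - 1` in a mirrored second group.
#'
#' @param spec a [PhantomSpec-class].
#' @param canalIndex 0-based index in `[0, nCanals * (1 + bilateral))`.
#' @param seed optional integer; when given the jitter is drawn from a local
#'   RNG stream and the caller's RNG state is untouched.
#' @return Numeric matrix (points x 3) of (d, h, w) positions in mm.
#' @export
canalCenterline <- function(spec, canalIndex, seed = NULL) {
  validObject(spec)
  total <- spec@nCanals * (1L + spec@bilateral)
  if (canalIndex < 0 || canalIndex >= total)
    stop(sprintf("canalIndex must lie in [0, %d)", total))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  ext <- spec@volumeShape * spec@spacingMm
  side <- canalIndex %/% spec@nCanals
  slot_in_side <- canalIndex %% spec@nCanals
  center <- c(ext[1] / 2,
              ext[2] / 2,
              if (spec@bilateral) ext[3] * (0.3 + 0.4 * side) else ext[3] / 2)
  center <- center + stats::runif(3, -2, 2)
  base_normals <- diag(3)
  n <- unit3(base_normals[, (slot_in_side %% 3L) + 1L] + stats::rnorm(3, sd = 0.15))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(c(n[2] * a[3] - n[3] * a[2], n[3] * a[1] - n[1] * a[3],
               n[1] * a[2] - n[2] * a[1]))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  r <- spec@canalDiameterMm / 2
  arc_len <- 2 * pi * r * spec@arcFraction
  n_pts <- max(2L, ceiling(arc_len / (spec@tubeRadiusMm / 2)) + 1L)
  t0 <- stats::runif(1, 0, 2 * pi)
  tt <- seq(t0, t0 + 2 * pi * spec@arcFraction, length.out = n_pts)
  pts <- t(vapply(tt, function(t) center + r * (cos(t) * u + sin(t) * v),
                  numeric(3)))
  margin <- spec@tubeRadiusMm
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  bad <- which(lo < 0 | hi > ext)
  if (length(bad))
    stop(sprintf(
      "canal circle does not fit: axis %s needs [%.2f, %.2f] mm within [0, %.2f] mm (margin %.2f mm)",
      c("d", "h", "w")[bad[1]], lo[bad[1]], hi[bad[1]], ext[bad[1]], margin))
  pts
}

#' Rasterize a tube around a polyline
#'
#' Marks exactly the voxels whose center lies within `tubeRadiusMm`
#' (Euclidean, mm) of the polyline through `centerline`; a single-point
#' centerline gives a ball. The mask is clipped at the volume boundary.
#'
#' @param centerline numeric matrix (points x 3) of (d, h, w) mm positions.
#' @param tubeRadiusMm tube radius in mm (> 0).
#' @param shape integer(3) voxel counts (D, H, W).
#' @param spacingMm voxel size in mm per axis.
#' @return Logical (D, H, W) array.
#' @export
rasterizeTube <- function(centerline, tubeRadiusMm, shape, spacingMm = c(1, 1, 1)) {
  if (is.null(dim(centerline))) centerline <- matrix(centerline, nrow = 1L)
  if (nrow(centerline) == 0L) stop("empty centerline")
  if (tubeRadiusMm <= 0) stop("tube radius must be > 0")
  m <- cpp_rasterize_tube(centerline, tubeRadiusMm, as.integer(shape),
                          as.numeric(spacingMm))
  dim(m) <- as.integer(shape)
  m
}

#' Generate one synthetic canal phantom
#'
#' Labels are the union of the rasterized canal lumens. Intensities start
#' from the background level, get a brighter bone-like shell (`shellMm` thick)
#' dilated around each lumen, the lumen level inside the tubes, and additive
#' Gaussian noise. Fully deterministic given `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [LabeledVolume-class].
#' @examples
#' vol <- generatePhantom(smallPhantomSpec(seed = 7))
#' mean(labels3d(vol))  # foreground fraction, well under 1%
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec@seed)
  shape <- spec@volumeShape
  total <- spec@nCanals * (1L + spec@bilateral)
  labels <- array(FALSE, shape)
  shell <- array(FALSE, shape)
  if (total > 0L) for (i in seq_len(total) - 1L) {
    cl <- canalCenterline(spec, i)
    labels <- labels | rasterizeTube(cl, spec@tubeRadiusMm, shape, spec@spacingMm)
    shell <- shell | rasterizeTube(cl, spec@tubeRadiusMm + spec@shellMm, shape,
                                   spec@spacingMm)
  }
  base <- array(spec@intensityBackground, shape)
  base[shell & !labels] <- spec@intensityBone
  base[labels] <- spec@intensityLumen
  if (spec@noiseSigma > 0)
    base <- base + stats::rnorm(length(base), sd = spec@noiseSigma)
  labeledVolume(base, array(as.numeric(labels), shape), spec@spacingMm)
}

child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 15485863) %% 2147483647)
}

#' Generate train/validation/test phantom splits
#'
#' Draws `nTrain + nVal + nTest` phantoms with per-volume seeds derived
#' deterministically from `seed`, so no volume is shared between splits and
#' the same master seed reproduces the same splits. The default split sizes
#' mirror the 26/7/6-case layout of the clinical study.
#'
#' @param spec a [PhantomSpec-class] (its own `seed` slot is overridden per
#'   volume).
#' @param nTrain,nVal,nTest split sizes (each >= 0).
#' @param seed master seed.
#' @return List with elements `train`, `val`, `test`, each a list of
#'   [LabeledVolume-class] objects.
#' @export
generateDataset <- function(spec, nTrain = 26L, nVal = 7L, nTest = 6L,
                            seed = spec@seed) {
  stopifnot(nTrain >= 0L, nVal >= 0L, nTest >= 0L)
  total <- nTrain + nVal + nTest
  vols <- lapply(seq_len(total), function(i) {
    s <- spec
    s@seed <- child_seed(seed, i)
    generatePhantom(s)
  })
  list(train = vols[seq_len(nTrain)],
       val = if (nVal > 0L) vols[nTrain + seq_len(nVal)] else list(),
       test = if (nTest > 0L) vols[nTrain + nVal + seq_len(nTest)] else list())
}
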