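# Evaluation metrics: Dice coefficient (DSC), average Hausdorff distance
# (AVD), average symmetric surface distance (ASD), and the Dice loss used in
# training. Distances are Euclidean in physical mm (voxel offsets scaled by
# the spacing); at the 1 mm isotropic spacing of the target CT protocol they
# coincide with voxel units.

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s vs %s", paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
}

mask_coords_mm <- function(mask, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  storage.mode(idx) <- "double"
  sweep(idx, 2L, as.numeric(spacing), `*`)
}

#' Dice loss
#'
#' `1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)`, the soft Dice
#' loss over a probability map `p` and binary ground truth `g`. With
#' `smooth > 0` the value lies in `[0, 1]` and is defined on all-background
#' patches. At binary `p` and `smooth -> 0` it equals `1 - dsc(p, g)`.
#'
#' @param p numeric array of per-voxel foreground probabilities in `[0, 1]`.
#' @param g binary array of the same shape.
#' @param smooth smoothing constant added to numerator and denominator.
#' @return Scalar loss.
#' @export
diceLoss <- function(p, g, smooth = 1e-5) {
  check_same_shape(p, g)
  if (smooth < 0) stop("smooth must be >= 0")
  1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
}

# Tape op: sigmoid + Dice loss on logits (used by the trainer).
op_dice_loss <- function(tape, logits, g, smooth) {
  p <- 1 / (1 + exp(-logits$value))
  s_pg <- sum(p * g); s_p <- sum(p); s_g <- sum(g)
  den <- s_p + s_g + smooth
  num <- 2 * s_pg + smooth
  val <- 1 - num / den
  tp_record(tape, val, list(logits), function(gy) {
    gp <- -(2 * g * den - num) / den^2
    list(as.numeric(gy) * gp * p * (1 - p))
  })
}

#' Dice similarity coefficient between binary masks
#'
#' `2 |P n G| / (|P| + |G|)`: voxel-set overlap in `[0, 1]`, symmetric in its
#' arguments.
#'
#' @param P,G binary arrays of identical shape; at least one must be nonempty.
#' @return Scalar DSC.
#' @export
dsc <- function(P, G) {
  check_same_shape(P, G)
  nP <- sum(P != 0); nG <- sum(G != 0)
  if (nP + nG == 0)
    stop("DSC undefined: both masks are empty (0/0)")
  2 * sum(P != 0 & G != 0) / (nP + nG)
}

#' Average Hausdorff distance (mm)
#'
#' Maximum of the two directed average distances `d(P, G)` and `d(G, P)`,
#' where `d(A, B)` is the mean over voxels of `A` of the Euclidean distance to
#' the nearest voxel of `B`, in mm. Zero exactly when the voxel sets coincide.
#'
#' @param P,G nonempty binary arrays of identical shape.
#' @param spacing voxel size in mm per axis.
#' @return Scalar AVD in mm.
#' @export
avd <- function(P, G, spacing = c(1, 1, 1)) {
  check_same_shape(P, G)
  if (sum(P != 0) == 0 || sum(G != 0) == 0)
    stop("AVD undefined: empty mask")
  cp <- mask_coords_mm(P, spacing)
  cg <- mask_coords_mm(G, spacing)
  max(cpp_nn_mean_dist(cp, cg), cpp_nn_mean_dist(cg, cp))
}

#' Surface voxels of a binary mask
#'
#' A foreground voxel is a surface voxel when at least one of its six
#' face-adjacent neighbors is background or lies outside the grid.
#'
#' @param R binary 3D array.
#' @return Logical array of the same shape marking the surface voxels (a
#'   subset of the foreground).
#' @export
surfaceVoxels <- function(R) {
  d <- dim(R)
  if (length(d) != 3L) stop("mask must be a 3D array")
  fg <- R != 0
  pad <- array(FALSE, d + 2L)  # grid boundary counts as background
  i1 <- 2:(d[1] + 1L); i2 <- 2:(d[2] + 1L); i3 <- 2:(d[3] + 1L)
  pad[i1, i2, i3] <- fg
  interior <- pad[i1 - 1L, i2, i3] & pad[i1 + 1L, i2, i3] &
              pad[i1, i2 - 1L, i3] & pad[i1, i2 + 1L, i3] &
              pad[i1, i2, i3 - 1L] & pad[i1, i2, i3 + 1L]
  fg & !interior
}

#' Average symmetric surface distance (mm)
#'
#' Pools, over the surface voxels of both masks, the Euclidean distance to
#' the other mask's nearest surface voxel, and divides by the total surface
#' voxel count. Symmetric, non-negative, and zero exactly when the two
#' surfaces coincide.
#'
#' @param R,G binary arrays of identical shape with nonempty surfaces.
#' @param spacing voxel size in mm per axis.
#' @return Scalar ASD in mm.
#' @export
asd <- function(R, G, spacing = c(1, 1, 1)) {
  check_same_shape(R, G)
  sR <- surfaceVoxels(R)
  sG <- surfaceVoxels(G)
  nR <- sum(sR); nG <- sum(sG)
  if (nR == 0 || nG == 0)
    stop("ASD undefined: empty surface set")
  cr <- mask_coords_mm(sR, spacing)
  cg <- mask_coords_mm(sG, spacing)
  (nR * cpp_nn_mean_dist(cr, cg) + nG * cpp_nn_mean_dist(cg, cr)) / (nR + nG)
}
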