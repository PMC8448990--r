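# Whole-volume prediction by overlapping patch evaluation.
#
# Patches slide with per-axis steps; every voxel's raw logits are accumulated
# together with a count matrix recording how many windows covered it. The
# averaged logits pass through a sigmoid and a threshold to give the binary
# mask. Averaging logits first (then sigmoid) is the default; averaging
# post-sigmoid probabilities is available as an option.

#' Window start offsets along one axis
#'
#' Starts are `0, step, 2*step, ...`; when the last regular window does not
#' end at `extent`, one final start clamped to `extent - patch` is appended,
#' so the windows jointly cover the whole axis.
#'
#' @param extent axis length in voxels.
#' @param patch window length (`<= extent`).
#' @param step stride (`0 < step <= patch`).
#' @return Integer vector of 0-based start offsets.
#' @examples
#' length(windowStarts(512, 64, 28))  # 17
#' windowStarts(64, 32, 8)            # 0 8 16 24 32
#' @export
windowStarts <- function(extent, patch, step) {
  extent <- as.integer(extent); patch <- as.integer(patch); step <- as.integer(step)
  if (patch > extent)
    stop(sprintf("patch (%d) larger than extent (%d)", patch, extent))
  if (step < 1L || step > patch)
    stop("step must satisfy 0 < step <= patch")
  s <- seq.int(0L, extent - patch, by = step)
  if (s[length(s)] != extent - patch) s <- c(s, extent - patch)
  s
}

#' Sliding-window whole-volume prediction
#'
#' @param model a `canalseg_model`, or a function taking a
#'   `(1, pD, pH, pW, N)` array of patches and returning same-shaped logits
#'   (useful for stubs and tests).
#' @param vol a [LabeledVolume-class] or a plain 3D intensity array.
#' @param spec a [SlidingSpec-class]; the volume must be at least patch-sized
#'   on every axis.
#' @param normalize z-score the volume before prediction (matches training).
#' @param average `"logits"` (default: average raw logits, then sigmoid) or
#'   `"probabilities"` (sigmoid per window, then average).
#' @param batchPatches windows evaluated per model call.
#' @return List with `prob` (voxel probability map), `counts` (windows
#'   covering each voxel; minimum 1 after a full sweep), and `mask`
#'   (`prob > threshold`).
#' @export
predictVolume <- function(model, vol, spec, normalize = TRUE,
                          average = c("logits", "probabilities"),
                          batchPatches = 4L) {
  average <- match.arg(average)
  validObject(spec)
  x <- if (is(vol, "LabeledVolume")) vol@intensities else vol
  d <- dim(x)
  p <- spec@patchSize
  small <- which(d < p)
  if (length(small))
    stop(sprintf("volume smaller than patch on axis %s (%d < %d)",
                 c("D", "H", "W")[small[1]], d[small[1]], p[small[1]]))
  if (normalize) x <- normalize_volume(x)
  starts <- mapply(windowStarts, d, p, spec@steps, SIMPLIFY = FALSE)
  grid <- as.matrix(expand.grid(d = starts[[1]], h = starts[[2]], w = starts[[3]]))
  acc <- array(0, d)
  counts <- array(0L, d)
  fwd <- if (is.function(model)) model else function(xb) predictLogits(model, xb)
  nb <- max(1L, as.integer(batchPatches))
  for (g0 in seq(1L, nrow(grid), by = nb)) {
    gi <- g0:min(nrow(grid) + 0L, g0 + nb - 1L)
    xb <- array(0, c(1L, p, length(gi)))
    for (b in seq_along(gi)) {
      o <- grid[gi[b], ]
      xb[1L, , , , b] <- x[o[1] + 1:p[1], o[2] + 1:p[2], o[3] + 1:p[3]]
    }
    yb <- fwd(xb)
    if (average == "probabilities") yb <- 1 / (1 + exp(-yb))
    dim(yb) <- c(p, length(gi))
    for (b in seq_along(gi)) {
      o <- grid[gi[b], ]
      i <- o[1] + 1:p[1]; j <- o[2] + 1:p[2]; k <- o[3] + 1:p[3]
      acc[i, j, k] <- acc[i, j, k] + yb[, , , b]
      counts[i, j, k] <- counts[i, j, k] + 1L
    }
  }
  avg <- acc / counts
  prob <- if (average == "logits") 1 / (1 + exp(-avg)) else avg
  list(prob = prob, counts = counts, mask = prob > spec@threshold)
}

#' Evaluate a model over labeled cases
#'
#' Runs sliding-window prediction on every case and computes DSC, AVD and ASD
#' against the labels, reporting one row per case plus a mean row (the layout
#' of a per-sample results table). Metric errors on a case (e.g. an empty
#' prediction) are recorded in the `note` column and leave NA metrics.
#'
#' @param model a `canalseg_model` or stub function (see [predictVolume()]).
#' @param cases list of [LabeledVolume-class] objects.
#' @param spec a [SlidingSpec-class].
#' @param ... passed to [predictVolume()].
#' @return data.frame with columns case, dsc, avd, asd, note.
#' @export
evaluateCases <- function(model, cases, spec, ...) {
  stopifnot(length(cases) > 0L)
  rows <- lapply(seq_along(cases), function(i) {
    v <- cases[[i]]
    pred <- predictVolume(model, v, spec, ...)
    out <- data.frame(case = as.character(i), dsc = NA_real_, avd = NA_real_,
                      asd = NA_real_, note = "", stringsAsFactors = FALSE)
    notes <- character(0)
    for (metric in c("dsc", "avd", "asd")) {
      val <- tryCatch(switch(metric,
        dsc = dsc(pred$mask, v@labels),
        avd = avd(pred$mask, v@labels, v@spacingMm),
        asd = asd(pred$mask, v@labels, v@spacingMm)), error = function(e) e)
      if (inherits(val, "error"))
        notes <- c(notes, sprintf("%s: %s", metric, conditionMessage(val)))
      else out[[metric]] <- val
    }
    out$note <- paste(notes, collapse = "; ")
    out
  })
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(case = "mean", dsc = mean(tab$dsc), avd = mean(tab$avd),
                         asd = mean(tab$asd), note = "", stringsAsFactors = FALSE)
  rbind(tab, mean_row)
}
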