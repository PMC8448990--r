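# Patch-based Dice-loss training with positive-patch sampling.
#
# Training crops are drawn uniformly among all patch origins whose window
# contains at least one foreground voxel (the canal occupies well under 1% of
# a volume, so unconstrained crops would be almost always empty). The valid
# origin set is computed exactly with a 3D summed-area table. Validation runs
# full sliding-window inference and tracks the best mean DSC checkpoint.

csum3 <- function(a) {
  a <- apply(a, c(2, 3), cumsum)
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
}

# Foreground voxel count of every patch placement; dims (D-p1+1, H-p2+1, W-p3+1).
window_fg_counts <- function(lab, patch) {
  d <- dim(lab)
  p <- as.integer(patch)
  if (any(p > d))
    stop(sprintf("patch %s larger than volume %s", paste(p, collapse = "x"),
                 paste(d, collapse = "x")))
  P <- array(0, d + 1L)
  P[-1L, -1L, -1L] <- csum3(lab != 0)
  i0 <- seq_len(d[1] - p[1] + 1L)
  j0 <- seq_len(d[2] - p[2] + 1L)
  k0 <- seq_len(d[3] - p[3] + 1L)
  A <- function(di, dj, dk) P[i0 + di, j0 + dj, k0 + dk, drop = FALSE]
  A(p[1], p[2], p[3]) - A(0L, p[2], p[3]) - A(p[1], 0L, p[3]) - A(p[1], p[2], 0L) +
    A(0L, 0L, p[3]) + A(0L, p[2], 0L) + A(p[1], 0L, 0L) - A(0L, 0L, 0L)
}

valid_origins <- function(lab, patch) {
  counts <- window_fg_counts(lab, patch)
  idx <- which(counts > 1e-9)
  if (length(idx) == 0L) stop("volume contains no foreground voxel")
  arrayInd(idx, dim(counts))
}

#' Sample a training patch guaranteed to contain foreground
#'
#' Draws a crop origin uniformly among all placements whose window contains
#' at least one labeled voxel, and returns the aligned intensity and label
#' patches.
#'
#' @param vol a [LabeledVolume-class] with at least one foreground voxel.
#' @param patchSize integer(3) patch shape (D, H, W), no larger than the
#'   volume.
#' @return List with `intensity` and `label` (3D arrays of shape `patchSize`)
#'   and `origin` (1-based crop origin).
#' @export
samplePositivePatch <- function(vol, patchSize) {
  ors <- valid_origins(vol@labels, patchSize)
  o <- ors[sample.int(nrow(ors), 1L), ]
  extract_patch(vol@intensities, vol@labels, o, as.integer(patchSize))
}

extract_patch <- function(x, lab, origin, p) {
  i <- origin[1]:(origin[1] + p[1] - 1L)
  j <- origin[2]:(origin[2] + p[2] - 1L)
  k <- origin[3]:(origin[3] + p[3] - 1L)
  list(intensity = x[i, j, k, drop = FALSE], label = lab[i, j, k, drop = FALSE],
       origin = origin)
}

normalize_volume <- function(x) {
  s <- stats::sd(x)
  (x - mean(x)) / if (s > 0) s else 1
}

## ---- optimizer -------------------------------------------------------------

optim_step <- function(params, cfg, t) {
  lr <- cfg@learningRate
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    g <- as.numeric(g) + cfg@weightDecay * as.numeric(p$value)
    if (cfg@optimizer == "adam") {
      p$m <- cfg@beta1 * p$m + (1 - cfg@beta1) * g
      p$v <- cfg@beta2 * p$v + (1 - cfg@beta2) * g * g
      mhat <- p$m / (1 - cfg@beta1^t)
      vhat <- p$v / (1 - cfg@beta2^t)
      upd <- mhat / (sqrt(vhat) + 1e-8)
    } else {
      p$m <- cfg@beta1 * p$m + g
      upd <- p$m
    }
    dim(upd) <- dim(p$value)  # keep matrices matrices, vectors vectors
    p$value <- p$value - lr * upd
  }
  invisible(NULL)
}

## ---- training loop ---------------------------------------------------------

#' Train a network on labeled volumes
#'
#' Optimizes the Dice loss over positively-sampled patches with Adam (or SGD
#' with momentum). Every `validationInterval` steps the model is evaluated by
#' sliding-window inference on the validation volumes and the state with the
#' best mean DSC is retained. The whole run is deterministic given the
#' configuration seed.
#'
#' @param netConfig a [NetworkConfig-class] (or an already-built
#'   `canalseg_model` to continue training).
#' @param trainConfig a [TrainingConfig-class].
#' @param trainSet nonempty list of [LabeledVolume-class] objects.
#' @param valSet list of validation volumes (may be empty).
#' @param sliding a [SlidingSpec-class] for validation inference; defaults to
#'   the training patch size with half-patch steps.
#' @param verbose print per-validation progress.
#' @return A `canalseg_fit` list: `model` (final), `bestState` (weights of the
#'   best validation checkpoint; final weights when no validation ran),
#'   `history` (data frame of per-step losses), `validations` (data frame of
#'   step and mean DSC), `bestStep`, `bestValDsc`.
#' @export
trainNetwork <- function(netConfig, trainConfig, trainSet, valSet = list(),
                         sliding = NULL, verbose = FALSE) {
  validObject(trainConfig)
  if (length(trainSet) == 0L) stop("empty training set")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(trainConfig@seed)
  model <- if (inherits(netConfig, "canalseg_model")) netConfig
           else buildNetwork(netConfig)
  p <- trainConfig@patchSize
  div <- pool_kernel(model$config)^model$config@nPool
  if (any(p %% div != 0L))
    stop(sprintf("patch dims %s must be divisible by %s for %d pooling stages",
                 paste(p, collapse = "x"), paste(div, collapse = "x"),
                 model$config@nPool))
  if (is.null(sliding))
    sliding <- slidingSpec(patchSize = p, steps = pmax(1L, p %/% 2L))
  prep <- lapply(trainSet, function(v)
    list(x = normalize_volume(v@intensities), lab = v@labels,
         origins = valid_origins(v@labels, p)))
  losses <- numeric(trainConfig@maxSteps)
  val_steps <- integer(0); val_dsc <- numeric(0)
  best_dsc <- -Inf; best_state <- NULL; best_step <- NA_integer_
  B <- trainConfig@batchSize
  make_batch <- function() {
    xb <- array(0, c(1L, p, B))
    gb <- array(0, c(1L, p, B))
    for (b in seq_len(B)) {
      vi <- sample.int(length(prep), 1L)
      pr <- prep[[vi]]
      o <- pr$origins[sample.int(nrow(pr$origins), 1L), ]
      pt <- extract_patch(pr$x, pr$lab, o, p)
      xb[1L, , , , b] <- pt$intensity
      gb[1L, , , , b] <- pt$label
    }
    list(x = xb, g = gb)
  }
  # Evaluation-mode forwards need batch-norm statistics that match the
  # current weights; a short frozen-weight sweep over fresh batches resets
  # them (fast optimization leaves running averages stale).
  calibrate <- function()
    calibrateBatchNorm(model, lapply(seq_len(2L), function(i) make_batch()$x))
  for (step in seq_len(trainConfig@maxSteps)) {
    bt <- make_batch()
    xb <- bt$x
    gb <- bt$g
    tape <- new_tape()
    zero_grads(model$params)
    logits <- network_forward(model, tape, tp_leaf(xb), training = TRUE)
    loss <- op_dice_loss(tape, logits, gb, trainConfig@smooth)
    lv <- as.numeric(loss$value)
    if (!is.finite(lv))
      stop(sprintf("training diverged: loss %s at step %d", format(lv), step))
    losses[step] <- lv
    tp_backward(tape, loss)
    optim_step(model$params, trainConfig, step)
    if (trainConfig@validationInterval > 0L && length(valSet) > 0L &&
        step %% trainConfig@validationInterval == 0L) {
      calibrate()
      md <- mean(vapply(valSet, function(v) {
        pred <- predictVolume(model, v, sliding)
        if (sum(pred$mask) + sum(v@labels) == 0) 1 else dsc(pred$mask, v@labels)
      }, numeric(1)))
      val_steps <- c(val_steps, step); val_dsc <- c(val_dsc, md)
      if (md > best_dsc) {
        best_dsc <- md; best_state <- modelState(model); best_step <- step
      }
      if (verbose)
        message(sprintf("step %d: loss %.4f, val DSC %.4f", step, lv, md))
    }
  }
  if (trainConfig@maxSteps > 0L) calibrate()
  if (is.null(best_state)) best_state <- modelState(model)
  fit <- list(model = model, bestState = best_state,
              history = data.frame(step = seq_len(trainConfig@maxSteps),
                                   loss = losses),
              validations = data.frame(step = val_steps, mean_dsc = val_dsc),
              bestStep = best_step,
              bestValDsc = if (is.finite(best_dsc)) best_dsc else NA_real_,
              netConfig = model$config, trainConfig = trainConfig)
  class(fit) <- "canalseg_fit"
  fit
}

#' Model carrying the best validation weights of a fit
#'
#' @param fit a `canalseg_fit` from [trainNetwork()].
#' @return A `canalseg_model` with the best-validation (or final) weights.
#' @export
bestModel <- function(fit) {
  m <- buildNetwork(fit$netConfig, seed = 0L)
  setModelState(m, fit$bestState)
}

#' @export
print.canalseg_fit <- function(x, ...) {
  cat(sprintf("canalseg fit: %d step(s), final loss %.4f%s\n",
              nrow(x$history),
              if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA,
              if (!is.na(x$bestStep))
                sprintf(", best val DSC %.4f @ step %d", x$bestValDsc, x$bestStep)
              else ""))
  invisible(x)
}

## ---- ablation harness ------------------------------------------------------

#' Train and compare architecture variants
#'
#' Trains each variant with identical seeds and data, evaluates on the test
#' split by sliding-window inference, and reports one row per variant with
#' mean DSC, AVD and ASD (the ablation-table layout). A variant whose
#' training fails is reported with NA metrics and an error note; the others
#' continue.
#'
#' @param variants character vector of variant names (see [networkVariants()]).
#' @param netConfig base [NetworkConfig-class]; its `variant` is overridden.
#' @param trainConfig a [TrainingConfig-class] shared by all variants.
#' @param dataset a list with `train`, `val`, `test` as from
#'   [generateDataset()].
#' @param sliding optional [SlidingSpec-class] for evaluation.
#' @return data.frame with columns variant, dsc, avd, asd, note.
#' @export
runAblation <- function(variants, netConfig, trainConfig, dataset,
                        sliding = NULL) {
  if (length(variants) == 0L) stop("need at least one variant")
  rows <- lapply(variants, function(v) {
    tryCatch({
      cfg <- netConfig
      cfg@variant <- v
      validObject(cfg)
      fit <- trainNetwork(cfg, trainConfig, dataset$train, dataset$val, sliding)
      rep <- evaluateCases(bestModel(fit), dataset$test,
                           sliding %||% slidingSpec(
                             patchSize = trainConfig@patchSize,
                             steps = pmax(1L, trainConfig@patchSize %/% 2L)))
      m <- rep[rep$case == "mean", ]
      data.frame(variant = v, dsc = m$dsc, avd = m$avd, asd = m$asd,
                 note = "", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(variant = v, dsc = NA_real_, avd = NA_real_, asd = NA_real_,
                 note = conditionMessage(e), stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
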