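# The attention-augmented 3D U-Net.
#
# Encoder: n_pool + 1 levels of two 3x3x3 conv + BN + ReLU blocks separated by
# max pooling. Attention variants gate each encoder level with a 3D spatial
# squeeze-and-excitation (sSE) module and/or fuse decoder stages with 3D
# global-attention-upsample (GAU) modules in place of skip connections. The
# baseline variant is the classic transposed-conv + concatenation 3D U-Net.
# The head is a 1x1x1 convolution to single-channel logits at full resolution.

make_conv_block <- function(cin, cout, name) {
  list(conv1 = layer_conv3d(cin, cout, name = paste0(name, ".conv1")),
       bn1 = layer_bn3d(cout, name = paste0(name, ".bn1")),
       conv2 = layer_conv3d(cout, cout, name = paste0(name, ".conv2")),
       bn2 = layer_bn3d(cout, name = paste0(name, ".bn2")))
}

conv_block_fwd <- function(blk, tape, x, training) {
  h <- op_relu(tape, blk$bn1$fwd(tape, blk$conv1$fwd(tape, x, training), training))
  op_relu(tape, blk$bn2$fwd(tape, blk$conv2$fwd(tape, h, training), training))
}

#' Spatial squeeze-and-excitation module (3D)
#'
#' Squeezes the channels of a feature map to a single-channel projection with
#' a 3x3x3 convolution, passes it through a sigmoid to get a spatial gate in
#' (0, 1), and rescales every channel of the input by that gate. The gate can
#' never increase an activation's magnitude.
#'
#' @param channels input channel count.
#' @return A module for use with [sseForward()]; its squeeze convolution is
#'   accessible as `$conv` (weights `$conv$W$value`, bias `$conv$b$value`).
#' @export
sseModule <- function(channels) {
  m <- list(conv = layer_conv3d(channels, 1L, name = "sse.conv"))
  m$params <- m$conv$params
  class(m) <- "canalseg_sse"
  m
}

sse_fwd <- function(m, tape, x, training) {
  u1 <- m$conv$fwd(tape, x, training)
  op_spatial_mul(tape, x, op_sigmoid(tape, u1))
}

#' Run a spatial-SE module on an array
#'
#' @param module an [sseModule()].
#' @param x a (C, D, H, W) or (C, D, H, W, N) array.
#' @return The gated feature map, same shape as `x`.
#' @export
sseForward <- function(module, x) {
  xt <- tp_leaf(as_input5(x))
  y <- sse_fwd(module, NULL, xt, training = FALSE)$value
  if (length(dim(x)) == 4L) dim(y) <- dim(x)
  y
}

#' Global-attention-upsample module (3D)
#'
#' Decoder fusion stage: the low-level map is transformed by a 1x1x1
#' convolution + BN + ReLU, then gated channel-wise by attention weights
#' derived from the globally average-pooled high-level map (1x1x1 conv + BN +
#' ReLU to the low-level channel count). The high-level map is upsampled by a
#' transposed convolution + BN to the low-level grid, and the two paths are
#' summed.
#'
#' @param cLow,cHigh channel counts of the low- and high-level inputs.
#' @param upsampleMode `"isotropic"` (kernel 4, stride 2, all axes) or
#'   `"inplane"` (kernel 1x4x4, stride 1x2x2: in-plane only).
#' @return A module for use with [gauForward()]; submodules are accessible as
#'   `$low_conv`, `$gate_conv`, `$up` (the transposed convolution), and their
#'   batch norms.
#' @export
gauModule <- function(cLow, cHigh, upsampleMode = "isotropic") {
  up <- if (upsampleMode == "inplane") {
    layer_tconv3d(cHigh, cLow, kernel = c(1L, 4L, 4L), stride = c(1L, 2L, 2L),
                  pad = c(0L, 1L, 1L), name = "gau.up")
  } else {
    layer_tconv3d(cHigh, cLow, kernel = c(4L, 4L, 4L), stride = c(2L, 2L, 2L),
                  pad = c(1L, 1L, 1L), name = "gau.up")
  }
  m <- list(
    low_conv = layer_conv3d(cLow, cLow, kernel = c(1L, 1L, 1L), name = "gau.low"),
    low_bn = layer_bn3d(cLow, name = "gau.low_bn"),
    gate_conv = layer_conv3d(cHigh, cLow, kernel = c(1L, 1L, 1L), name = "gau.gate"),
    gate_bn = layer_bn3d(cLow, name = "gau.gate_bn"),
    up = up, up_bn = layer_bn3d(cLow, name = "gau.up_bn"),
    upsampleMode = upsampleMode)
  m$params <- c(m$low_conv$params, m$low_bn$params, m$gate_conv$params,
                m$gate_bn$params, m$up$params, m$up_bn$params)
  class(m) <- "canalseg_gau"
  m
}

gau_fwd <- function(m, tape, low, high, training, gate = c("learned", "open", "closed")) {
  gate <- match.arg(gate)
  f3a <- op_relu(tape, m$low_bn$fwd(tape, m$low_conv$fwd(tape, low, training), training))
  f3 <- switch(gate,
    learned = {
      pooled <- op_gap(tape, high)
      w1 <- op_relu(tape, m$gate_bn$fwd(tape, m$gate_conv$fwd(tape, pooled, training), training))
      op_channel_mul(tape, f3a, w1)
    },
    open = f3a,
    closed = op_const(array(0, dim(f3a$value))))
  f4 <- m$up_bn$fwd(tape, m$up$fwd(tape, high, training), training)
  if (!identical(dim(f3$value), dim(f4$value)))
    stop(sprintf("GAU shape mismatch: low path %s vs upsampled high path %s",
                 paste(dim(f3$value), collapse = "x"),
                 paste(dim(f4$value), collapse = "x")))
  op_add(tape, f3, f4)
}

#' Run a global-attention-upsample module on arrays
#'
#' @param module a [gauModule()].
#' @param low,high the low-level and high-level feature maps, (C, D, H, W)
#'   or batched (C, D, H, W, N) arrays.
#' @param gate `"learned"` uses the pooled high-level attention weights;
#'   `"open"` forces an all-ones gate; `"closed"` an all-zeros gate.
#' @return The fused map with the low-level shape.
#' @export
gauForward <- function(module, low, high, gate = "learned") {
  lt <- tp_leaf(as_input5(low)); ht <- tp_leaf(as_input5(high))
  y <- gau_fwd(module, NULL, lt, ht, training = FALSE, gate = gate)$value
  if (length(dim(low)) == 4L) dim(y) <- dim(low)
  y
}

#' Combined attention stage (sSE + GAU arrangements)
#'
#' Builds one decoder fusion stage owning both an sSE and a GAU submodule,
#' wired per arrangement: `sequential_spatial_first` applies the spatial gate
#' to the low-level features before the GAU fusion; `sequential_channel_first`
#' applies it to the GAU output; `parallel` sums the gated low-level features
#' with the GAU output. All three own identical submodules (identical
#' parameter counts), differing only in wiring.
#'
#' @param cLow,cHigh channel counts; @param mode arrangement; @param upsampleMode see [gauModule()].
#' @return A stage for [combineAttention()]; submodules at `$sse` and `$gau`.
#' @export
attentionStage <- function(cLow, cHigh,
                           mode = c("sequential_spatial_first",
                                    "sequential_channel_first", "parallel"),
                           upsampleMode = "isotropic") {
  mode <- match.arg(mode)
  m <- list(sse = sseModule(cLow), gau = gauModule(cLow, cHigh, upsampleMode),
            mode = mode)
  m$params <- c(m$sse$params, m$gau$params)
  class(m) <- "canalseg_stage"
  m
}

stage_fwd <- function(m, tape, low, high, training, gauGate = "learned") {
  switch(m$mode,
    sequential_spatial_first =
      gau_fwd(m$gau, tape, sse_fwd(m$sse, tape, low, training), high, training, gauGate),
    sequential_channel_first =
      sse_fwd(m$sse, tape, gau_fwd(m$gau, tape, low, high, training, gauGate), training),
    parallel =
      op_add(tape, sse_fwd(m$sse, tape, low, training),
             gau_fwd(m$gau, tape, low, high, training, gauGate)),
    stop(sprintf("unknown attention arrangement '%s'; valid modes: %s", m$mode,
                 "sequential_spatial_first, sequential_channel_first, parallel")))
}

#' Run a combined attention stage on arrays
#'
#' @param stage an [attentionStage()].
#' @param low,high feature maps as in [gauForward()].
#' @param gauGate passed to the GAU submodule (`"learned"`, `"open"`, `"closed"`).
#' @return The fused map with the low-level shape.
#' @export
combineAttention <- function(stage, low, high, gauGate = "learned") {
  lt <- tp_leaf(as_input5(low)); ht <- tp_leaf(as_input5(high))
  y <- stage_fwd(stage, NULL, lt, ht, training = FALSE, gauGate = gauGate)$value
  if (length(dim(low)) == 4L) dim(y) <- dim(low)
  y
}

## ---- whole network ---------------------------------------------------------

has_sse <- function(variant) variant %in% c("sse_only", "sequential_spatial_first",
                                            "sequential_channel_first", "parallel")
has_gau <- function(variant) variant %in% c("gau_only", "sequential_spatial_first",
                                            "sequential_channel_first", "parallel")

pool_kernel <- function(config)
  if (config@gauUpsampleMode == "inplane") c(1L, 2L, 2L) else c(2L, 2L, 2L)

#' Build an attention-augmented 3D U-Net
#'
#' Assembles the encoder, the variant-specific decoder wiring, and the 1x1x1
#' logits head described by a [networkConfig()]. Convolution weights use
#' Kaiming fan-in initialization; batch norms start at identity.
#'
#' @param config a [NetworkConfig-class].
#' @param seed optional integer; when given, initialization is deterministic.
#' @return An object of class `canalseg_model`.
#' @examples
#' net <- buildNetwork(networkConfig(encoderChannels = c(4, 8, 16, 32)), seed = 1)
#' logits <- predictLogits(net, array(rnorm(1 * 16 * 16 * 16), c(1, 16, 16, 16)))
#' dim(logits)
#' @export
buildNetwork <- function(config, seed = NULL) {
  validObject(config)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  ch <- config@encoderChannels
  np <- config@nPool
  v <- config@variant
  enc <- vector("list", np + 1L)
  cin <- 1L
  for (i in seq_len(np + 1L)) {
    enc[[i]] <- make_conv_block(cin, ch[i], paste0("enc", i))
    cin <- ch[i]
  }
  # sse_only gates every encoder level directly; the combined arrangements own
  # their per-level gates inside the attention stages, so only the bottleneck
  # (which no stage covers) is gated here.
  sse <- vector("list", np + 1L)
  if (v == "sse_only") {
    for (i in seq_len(np + 1L)) sse[[i]] <- sseModule(ch[i])
  } else if (has_sse(v) && config@sseBottleneck) {
    sse[[np + 1L]] <- sseModule(ch[np + 1L])
  }
  dec <- vector("list", np)
  if (has_gau(v)) {
    for (l in rev(seq_len(np))) {
      dec[[l]] <- if (v == "gau_only")
        gauModule(ch[l], ch[l + 1L], config@gauUpsampleMode)
      else
        attentionStage(ch[l], ch[l + 1L], mode = v,
                       upsampleMode = config@gauUpsampleMode)
    }
  } else {
    pk <- pool_kernel(config)
    tk <- ifelse(pk == 2L, 2L, 1L)
    for (l in rev(seq_len(np))) {
      dec[[l]] <- list(
        up = layer_tconv3d(ch[l + 1L], ch[l], kernel = tk, stride = tk,
                           pad = c(0L, 0L, 0L), name = paste0("dec", l, ".up")),
        blk = make_conv_block(2L * ch[l], ch[l], paste0("dec", l)))
    }
  }
  head <- layer_conv3d(ch[1L], 1L, kernel = c(1L, 1L, 1L), name = "head")
  # Foreground occupies well under 1% of a volume; starting the head bias at
  # the background log-odds keeps early Dice gradients from being swamped by
  # the background sum.
  head$b$value[] <- stats::qlogis(0.01)
  model <- list(config = config, enc = enc, sse = sse, dec = dec, head = head)
  model$params <- collect_params(model)
  class(model) <- "canalseg_model"
  model
}

collect_params <- function(x) {
  out <- list()
  walk <- function(o) {
    if (is.environment(o)) {
      if (!is.null(o$params)) out <<- c(out, o$params)
    } else if (inherits(o, c("canalseg_sse", "canalseg_gau", "canalseg_stage"))) {
      for (f in o[!names(o) %in% c("params", "mode", "upsampleMode")]) walk(f)
    } else if (is.list(o)) {
      for (f in o) walk(f)
    }
  }
  walk(list(x$enc, x$sse, x$dec, x$head))
  out
}

check_input_dims <- function(config, sp) {
  pk <- pool_kernel(config)
  div <- pk^config@nPool
  if (any(sp %% div != 0L))
    stop(sprintf("input spatial dims %s must be divisible by %s (%d pooling stages)",
                 paste(sp, collapse = "x"), paste(div, collapse = "x"), config@nPool))
}

# Full forward pass; returns the logits tensor (1, D, H, W, N).
network_forward <- function(model, tape, x, training = FALSE) {
  cfg <- model$config
  v <- cfg@variant
  np <- cfg@nPool
  check_input_dims(cfg, dim(x$value)[2:4])
  pk <- pool_kernel(cfg)
  feats <- vector("list", np + 1L)
  h <- x
  for (i in seq_len(np + 1L)) {
    if (i > 1L) h <- op_maxpool(tape, h, kernel = pk)
    h <- conv_block_fwd(model$enc[[i]], tape, h, training)
    if (!is.null(model$sse[[i]]))
      h <- sse_fwd(model$sse[[i]], tape, h, training)
    feats[[i]] <- h
  }
  high <- feats[[np + 1L]]
  if (has_gau(v)) {
    for (l in rev(seq_len(np))) {
      st <- model$dec[[l]]
      high <- if (v == "gau_only") gau_fwd(st, tape, feats[[l]], high, training)
              else stage_fwd(st, tape, feats[[l]], high, training)
    }
  } else {
    for (l in rev(seq_len(np))) {
      st <- model$dec[[l]]
      up <- st$up$fwd(tape, high, training)
      high <- conv_block_fwd(st$blk, tape, op_concat_channels(tape, feats[[l]], up), training)
    }
  }
  model$head$fwd(tape, high, training)
}

#' Forward pass returning logits
#'
#' Evaluation-mode forward pass (batch norm uses running statistics).
#'
#' @param model a `canalseg_model` from [buildNetwork()].
#' @param x input array, (1, D, H, W) or (1, D, H, W, N); spatial dims must be
#'   divisible by the total pooling factor.
#' @return Logits with the same spatial shape as the input.
#' @export
predictLogits <- function(model, x) {
  xin <- as_input5(x)
  y <- network_forward(model, NULL, tp_leaf(xin), training = FALSE)$value
  if (length(dim(x)) == 4L) dim(y) <- dim(x)
  y
}

#' Count learnable parameters
#'
#' @param model a `canalseg_model` (or any module with a `$params` list).
#' @return Total number of learnable scalar parameters.
#' @export
countParameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' @export
print.canalseg_model <- function(x, ...) {
  cat(sprintf("canalseg attention 3D U-Net ('%s'): channels %s, %d pooling stage(s), %s parameters\n",
              x$config@variant, paste(x$config@encoderChannels, collapse = "-"),
              x$config@nPool, format(countParameters(x), big.mark = ",")))
  invisible(x)
}

## ---- model state / checkpoints --------------------------------------------

bn_layers <- function(model) {
  out <- list()
  walk <- function(o) {
    if (is.environment(o)) {
      if (!is.null(o$running_mean)) out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) for (f in o) walk(f)
  }
  walk(list(model$enc, model$sse, model$dec, model$head))
  out
}

#' Extract / restore the numeric state of a model
#'
#' `modelState()` returns all learnable parameters plus batch-norm running
#' statistics; `setModelState()` writes such a state back into a model built
#' from the same configuration.
#'
#' @param model a `canalseg_model`.
#' @return For `modelState()`, a list with `params` and `bn_stats`.
#' @export
modelState <- function(model) {
  list(params = lapply(model$params, function(p) p$value),
       bn_stats = lapply(bn_layers(model), function(b)
         list(mean = b$running_mean, var = b$running_var)))
}

#' @rdname modelState
#' @param state a state list from [modelState()].
#' @export
setModelState <- function(model, state) {
  stopifnot(length(state$params) == length(model$params))
  for (i in seq_along(state$params)) model$params[[i]]$value <- state$params[[i]]
  bns <- bn_layers(model)
  stopifnot(length(state$bn_stats) == length(bns))
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- state$bn_stats[[i]]$mean
    bns[[i]]$running_var <- state$bn_stats[[i]]$var
  }
  invisible(model)
}

#' Recalibrate batch-norm running statistics
#'
#' Replaces every batch-norm layer's running mean/variance with the average of
#' the batch statistics observed over `batches`, under frozen weights. Useful
#' after fast optimization, where running averages lag the weights and degrade
#' evaluation-mode forward passes.
#'
#' @param model a `canalseg_model`.
#' @param batches list of input arrays `(1, D, H, W, N)`.
#' @return The model, invisibly (batch-norm state updated in place).
#' @export
calibrateBatchNorm <- function(model, batches) {
  bns <- bn_layers(model)
  saved <- vapply(bns, function(b) b$momentum, numeric(1))
  for (i in seq_along(batches)) {
    for (b in bns) b$momentum <- 1 / i  # cumulative average of batch stats
    network_forward(model, NULL, tp_leaf(as_input5(batches[[i]])), training = TRUE)
  }
  for (i in seq_along(bns)) bns[[i]]$momentum <- saved[i]
  invisible(model)
}

config_to_list <- function(config) {
  list(encoderChannels = config@encoderChannels, nPool = config@nPool,
       variant = config@variant, gauUpsampleMode = config@gauUpsampleMode,
       sseBottleneck = config@sseBottleneck)
}

config_from_list <- function(x) {
  networkConfig(encoderChannels = unlist(x$encoderChannels), nPool = x$nPool,
                variant = x$variant, gauUpsampleMode = x$gauUpsampleMode,
                sseBottleneck = x$sseBottleneck)
}

#' Save / load a self-describing model checkpoint
#'
#' The checkpoint stores the full network configuration alongside the weights,
#' so `loadCheckpoint()` can rebuild the model without further information.
#'
#' @param model a `canalseg_model`; @param path file path (.rds).
#' @return `loadCheckpoint()` returns the restored `canalseg_model`.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(config = config_to_list(model$config), state = modelState(model),
               package_version = as.character(utils::packageVersion("canalseg"))),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- buildNetwork(config_from_list(ck$config), seed = 0L)
  setModelState(model, ck$state)
}

## ---- RNG helpers -----------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  code
}
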