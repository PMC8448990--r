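# Architecture contracts: shapes, attention-gate behavior, variant wiring,
# parameter accounting, and checkpointing.

ns <- asNamespace("canalseg")

test_that("every variant preserves full resolution and is deterministic in eval mode", {
  set.seed(41)
  xin <- array(rnorm(1 * 16 * 16 * 24), c(1, 16, 16, 24))
  for (v in networkVariants()) {
    net <- buildNetwork(tiny_net_config(v), seed = 42)
    lg <- predictLogits(net, xin)
    expect_equal(dim(lg), dim(xin), label = v)
    expect_identical(lg, predictLogits(net, xin), label = v)
  }
})

test_that("indivisible input dims raise a configuration error", {
  net <- buildNetwork(tiny_net_config(), seed = 1)
  bad <- array(0, c(1, 15, 16, 16))  # 15 not divisible by 2^2
  expect_error(predictLogits(net, bad), "divisible")
})

test_that("spatial SE gates stay in (0,1) and never amplify activations", {
  set.seed(43)
  m <- sseModule(4L)
  x <- array(rnorm(4 * 6 * 6 * 6), c(4, 6, 6, 6))
  y <- sseForward(m, x)
  expect_true(all(abs(y) <= abs(x)))
  expect_true(all(y * x >= 0))  # gate is positive: no sign flips
})

test_that("saturated spatial SE gates reproduce or annihilate the input", {
  set.seed(44)
  m <- sseModule(3L)
  x <- array(rnorm(3 * 5 * 5 * 5), c(3, 5, 5, 5))
  m$conv$W$value[] <- 0
  m$conv$b$value[] <- 20     # sigmoid(20) ~ 1
  expect_lt(max(abs(sseForward(m, x) - x)), 1e-6)
  m$conv$b$value[] <- -20    # sigmoid(-20) ~ 0
  expect_lt(max(abs(sseForward(m, x))), 1e-6)
})

test_that("GAU reduces to its low path with zeroed upsampling and an open gate", {
  set.seed(45)
  m <- gauModule(3L, 5L)
  low <- array(rnorm(3 * 8 * 8 * 8), c(3, 8, 8, 8))
  high <- array(rnorm(5 * 4 * 4 * 4), c(5, 4, 4, 4))
  m$up$W$value[] <- 0
  m$up$b$value[] <- 0
  # the low path alone: 1x1x1 conv + BN + ReLU of the low-level features
  f3 <- ns$op_relu(NULL, m$low_bn$fwd(NULL, m$low_conv$fwd(
    NULL, ns$tp_leaf(array(low, c(dim(low), 1)))), FALSE))$value
  open <- gauForward(m, low, high, gate = "open")
  expect_identical(open, array(f3, dim(low)))
  closed <- gauForward(m, low, high, gate = "closed")
  expect_identical(closed, array(0, dim(low)))  # F5 = F4 = 0 here
})

test_that("GAU output takes the low-level shape and mismatches are reported", {
  m <- gauModule(4L, 6L)
  low <- array(0, c(4, 8, 12, 16))
  high <- array(0, c(6, 4, 6, 8))
  expect_equal(dim(gauForward(m, low, high)), dim(low))
  expect_error(gauForward(m, low, array(0, c(6, 4, 4, 4))), "shape mismatch")
})

test_that("attention arrangements share shapes and reduce to GAU under open sSE gates", {
  set.seed(46)
  low <- array(rnorm(3 * 8 * 8 * 8), c(3, 8, 8, 8))
  high <- array(rnorm(5 * 4 * 4 * 4), c(5, 4, 4, 4))
  outs <- lapply(c("sequential_spatial_first", "sequential_channel_first",
                   "parallel"), function(mode) {
    st <- attentionStage(3L, 5L, mode = mode)
    y <- combineAttention(st, low, high)
    expect_equal(dim(y), dim(low), label = mode)
    st
  })
  for (st in outs[1:2]) {   # the two sequential arrangements
    st$sse$conv$W$value[] <- 0
    st$sse$conv$b$value[] <- 20
    got <- combineAttention(st, low, high)
    want <- gauForward(st$gau, low, high)
    expect_lt(max(abs(got - want)), 1e-5)
  }
  expect_error(ns$stage_fwd(list(mode = "bogus"), NULL, 1, 2, FALSE),
               "valid modes")
})

test_that("parameter counts order as expected across variants", {
  counts <- vapply(networkVariants(), function(v)
    countParameters(buildNetwork(tiny_net_config(v), seed = 2)), numeric(1))
  # the three combined arrangements own identical submodules
  expect_equal(counts[["sequential_spatial_first"]],
               counts[["sequential_channel_first"]])
  expect_equal(counts[["sequential_spatial_first"]], counts[["parallel"]])
  # sSE costs exactly one C-to-1 3x3x3 conv (27C weights + 1 bias) per level
  ch <- tiny_net_config()@encoderChannels
  sse_cost <- sum(27 * ch + 1)
  expect_equal(counts[["sequential_spatial_first"]] - counts[["gau_only"]],
               sse_cost)
  expect_equal(counts[["sse_only"]] - counts[["baseline_3dunet"]], sse_cost)
  expect_lt(counts[["gau_only"]], counts[["parallel"]])
})

test_that("gradients reach the first encoder convolution in every variant", {
  set.seed(47)
  xin <- array(rnorm(1 * 8 * 8 * 8), c(1, 8, 8, 8, 1))
  g <- array(rbinom(length(xin), 1, 0.2), dim(xin))
  for (v in networkVariants()) {
    net <- buildNetwork(tiny_net_config(v), seed = 48)
    tape <- ns$new_tape()
    l <- ns$op_dice_loss(tape, ns$network_forward(net, tape, ns$tp_leaf(xin),
                                                  training = TRUE), g, 1e-5)
    ns$zero_grads(net$params)
    ns$tp_backward(tape, l)
    g1 <- net$enc[[1]]$conv1$W$grad
    expect_false(is.null(g1), label = v)
    expect_gt(sum(abs(g1)), 0, label = v)
  }
})

test_that("checkpoints are self-describing and restore the exact forward map", {
  set.seed(49)
  net <- buildNetwork(tiny_net_config("parallel"), seed = 50)
  xin <- array(rnorm(1 * 8 * 8 * 8), c(1, 8, 8, 8))
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f)
  net2 <- loadCheckpoint(f)
  expect_identical(predictLogits(net2, xin), predictLogits(net, xin))
  expect_identical(net2$config@variant, "parallel")
})

test_that("in-plane upsampling leaves the depth axis untouched", {
  cfg <- networkConfig(encoderChannels = c(2L, 3L, 4L), nPool = 2L,
                       gauUpsampleMode = "inplane")
  net <- buildNetwork(cfg, seed = 51)
  xin <- array(rnorm(1 * 5 * 8 * 8), c(1, 5, 8, 8))  # depth 5 not pooled
  expect_equal(dim(predictLogits(net, xin)), dim(xin))
})
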