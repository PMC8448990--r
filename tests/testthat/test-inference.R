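# Sliding-window inference: start enumeration, coverage accounting,
# averaging semantics, and case-level evaluation.

ns <- asNamespace("canalseg")

test_that("window start enumeration covers the axis with a final clamped start", {
  s <- windowStarts(512, 64, 28)
  expect_length(s, 17)
  expect_equal(s[17], 448)              # 448 + 64 = 512, no clamp needed
  expect_equal(windowStarts(64, 32, 8), c(0L, 8L, 16L, 24L, 32L))
  expect_equal(windowStarts(32, 32, 8), 0L)
  s2 <- windowStarts(50, 16, 12)        # clamped final start
  expect_equal(s2, c(0L, 12L, 24L, 34L))
  expect_equal(s2[length(s2)] + 16, 50)
  expect_error(windowStarts(10, 16, 4), "larger than extent")
  expect_error(windowStarts(64, 32, 0), "step")
  expect_error(windowStarts(64, 32, 40), "step")
})

test_that("a constant-logit stub yields a bit-constant probability map and full coverage", {
  vol <- array(rnorm(24 * 40 * 40), c(24, 40, 40))
  sp <- slidingSpec(patchSize = c(16L, 16L, 16L), steps = c(8L, 12L, 12L))
  stub <- function(xb) array(1.5, dim(xb))
  pred <- predictVolume(stub, vol, sp)
  expect_equal(length(unique(as.vector(pred$prob))), 1)
  expect_equal(pred$prob[1, 1, 1], 1 / (1 + exp(-1.5)))
  expect_true(all(pred$mask))           # sigmoid(1.5) > 0.5
  expect_gte(min(pred$counts), 1)
  # closed-gate stub below threshold gives the empty mask
  stub0 <- function(xb) array(-1, dim(xb))
  expect_false(any(predictVolume(stub0, vol, sp)$mask))
})

test_that("the count matrix matches a brute-force window-coverage oracle", {
  d <- c(20L, 25L, 30L)
  sp <- slidingSpec(patchSize = c(8L, 8L, 8L), steps = c(4L, 6L, 7L))
  pred <- predictVolume(function(xb) array(0, dim(xb)), array(0, d), sp)
  counts <- array(0L, d)
  for (a in windowStarts(d[1], 8, 4)) for (b in windowStarts(d[2], 8, 6))
    for (c in windowStarts(d[3], 8, 7)) {
      counts[a + 1:8, b + 1:8, c + 1:8] <- counts[a + 1:8, b + 1:8, c + 1:8] + 1L
    }
  expect_identical(pred$counts, counts)
  expect_gte(min(counts), 1)
  expect_true(any(counts > 1))
})

test_that("overlap averaging is independent of window evaluation order", {
  set.seed(81)
  d <- c(16L, 20L, 20L)
  x <- array(rnorm(prod(d)), d)
  sp <- slidingSpec(patchSize = c(8L, 8L, 8L), steps = c(4L, 5L, 5L))
  # deterministic position-dependent stub: logit = patch content
  stub <- function(xb) xb
  pred <- predictVolume(stub, x, sp, normalize = FALSE)
  # oracle accumulation with the window order reversed
  grid <- expand.grid(a = windowStarts(d[1], 8, 4), b = windowStarts(d[2], 8, 5),
                      c = windowStarts(d[3], 8, 5))
  acc <- array(0, d); cnt <- array(0, d)
  for (r in rev(seq_len(nrow(grid)))) {
    o <- as.integer(grid[r, ])
    i <- o[1] + 1:8; j <- o[2] + 1:8; k <- o[3] + 1:8
    acc[i, j, k] <- acc[i, j, k] + x[i, j, k]
    cnt[i, j, k] <- cnt[i, j, k] + 1
  }
  expect_equal(pred$prob, 1 / (1 + exp(-acc / cnt)), tolerance = 1e-6)
})

test_that("raising the threshold never adds voxels to the mask", {
  set.seed(82)
  vol <- generatePhantom(smallPhantomSpec(seed = 83))
  net <- buildNetwork(tiny_net_config(), seed = 84)
  lo <- predictVolume(net, vol, slidingSpec(patchSize = c(16L, 32L, 32L),
                                            steps = c(16L, 32L, 32L),
                                            threshold = 0.3))
  hi_mask <- lo$prob > 0.7
  expect_true(all(which(hi_mask) %in% which(lo$mask)))
})

test_that("probability-averaging mode applies the sigmoid before pooling", {
  d <- c(8L, 8L, 8L)
  x <- array(0, d)
  sp <- slidingSpec(patchSize = c(8L, 8L, 8L), steps = c(8L, 8L, 8L))
  stub <- function(xb) array(3, dim(xb))
  pl <- predictVolume(stub, x, sp, average = "logits")
  pp <- predictVolume(stub, x, sp, average = "probabilities")
  expect_equal(pl$prob, pp$prob)  # single window: both orders agree
})

test_that("case evaluation reports per-case rows plus an exact mean row", {
  set.seed(85)
  cases <- lapply(1:3, function(i) {
    lab <- array(0, c(16, 16, 16))
    lab[4:6 + i, 4:6, 4:6] <- 1
    labeledVolume(lab, lab)  # intensities equal the labels
  })
  # logit +/-20 according to the (unnormalized) intensity: prediction == truth
  stub <- function(xb) 40 * (xb - 0.5)
  sp <- slidingSpec(patchSize = c(16L, 16L, 16L), steps = c(8L, 8L, 8L))
  rep <- evaluateCases(stub, cases, sp, normalize = FALSE)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$case, c("1", "2", "3", "mean"))
  expect_equal(rep$dsc, rep(1, 4))
  expect_equal(rep$avd, rep(0, 4))
  expect_equal(rep$asd, rep(0, 4))
  # an empty prediction is surfaced per case, not silently averaged
  rep2 <- evaluateCases(function(xb) array(-20, dim(xb)), cases[1], sp,
                        normalize = FALSE)
  expect_match(rep2$note[1], "empty")
  expect_equal(rep2$dsc[1], 0)       # DSC is defined (0) for an empty prediction
  expect_true(is.na(rep2$avd[1]))    # the distance metrics are not
  expect_true(is.na(rep2$asd[1]))
})
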