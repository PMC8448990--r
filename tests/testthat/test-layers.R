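# Compiled layer kernels: forward correctness against naive oracles and
# gradient correctness against finite differences.

ns <- asNamespace("canalseg")

naive_conv3d <- function(x, Warr, b, stride, pad) {
  d <- dim(x)
  co <- dim(Warr)[1]; k <- dim(Warr)[3:5]
  osp <- (d[2:4] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(co, osp))
  for (oc in 1:co) for (od in 1:osp[1]) for (oh in 1:osp[2]) for (ow in 1:osp[3]) {
    acc <- b[oc]
    for (c in 1:d[1]) for (a in 1:k[1]) for (bb in 1:k[2]) for (cc in 1:k[3]) {
      di <- (od - 1) * stride[1] - pad[1] + a
      hi <- (oh - 1) * stride[2] - pad[2] + bb
      wi <- (ow - 1) * stride[3] - pad[3] + cc
      if (di >= 1 && di <= d[2] && hi >= 1 && hi <= d[3] && wi >= 1 && wi <= d[4])
        acc <- acc + Warr[oc, c, a, bb, cc] * x[c, di, hi, wi]
    }
    y[oc, od, oh, ow] <- acc
  }
  y
}

unpack_weights <- function(Wm, cin, cout, k) {
  Warr <- array(0, c(cout, cin, k))
  for (oc in seq_len(cout)) Warr[oc, , , , ] <- array(Wm[, oc], c(cin, k))
  Warr
}

test_that("conv3d forward matches a naive triple-loop oracle", {
  set.seed(31)
  for (case in list(list(k = c(3L, 3L, 3L), s = c(1L, 1L, 1L), sp = c(5L, 6L, 4L)),
                    list(k = c(2L, 2L, 2L), s = c(2L, 2L, 2L), sp = c(4L, 6L, 8L)),
                    list(k = c(1L, 1L, 1L), s = c(1L, 1L, 1L), sp = c(3L, 3L, 3L)))) {
    cin <- 3L; cout <- 4L
    pad <- if (all(case$k == 3L)) c(1L, 1L, 1L) else c(0L, 0L, 0L)
    ly <- ns$layer_conv3d(cin, cout, kernel = case$k, stride = case$s, pad = pad)
    x <- array(rnorm(cin * prod(case$sp)), c(cin, case$sp))
    y <- ly$fwd(NULL, ns$tp_leaf(array(x, c(dim(x), 1))))$value
    yo <- naive_conv3d(x, unpack_weights(ly$W$value, cin, cout, case$k),
                       ly$b$value, case$s, pad)
    expect_equal(array(y, dim(yo)), yo, tolerance = 1e-12)
  }
})

test_that("transposed convolution is the exact adjoint of the reverse convolution", {
  set.seed(32)
  tc <- ns$layer_tconv3d(3L, 2L, kernel = c(4L, 4L, 4L), stride = c(2L, 2L, 2L),
                         pad = c(1L, 1L, 1L))
  tc$b$value[] <- 0
  x <- array(rnorm(3 * 4 * 5 * 6), c(3, 4, 5, 6, 1))
  y <- tc$fwd(NULL, ns$tp_leaf(x))$value
  expect_equal(dim(y), c(2L, 8L, 10L, 12L, 1L))  # doubled spatial dims
  z <- array(rnorm(length(y)), dim(y))
  convz <- ns$cpp_conv3d_forward(z, tc$W$value, dim(z)[1:4], 1L, tc$kernel,
                                 tc$stride, tc$pad)
  expect_equal(sum(y * z), sum(x * convz), tolerance = 1e-9)
})

test_that("max pooling takes blockwise maxima and routes gradients to argmax", {
  set.seed(33)
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4, 1))
  res <- ns$op_maxpool(NULL, ns$tp_leaf(x))
  y <- res$value
  for (c in 1:2) for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_equal(y[c, i, j, k, 1],
                 max(x[c, 2 * i - (1:0), 2 * j - (1:0), 2 * k - (1:0), 1]))
  tape <- ns$new_tape()
  xt <- ns$tp_leaf(x)
  yt <- ns$op_maxpool(tape, xt)
  l <- ns$tp_record(tape, sum(yt$value), list(yt),
                    function(gy) list(array(as.numeric(gy), dim(yt$value))))
  ns$tp_backward(tape, l)
  expect_equal(sum(xt$grad), length(y))        # one unit per pooled cell
  expect_true(all(xt$grad %in% c(0, 1)))
})

test_that("batch norm standardizes per channel in training mode", {
  set.seed(34)
  bn <- ns$layer_bn3d(3L)
  x <- array(rnorm(3 * 4 * 4 * 4 * 2, mean = 5, sd = 3), c(3, 4, 4, 4, 2))
  y <- bn$fwd(NULL, ns$tp_leaf(x), training = TRUE)$value
  ym <- matrix(y, nrow = 3)
  expect_equal(unname(rowMeans(ym)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(ym, 1, function(r) mean(r^2))), rep(1, 3),
               tolerance = 1e-3)
})

test_that("the full network backward pass matches finite differences", {
  set.seed(35)
  net <- buildNetwork(tiny_net_config(), seed = 36)
  xin <- array(rnorm(1 * 8 * 8 * 8 * 2), c(1, 8, 8, 8, 2))
  g <- array(rbinom(length(xin), 1, 0.3), dim(xin))
  bns <- ns$bn_layers(net)
  snap <- lapply(bns, function(b) list(m = b$running_mean, v = b$running_var))
  restore <- function() for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- snap[[i]]$m
    bns[[i]]$running_var <- snap[[i]]$v
  }
  loss_of <- function() {
    tape <- ns$new_tape()
    l <- ns$op_dice_loss(tape, ns$network_forward(net, tape, ns$tp_leaf(xin),
                                                  training = TRUE), g, 1e-5)
    list(tape = tape, l = l)
  }
  r <- loss_of()
  ns$zero_grads(net$params)
  ns$tp_backward(r$tape, r$l)
  maxerr <- 0
  for (pi in unique(c(1L, 4L, 9L, length(net$params) - 1L, length(net$params)))) {
    p <- net$params[[pi]]
    expect_false(is.null(p$grad), label = paste("grad present for", p$name))
    for (i in sample(length(p$value), min(3L, length(p$value)))) {
      v0 <- p$value
      p$value[i] <- v0[i] + 1e-5; restore(); lp <- loss_of()$l$value
      p$value <- v0; p$value[i] <- v0[i] - 1e-5; restore(); lm <- loss_of()$l$value
      p$value <- v0; restore()
      maxerr <- max(maxerr, abs((lp - lm) / 2e-5 - p$grad[i]))
    }
  }
  expect_lt(maxerr, 1e-6)
})
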