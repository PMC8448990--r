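# Network layer primitives on channel-major (C, D, H, W, N) arrays.
#
# Each layer constructor returns an environment holding its parameters and a
# forward method `fwd(tape, x, training)`; x and the return value are tape
# tensors. The heavy kernels (conv3d and its two gradients, max pooling) live
# in src/kernels.cpp; batch norm and the pointwise ops are vectorised R.

as_input5 <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) dim(x) <- c(d, 1L)
  else if (length(d) != 5L) stop("expected a 4D (C,D,H,W) or 5D (C,D,H,W,N) array")
  x
}

kaiming_sd <- function(fan_in) sqrt(2 / fan_in)

## ---- 3D convolution -------------------------------------------------------

layer_conv3d <- function(cin, cout, kernel = c(3L, 3L, 3L), stride = c(1L, 1L, 1L),
                         pad = (kernel - 1L) %/% 2L, name = "conv") {
  ly <- new.env(parent = emptyenv())
  K <- cin * prod(kernel)
  ly$cin <- cin; ly$cout <- cout
  ly$kernel <- as.integer(kernel); ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad)
  ly$W <- new_param(matrix(stats::rnorm(K * cout, sd = kaiming_sd(K)), K, cout),
                    paste0(name, ".W"))
  ly$b <- new_param(numeric(cout), paste0(name, ".b"))
  ly$params <- list(ly$W, ly$b)
  ly$fwd <- function(tape, x, training = FALSE) {
    xv <- x$value
    xd <- dim(xv)
    y <- cpp_conv3d_forward(xv, ly$W$value, xd[1:4], xd[5], ly$kernel, ly$stride, ly$pad)
    y <- y + ly$b$value  # recycles along the (fastest) channel axis
    tp_record(tape, y, list(x, ly$W, ly$b), function(gy) {
      list(cpp_conv3d_bwd_input(gy, ly$W$value, xd[1:4], xd[5], ly$kernel, ly$stride, ly$pad),
           cpp_conv3d_bwd_weight(xv, gy, ly$cout, xd[1:4], xd[5], ly$kernel, ly$stride, ly$pad),
           rowSums(matrix(gy, nrow = ly$cout)))
    })
  }
  ly
}

## ---- transposed 3D convolution --------------------------------------------
# Implemented as the adjoint of a strided convolution: the forward pass is the
# convolution's input-gradient, so kernel/stride/pad describe the reverse
# (downsampling) convolution mapping output space back to input space.

layer_tconv3d <- function(cin, cout, kernel = c(4L, 4L, 4L), stride = c(2L, 2L, 2L),
                          pad = c(1L, 1L, 1L), name = "tconv") {
  ly <- new.env(parent = emptyenv())
  K <- cout * prod(kernel)  # rows of the reverse conv's im2col
  ly$cin <- cin; ly$cout <- cout
  ly$kernel <- as.integer(kernel); ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad)
  ly$W <- new_param(matrix(stats::rnorm(K * cin, sd = kaiming_sd(K)), K, cin),
                    paste0(name, ".W"))
  ly$b <- new_param(numeric(cout), paste0(name, ".b"))
  ly$params <- list(ly$W, ly$b)
  ly$fwd <- function(tape, x, training = FALSE) {
    xv <- x$value
    xd <- dim(xv)
    out_sp <- (xd[2:4] - 1L) * ly$stride - 2L * ly$pad + ly$kernel
    ydim <- c(ly$cout, out_sp)
    y <- cpp_conv3d_bwd_input(xv, ly$W$value, ydim, xd[5], ly$kernel, ly$stride, ly$pad)
    y <- y + ly$b$value
    tp_record(tape, y, list(x, ly$W, ly$b), function(gy) {
      list(cpp_conv3d_forward(gy, ly$W$value, ydim, xd[5], ly$kernel, ly$stride, ly$pad),
           cpp_conv3d_bwd_weight(gy, xv, ly$cin, ydim, xd[5], ly$kernel, ly$stride, ly$pad),
           rowSums(matrix(gy, nrow = ly$cout)))
    })
  }
  ly
}

## ---- batch normalization --------------------------------------------------

layer_bn3d <- function(C, momentum = 0.1, eps = 1e-5, name = "bn") {
  ly <- new.env(parent = emptyenv())
  ly$C <- C; ly$momentum <- momentum; ly$eps <- eps
  ly$gamma <- new_param(rep(1, C), paste0(name, ".gamma"))
  ly$beta <- new_param(numeric(C), paste0(name, ".beta"))
  ly$running_mean <- numeric(C)
  ly$running_var <- rep(1, C)
  ly$params <- list(ly$gamma, ly$beta)
  ly$fwd <- function(tape, x, training = FALSE) {
    xv <- x$value
    xd <- dim(xv)
    xm <- matrix(xv, nrow = ly$C)
    if (training) {
      mu <- rowMeans(xm)
      va <- rowMeans(xm * xm) - mu * mu
      va[va < 0] <- 0
      ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
      ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * va
    } else {
      mu <- ly$running_mean
      va <- ly$running_var
    }
    invstd <- 1 / sqrt(va + ly$eps)
    xhat <- (xm - mu) * invstd
    y <- ly$gamma$value * xhat + ly$beta$value
    dim(y) <- xd
    tp_record(tape, y, list(x, ly$gamma, ly$beta), function(gy) {
      gym <- matrix(gy, nrow = ly$C)
      ggamma <- rowSums(gym * xhat)
      gbeta <- rowSums(gym)
      gxhat <- gym * ly$gamma$value
      if (training) {
        m <- ncol(xm)
        gx <- invstd * (gxhat - rowMeans(gxhat) - xhat * (rowSums(gxhat * xhat) / m))
      } else {
        gx <- gxhat * invstd
      }
      dim(gx) <- xd
      list(gx, ggamma, gbeta)
    })
  }
  ly
}

## ---- pointwise and pooling ops --------------------------------------------

op_relu <- function(tape, x) {
  mask <- x$value > 0
  tp_record(tape, x$value * mask, list(x), function(gy) list(gy * mask))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  tp_record(tape, s, list(x), function(gy) list(gy * s * (1 - s)))
}

op_add <- function(tape, a, b) {
  tp_record(tape, a$value + b$value, list(a, b), function(gy) list(gy, gy))
}

op_maxpool <- function(tape, x, kernel = c(2L, 2L, 2L), stride = kernel) {
  xd <- dim(x$value)
  res <- cpp_maxpool3d_forward(x$value, xd[1:4], xd[5], as.integer(kernel),
                               as.integer(stride))
  tp_record(tape, res$y, list(x), function(gy) {
    list(cpp_maxpool3d_backward(gy, res$idx, xd[1:4], xd[5]))
  })
}

# Global average pooling: (C,D,H,W,N) -> (C,1,1,1,N)
op_gap <- function(tape, x) {
  xd <- dim(x$value)
  nv <- prod(xd[2:4])
  xa <- array(x$value, c(xd[1], nv, xd[5]))
  y <- apply(xa, 3L, rowMeans)
  dim(y) <- c(xd[1], 1L, 1L, 1L, xd[5])
  tp_record(tape, y, list(x), function(gy) {
    g <- array(0, xd)
    gm <- matrix(gy, nrow = xd[1])  # C x N
    for (n in seq_len(xd[5]))
      g[, , , , n] <- array(rep(gm[, n] / nv, times = nv), xd[1:4])
    list(g)
  })
}

# Spatial gating: y[c,v,n] = x[c,v,n] * s[1,v,n] (sSE excitation).
op_spatial_mul <- function(tape, x, s) {
  xd <- dim(x$value)
  sb <- rep(as.vector(s$value), each = xd[1])
  dim(sb) <- xd
  tp_record(tape, x$value * sb, list(x, s), function(gy) {
    gs <- colSums(matrix(gy * x$value, nrow = xd[1]))
    dim(gs) <- c(1L, xd[2:5])
    list(gy * sb, gs)
  })
}

# Channel gating: y[c,v,n] = x[c,v,n] * w[c,n] (GAU attention weights).
op_channel_mul <- function(tape, x, w) {
  xd <- dim(x$value)
  nv <- prod(xd[2:4])
  xa <- array(x$value, c(xd[1], nv, xd[5]))
  wm <- matrix(w$value, nrow = xd[1])  # C x N
  y <- xa
  for (n in seq_len(xd[5])) y[, , n] <- xa[, , n] * wm[, n]
  dim(y) <- xd
  tp_record(tape, y, list(x, w), function(gy) {
    ga <- array(gy, c(xd[1], nv, xd[5]))
    gx <- ga
    gw <- matrix(0, xd[1], xd[5])
    for (n in seq_len(xd[5])) {
      gx[, , n] <- ga[, , n] * wm[, n]
      gw[, n] <- rowSums(ga[, , n] * xa[, , n])
    }
    dim(gx) <- xd
    dim(gw) <- c(xd[1], 1L, 1L, 1L, xd[5])
    list(gx, gw)
  })
}

op_concat_channels <- function(tape, a, b) {
  ad <- dim(a$value); bd <- dim(b$value)
  y <- array(0, c(ad[1] + bd[1], ad[2:5]))
  ia <- seq_len(ad[1])
  y[ia, , , , ] <- a$value
  y[-ia, , , , ] <- b$value
  tp_record(tape, y, list(a, b), function(gy) {
    list(array(gy[ia, , , , , drop = FALSE], ad),
         array(gy[-ia, , , , , drop = FALSE], bd))
  })
}

# A constant (non-learned) tensor wrapper, e.g. a forced attention gate.
op_const <- function(value) tp_leaf(value)
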