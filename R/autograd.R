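# Minimal reverse-mode tape used by the network layers.
#
# A "tensor" is an environment with $value (numeric array) and $grad (same
# shape, filled during the backward sweep). Operations executed under a tape
# append a node holding the output tensor, its input tensors, and a closure
# mapping the output gradient to input gradients. Running with tape = NULL
# performs plain forward evaluation with no recording (inference mode).

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

tp_leaf <- function(value) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t
}

# Record an op. `backward` receives the output gradient and returns a list of
# gradients aligned with `inputs`; NULL entries mean "no gradient this input".
tp_record <- function(tape, value, inputs, backward) {
  out <- tp_leaf(value)
  if (!is.null(tape)) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
    tape$nodes[[n]] <- list(out = out, inputs = inputs, backward = backward)
    tape$n <- n
  }
  out
}

tp_backward <- function(tape, loss) {
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    gy <- node$out$grad
    if (is.null(gy)) next
    gs <- node$backward(gy)
    for (k in seq_along(node$inputs)) {
      g <- gs[[k]]
      if (is.null(g)) next
      tin <- node$inputs[[k]]
      tin$grad <- if (is.null(tin$grad)) g else tin$grad + g
    }
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parameter: a leaf tensor with persistent Adam state.
new_param <- function(value, name = "") {
  p <- tp_leaf(value)
  p$name <- name
  p$m <- array(0, dim = dim(value) %||% length(value))
  p$v <- array(0, dim = dim(value) %||% length(value))
  p
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
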