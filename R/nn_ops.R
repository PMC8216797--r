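# Low-level numeric kernels for the convolutional backbone.
#
# Batches are stored as H x W x C x N arrays (column-major), so a per-sample
# feature map flattens to one column of a matrix.  The 3x3 "same"
# convolutions and 2x2 max-pooling run in compiled code (src/nn_kernels.cpp);
# the softmax/linear algebra stays in R where BLAS already does the work.

# Column-wise softmax of a C x N score matrix.
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# Backward through column-wise softmax: given p = softmax(z) and dL/dp,
# returns dL/dz = p * (dp - sum_c dp_c p_c).
softmax_backward_cols <- function(p, dp) {
  p * (dp - rep(colSums(dp * p), each = nrow(p)))
}

# 3x3 "same" convolution.  X: H x W x Cin x N, K: 3 x 3 x Cin x Cout,
# b: length Cout.  Returns list(out, cols, in_dim); cols is the im2col
# packing of X, cached because the backward pass reuses it.
conv3x3_forward <- function(X, K, b) {
  d <- as.integer(dim(X))
  r <- conv3x3_fwd_cpp(X, d, K, dim(K)[4L], b)
  out <- r$out
  dim(out) <- c(d[1L], d[2L], dim(K)[4L], d[4L])
  list(out = out, cols = r$cols, in_dim = d)
}

# Backward of conv3x3_forward.  dOut: H x W x Cout x N.  Returns gradients
# w.r.t. the kernel, the bias and the layer input.
conv3x3_backward <- function(dOut, cache, K) {
  g <- conv3x3_bwd_cpp(dOut, cache$cols, cache$in_dim, K, dim(K)[4L])
  dim(g$dK) <- dim(K)
  dim(g$dX) <- cache$in_dim
  g
}

# 2x2 max pooling, stride 2.  H and W must be even.  The argmax position
# within each window (fixed scan order, first maximum under ties) is cached
# for deterministic gradient routing.
maxpool2_forward <- function(X) {
  d <- dim(X)
  r <- maxpool2_fwd_cpp(X, as.integer(d))
  out <- r$out
  dim(out) <- c(d[1L] %/% 2L, d[2L] %/% 2L, d[3L], d[4L])
  list(out = out, arg = r$arg, in_dim = d)
}

maxpool2_backward <- function(dOut, cache) {
  dX <- maxpool2_bwd_cpp(dOut, cache$arg, as.integer(cache$in_dim))
  dim(dX) <- cache$in_dim
  dX
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Adam update on a flat list of arrays; state carries first/second moments
# and the step counter.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
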