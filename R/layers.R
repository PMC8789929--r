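# Differentiable layer primitives.  Each forward returns the output plus
# whatever the matching backward needs.  Activations are (X, Y, Z, C)
# double arrays.

BN_EPS <- 1e-3          # variance floor inside normalization layers
BN_MOMENTUM <- 0.99     # running-statistics decay, per-step

conv3_forward <- function(x, w, b) {
  d <- dim(x)
  .conv3d_forward(x, w, b, c(d[1:3], d[4], dim(w)[5]))
}

conv3_backward <- function(x, w, gy) {
  d <- dim(x)
  .conv3d_backward(x, w, gy, c(d[1:3], d[4], dim(w)[5]))
}

# 1x1x1 convolution (a per-voxel linear map), used by the supervision heads.
conv1_forward <- function(x, w, b) {
  d <- dim(x)
  m <- matrix(x, ncol = d[4]) %*% w
  m <- sweep(m, 2L, b, "+")
  dim(m) <- c(d[1:3], ncol(w))
  m
}

conv1_backward <- function(x, w, gy) {
  d <- dim(x); dc <- dim(gy)
  xm <- matrix(x, ncol = d[4])
  gm <- matrix(gy, ncol = dc[4])
  gx <- gm %*% t(w)
  dim(gx) <- d
  list(gx = gx, gw = t(xm) %*% gm, gb = colSums(gm))
}

relu_forward <- function(x) .relu_forward(x)

relu_backward <- function(gy, y) .relu_backward(gy, y)

# Per-channel statistics over all voxels of the presented sample.
channel_stats <- function(x) .channel_stats(x, dim(x))

# Batch normalization over the voxel dimension of a single volume.
# `stats` supplies the normalization statistics (batch statistics during
# training and sample-statistics prediction; stored running statistics for
# standard prediction).
bn_forward <- function(x, gamma, beta, stats) {
  invstd <- 1 / sqrt(stats$var + BN_EPS)
  out <- .bn_apply(x, stats$mean, invstd, gamma, beta, dim(x))
  list(y = out$y, xhat = out$xhat, invstd = invstd)
}

# Backward through batch normalization.  `batch = TRUE` uses the full
# batch-statistics Jacobian (statistics depend on the input); FALSE treats
# the statistics as constants (standard prediction).
bn_backward <- function(gy, gamma, cache, batch = TRUE) {
  out <- .bn_grad(gy, cache$xhat, gamma, cache$invstd, dim(gy), batch)
  list(gx = out$gx, dgamma = out$dgamma, dbeta = out$dbeta)
}

dropout_forward <- function(x, rate) {
  if (rate <= 0) return(list(y = x, mask = NULL))
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(gy, mask) {
  if (is.null(mask)) gy else gy * mask
}

maxpool_forward <- function(x) {
  .maxpool3d_forward(x, dim(x))
}

maxpool_backward <- function(gy, idx, in_dims) {
  .maxpool3d_backward(gy, idx, as.integer(in_dims))
}

upsample_forward <- function(x) {
  .upsample3d_forward(x, dim(x))
}

upsample_backward <- function(gy) {
  .upsample3d_backward(gy, dim(gy))
}

concat_channels <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])[1:3]
  for (p in parts)
    if (!identical(dim(p)[1:3], d))
      stop("concatenation inputs disagree on the spatial grid")
  cs <- vapply(parts, function(p) dim(p)[4], integer(1))
  out <- array(0, c(d, sum(cs)))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[4]
    out[, , , at + seq_len(cp)] <- p
    at <- at + cp
  }
  out
}

split_channels <- function(g, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    out <- g[, , , at + seq_len(s), drop = FALSE]
    at <<- at + s
    out
  })
}
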