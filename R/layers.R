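# Tensor layout: numeric array with dim = c(spatial..., channels), spatial
# being 2 (in-plane) or 3 (volume) axes. All hot kernels (convolution,
# transposed convolution, pooling, ReLU) live in src/ and accumulate
# through BLAS; weights for a k^d kernel are stored as a (k^d * Cin) x Cout
# matrix, tap-major with axis-1 offsets fastest.

conv_fwd <- function(x, w, dilation = 1L, pad = TRUE, where = "conv") {
  d <- length(dim(x)) - 1L
  padw <- if (pad) dilation else 0L
  osp <- dim(x)[seq_len(d)] + 2L * padw - 2L * dilation
  if (any(osp < 1L)) {
    stop(sprintf("%s: spatial shape (%s) too small for a 3^%d kernel (dilation %d)",
                 where, paste(dim(x)[seq_len(d)], collapse = "x"), d, dilation),
         call. = FALSE)
  }
  conv_fwd_cpp(x, w$W, w$b, as.integer(dilation), as.integer(padw))
}

conv_bwd <- function(x, w, dy, dilation = 1L, pad = TRUE) {
  padw <- if (pad) dilation else 0L
  conv_bwd_cpp(x, w$W, dy, as.integer(dilation), as.integer(padw))
}

# 1-voxel convolution (channel mixing); W is Cin x Cout
conv1_fwd <- function(x, w) {
  d <- length(dim(x)) - 1L
  y <- matrix(x, ncol = dim(x)[d + 1L]) %*% w$W
  y <- y + rep(w$b, each = nrow(y))
  dim(y) <- c(dim(x)[seq_len(d)], length(w$b))
  y
}

conv1_bwd <- function(x, w, dy) {
  d <- length(dim(x)) - 1L
  xmat <- matrix(x, ncol = dim(x)[d + 1L])
  dymat <- matrix(dy, ncol = dim(dy)[d + 1L])
  list(dx = array(tcrossprod(dymat, w$W), dim(x)),
       dW = crossprod(xmat, dymat), db = colSums(dymat))
}

# 2^d max-pooling, stride 2; ties go to the first tap in scan order
pool_fwd <- function(x) {
  d <- length(dim(x)) - 1L
  sp <- dim(x)[seq_len(d)]
  if (any(sp %% 2L != 0L)) {
    stop("max-pooling requires even spatial extents, got ",
         paste(sp, collapse = "x"), call. = FALSE)
  }
  pool_fwd_cpp(x)
}

pool_bwd <- function(dy, argmax, x_dim) {
  pool_bwd_cpp(dy, argmax, as.integer(x_dim))
}

# transposed convolution, kernel 2^d, stride 2
upconv_fwd <- function(x, w) upconv_fwd_cpp(x, w$W, w$b)
upconv_bwd <- function(x, w, dy) upconv_bwd_cpp(x, w$W, dy)

relu_fwd <- function(x) relu_fwd_cpp(x)
relu_bwd <- function(y, dy) relu_bwd_cpp(y, dy)

concat_channels <- function(a, b) {
  d <- length(dim(a)) - 1L
  array(c(a, b), c(dim(a)[seq_len(d)], dim(a)[d + 1L] + dim(b)[d + 1L]))
}

# center-crop the spatial axes of x down to `target` (unpadded skips)
crop_to <- function(x, target) {
  d <- length(dim(x)) - 1L
  sp <- dim(x)[seq_len(d)]
  m <- (sp - target) %/% 2L
  if (any(m < 0L) || any((sp - target) %% 2L != 0L)) {
    stop("crop_to: cannot center-crop ", paste(sp, collapse = "x"), " to ",
         paste(target, collapse = "x"), call. = FALSE)
  }
  idx <- lapply(seq_len(d), function(ax) m[ax] + seq_len(target[ax]))
  if (d == 2L) x[idx[[1L]], idx[[2L]], , drop = FALSE]
  else x[idx[[1L]], idx[[2L]], idx[[3L]], , drop = FALSE]
}

uncrop_to <- function(dy, orig_sp) {
  d <- length(dim(dy)) - 1L
  target <- dim(dy)[seq_len(d)]
  m <- (orig_sp - target) %/% 2L
  dx <- array(0, c(orig_sp, dim(dy)[d + 1L]))
  idx <- lapply(seq_len(d), function(ax) m[ax] + seq_len(target[ax]))
  if (d == 2L) dx[idx[[1L]], idx[[2L]], ] <- dy
  else dx[idx[[1L]], idx[[2L]], idx[[3L]], ] <- dy
  dx
}

# numerically stable two-channel softmax; returns foreground probability
softmax2 <- function(logits) {
  d <- length(dim(logits)) - 1L
  sp <- dim(logits)[seq_len(d)]
  z <- matrix(logits, ncol = 2L)
  m <- pmax(z[, 1L], z[, 2L])
  e0 <- exp(z[, 1L] - m)
  e1 <- exp(z[, 2L] - m)
  p <- e1 / (e0 + e1)
  dim(p) <- sp
  p
}
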