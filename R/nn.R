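# Thin R wrappers around the compiled tensor primitives, plus the small dense
# and temporal-convolution layers and the Adam optimizer. Feature maps are
# channel-first arrays (C, H, W, N); weights of a k x k convolution with C_in
# channels and F filters form an (F x C_in*k*k) matrix whose column order is
# channel-fastest, matching the im2col layout in src/nn_ops.cpp.

conv2d_fwd <- function(x, w, b, k = 3L, pad = (k - 1L) %/% 2L) {
  .cpp_conv2d_fwd(x, dim(x), w, b, as.integer(k), as.integer(pad))
}

conv2d_bwd <- function(x, w, dout, k = 3L, pad = (k - 1L) %/% 2L,
                       need_dx = TRUE) {
  .cpp_conv2d_bwd(x, dim(x), w, dout, as.integer(k), as.integer(pad), need_dx)
}

maxpool2_fwd <- function(x) .cpp_maxpool2_fwd(x, dim(x))
maxpool2_bwd <- function(dout, idx, in_dims) .cpp_maxpool2_bwd(dout, idx,
                                                               as.integer(in_dims))
avgpool_fwd <- function(x, f) .cpp_avgpool_fwd(x, dim(x), as.integer(f))
gap_fwd <- function(x) .cpp_gap_fwd(x, dim(x))
gap_bwd <- function(dout, in_dims) .cpp_gap_bwd(dout, as.integer(in_dims))

# He-normal initialization for a conv/dense weight matrix (F x fan_in)
he_init <- function(f_out, fan_in) {
  matrix(rnorm(f_out * fan_in, 0, sqrt(2 / fan_in)), f_out, fan_in)
}

# 1D convolution over time, 'valid' padding. feat: (F, T, n) array; w: an
# (nf x k*F) matrix, column order feature-fastest within each kernel tap.
# Returns (To, nf, n) with To = T - k + 1.
conv1d_fwd <- function(feat, w, b, k) {
  F <- dim(feat)[1]; T <- dim(feat)[2]; n <- dim(feat)[3]
  To <- T - k + 1
  stopifnot(To >= 1)
  out <- array(0, dim = c(To, nrow(w), n))
  for (i in seq_len(n)) {
    U <- matrix(0, To, k * F)
    for (j in seq_len(k))
      U[, ((j - 1) * F + 1):(j * F)] <- t(feat[, j:(j + To - 1), i])
    out[, , i] <- U %*% t(w) + matrix(b, To, length(b), byrow = TRUE)
  }
  out
}

# Backward of conv1d_fwd; dout: (To, nf, n). Returns dw, db, dfeat.
conv1d_bwd <- function(feat, w, dout, k) {
  F <- dim(feat)[1]; T <- dim(feat)[2]; n <- dim(feat)[3]
  To <- T - k + 1
  dw <- matrix(0, nrow(w), ncol(w)); db <- numeric(nrow(w))
  dfeat <- array(0, dim = dim(feat))
  for (i in seq_len(n)) {
    U <- matrix(0, To, k * F)
    for (j in seq_len(k))
      U[, ((j - 1) * F + 1):(j * F)] <- t(feat[, j:(j + To - 1), i])
    dy <- matrix(dout[, , i], To)
    dw <- dw + t(dy) %*% U
    db <- db + colSums(dy)
    dU <- dy %*% w                                   # To x k*F
    for (j in seq_len(k)) {
      blk <- t(dU[, ((j - 1) * F + 1):(j * F), drop = FALSE])  # F x To
      dfeat[, j:(j + To - 1), i] <- dfeat[, j:(j + To - 1), i] + blk
    }
  }
  list(dw = dw, db = db, dfeat = dfeat)
}

# global max over the time axis: (To, nf, n) -> (nf, n) plus argmax
gmaxpool_fwd <- function(x) {
  To <- dim(x)[1]; nf <- dim(x)[2]; n <- dim(x)[3]
  out <- matrix(0, nf, n); idx <- matrix(0L, nf, n)
  for (i in seq_len(n)) {
    m <- matrix(x[, , i], To)
    idx[, i] <- max.col(t(m), ties.method = "first")
    out[, i] <- m[cbind(idx[, i], seq_len(nf))]
  }
  list(out = out, idx = idx)
}

gmaxpool_bwd <- function(dout, idx, in_dims) {
  dx <- array(0, dim = in_dims)
  nf <- in_dims[2]
  for (i in seq_len(in_dims[3]))
    dx[cbind(idx[, i], seq_len(nf), i)] <- dout[, i]
  dx
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# mean binary cross-entropy with the usual epsilon guard
bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# --- Adam over an arbitrarily nested list of numeric parameters -------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps)
}

adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr <- state$lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - corr * m / (sqrt(v) + state$eps)
    list(p = p, m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  state$m <- out$m; state$v <- out$v
  list(params = out$p, state = state)
}
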