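# Bilinear warping utilities shared by in-plane resampling, rigid
# registration and online augmentation. Coordinates are 1-based pixel-center
# indices; samples outside the source grid are zero-filled.

# Sample one or more frames (columns of a (H*W) x n matrix, column-major in
# (y, x)) at fractional source coordinates (ys, xs), each of length m.
# Returns an m x n matrix.
bilinear_sample <- function(frames, H, W, ys, xs) {
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0;   fx <- xs - x0
  w00 <- (1 - fy) * (1 - fx); w10 <- fy * (1 - fx)
  w01 <- (1 - fy) * fx;       w11 <- fy * fx
  idx <- function(y, x) {
    ok <- y >= 1 & y <= H & x >= 1 & x <= W
    i <- ifelse(ok, (x - 1) * H + y, 1L)
    list(i = i, ok = ok)
  }
  acc <- 0
  for (term in list(list(y0, x0, w00), list(y0 + 1, x0, w10),
                    list(y0, x0 + 1, w01), list(y0 + 1, x0 + 1, w11))) {
    p <- idx(term[[1]], term[[2]])
    w <- term[[3]] * p$ok
    acc <- acc + frames[p$i, , drop = FALSE] * w
  }
  acc
}

# Inverse-map source coordinates realizing a rigid transform of the image
# content: rotation by theta (degrees, counter-clockwise) about the image
# center followed by a translation of (dy, dx) pixels.
rigid_map <- function(H, W, theta_deg = 0, dy = 0, dx = 0, flip_y = FALSE) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  yy <- g$y - cy - dy
  xx <- g$x - cx - dx
  if (flip_y) yy <- -yy
  th <- -theta_deg * pi / 180
  list(ys = cy + cos(th) * yy - sin(th) * xx,
       xs = cx + sin(th) * yy + cos(th) * xx)
}

# Apply a rigid transform to a stack of frames ((H*W) x n matrix); returns the
# warped stack with the same shape.
warp_rigid <- function(frames, H, W, theta_deg = 0, dy = 0, dx = 0,
                       flip_y = FALSE) {
  m <- rigid_map(H, W, theta_deg, dy, dx, flip_y)
  bilinear_sample(frames, H, W, m$ys, m$xs)
}
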