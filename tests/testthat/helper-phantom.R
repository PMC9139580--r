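# Shared fixtures, built in code. The default-grid noiseless phantom is used
# by several files; small-grid variants keep model tests fast.

noiseless_spec <- function(...) phantom_spec(noise_sigma = 0, ...)

# one rendered noiseless default phantom, cached per test run
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- render_phantom(noiseless_spec())
    cache
  }
})

# small fast phantom spec: 32 px grid, 12 frames
small_spec <- function(noise_sigma = 0, ...) {
  phantom_spec(grid_shape = c(32, 32), dt = 1.5, duration = 18,
               noise_sigma = noise_sigma, brain_axes_mm = c(75, 90), ...)
}

small_lesion <- function(radii = c(18, 15), cbv_scale = 0.25)
  lesion_spec(center = c(-30, 5), radii = radii, cbv_scale = cbv_scale)

# small model config matched to the small phantom
small_config <- function(...) {
  model_config(backbone = "tiny", feature_dim = 8, n_frames = 12,
               input_px = 32, stem_pool = 4, dense_units = 4, ...)
}

# brute-force pairwise ROC-AUC oracle (0.5 credit for ties)
auc_brute <- function(labels, scores) {
  y <- as.numeric(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}
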