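#' Batch generation settings
#'
#' Online training batches are random subsets of the dataset (drawn without
#' replacement within a batch), standardized to zero mean and unit variance
#' over all voxels of the batch, then augmented per sample with a random
#' rotation, in-plane shift and vertical flip. One augmentation draw is shared
#' by both slices and all frames of a sample, preserving inter-slice anatomy.
#'
#' @param batch_size Samples per batch.
#' @param rotation_range Rotation range in degrees.
#' @param shift_range In-plane shift range in pixels (applies to both axes).
#' @param vflip Allow random vertical flips (probability 1/2).
#' @return An object of class `batch_spec`.
#' @export
batch_spec <- function(batch_size = 12, rotation_range = c(-15, 15),
                       shift_range = c(-10, 10), vflip = TRUE) {
  stopifnot(batch_size >= 1, length(rotation_range) == 2,
            length(shift_range) == 2)
  structure(list(batch_size = as.integer(batch_size),
                 rotation_range = rotation_range, shift_range = shift_range,
                 vflip = isTRUE(vflip)),
            class = "batch_spec")
}

# stack selected cohort samples into the (H, W, T, S, n) training layout
stack_samples <- function(samples) {
  d <- dim(samples[[1]]$image)             # (S, T, H, W)
  x <- array(0, dim = c(d[3], d[4], d[2], d[1], length(samples)))
  for (i in seq_along(samples))
    x[, , , , i] <- aperm(samples[[i]]$image, c(3, 4, 2, 1))
  x
}

# zero-mean/unit-variance standardization over all voxels of the batch
standardize_batch <- function(x, eps = 1e-8) {
  mu <- mean(x)
  sig <- sd(x)
  if (sig < eps) {
    warning("zero-variance batch; epsilon-guarded standardization")
    sig <- eps
  }
  (x - mu) / sig
}

#' Generate one standardized, augmented training batch
#'
#' Draws `batch_size` samples without replacement from `ids` (default: the
#' whole cohort), standardizes the batch to zero mean and unit variance, and
#' applies one random rotation / xy-shift / vertical-flip draw per sample to
#' all of its frames. Rotated/shifted-in regions are zero-filled, i.e. filled
#' with the post-standardization background. Uses the current RNG state; seed
#' the caller for reproducibility.
#'
#' @param cohort A `ctp_cohort` with labeled samples.
#' @param spec A [batch_spec()].
#' @param ids Integer indices of the eligible samples.
#' @param augment Apply the augmentation draws.
#' @return List with `x` (H, W, T, slices, n), `y` (1 = large core), `ids`,
#'   and `draws` (per-sample rotation, shift and flip actually applied).
#' @export
make_batch <- function(cohort, spec = batch_spec(), ids = NULL,
                       augment = TRUE) {
  stopifnot(inherits(cohort, "ctp_cohort"))
  if (is.null(ids)) ids <- seq_along(cohort$samples)
  take <- if (length(ids) <= spec$batch_size) ids
          else sort(sample(ids, spec$batch_size))
  samples <- cohort$samples[take]
  x <- standardize_batch(stack_samples(samples))
  y <- as.numeric(cohort_labels(cohort)[take] == "large")
  n <- length(take)
  draws <- data.frame(rot = numeric(n), dy = numeric(n), dx = numeric(n),
                      flip = logical(n))
  if (augment) {
    draws$rot <- runif(n, spec$rotation_range[1], spec$rotation_range[2])
    draws$dy <- runif(n, spec$shift_range[1], spec$shift_range[2])
    draws$dx <- runif(n, spec$shift_range[1], spec$shift_range[2])
    draws$flip <- spec$vflip & (runif(n) < 0.5)
    d <- dim(x)
    H <- d[1]; W <- d[2]
    for (i in seq_len(n)) {
      if (draws$rot[i] == 0 && draws$dy[i] == 0 && draws$dx[i] == 0 &&
          !draws$flip[i]) next
      frames <- matrix(x[, , , , i], nrow = H * W)
      x[, , , , i] <- array(warp_rigid(frames, H, W,
                                       theta_deg = draws$rot[i],
                                       dy = draws$dy[i], dx = draws$dx[i],
                                       flip_y = draws$flip[i]),
                            dim = d[1:4])
    }
  }
  list(x = x, y = y, ids = take, draws = draws)
}

#' Predict large-core probabilities for samples
#'
#' Deterministic given fixed weights: no augmentation is applied; each
#' prediction batch is standardized with the same batch-wise zero-mean,
#' unit-variance rule used in training.
#'
#' @param object A `ctp_model`.
#' @param samples List of `ctp_sample`s, or a `ctp_cohort`.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Data frame with `sample_id` and `probability` (in `[0, 1]`).
#' @export
predict.ctp_model <- function(object, samples, batch_size = 12, ...) {
  if (inherits(samples, "ctp_cohort")) samples <- samples$samples
  if (inherits(samples, "ctp_sample")) samples <- list(samples)
  n <- length(samples)
  probs <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- standardize_batch(stack_samples(samples[idx]))
    probs[idx] <- model_forward(object, x)$prob
  }
  data.frame(sample_id = vapply(samples, function(s) s$sample_id,
                                character(1)),
             probability = probs)
}
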