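#' Deconvolution configuration
#'
#' @param svd_truncation Singular values below this fraction of the largest
#'   singular value are zeroed before inverting the AIF convolution matrix.
#'   The default 0.005 is appropriate for noiseless or lightly smoothed data;
#'   use ~0.2 for noisy clinical-grade data.
#' @param baseline_frames Number of pre-bolus frames averaged for the baseline
#'   HU level (>= 1).
#' @param hu_per_conc HU-to-concentration conversion, or `NULL` to take it
#'   from the sample metadata (falling back to 1; all derived perfusion
#'   parameters are ratios and do not depend on this scale).
#' @param brain_hu_min Baseline HU threshold defining the brain mask.
#' @return An object of class `deconv_config`.
#' @export
deconv_config <- function(svd_truncation = 0.005, baseline_frames = 3,
                          hu_per_conc = NULL, brain_hu_min = 5) {
  if (svd_truncation <= 0 || svd_truncation >= 1)
    stop("'svd_truncation' must be in (0,1)")
  if (baseline_frames < 1) stop("'baseline_frames' must be >= 1")
  structure(list(svd_truncation = svd_truncation,
                 baseline_frames = as.integer(baseline_frames),
                 hu_per_conc = hu_per_conc, brain_hu_min = brain_hu_min),
            class = "deconv_config")
}

#' Convert a HU stack to concentration
#'
#' Per voxel, `C(t) = (HU(t) - baseline) / hu_per_conc` with the baseline
#' estimated as the mean of the first `baseline_frames` frames. Negative
#' values (noise) are kept; integration steps clip them at zero.
#'
#' @param sample A `ctp_sample`.
#' @param cfg A [deconv_config()].
#' @return List with `conc` (slice, time, y, x), `baseline` (slice, y, x) and
#'   `brain_mask` (slice, y, x) from thresholding the baseline HU map.
#' @export
signal_to_concentration <- function(sample, cfg = deconv_config()) {
  stopifnot(inherits(sample, "ctp_sample"))
  d <- dim(sample$image)
  if (cfg$baseline_frames >= d[2])
    stop("'baseline_frames' must be smaller than the frame count")
  k <- cfg$hu_per_conc
  if (is.null(k)) k <- sample$meta$hu_per_conc
  if (is.null(k)) k <- 1
  bl <- array(0, dim = d[c(1, 3, 4)])
  for (s in seq_len(d[1]))
    bl[s, , ] <- apply(sample$image[s, seq_len(cfg$baseline_frames), , ,
                                    drop = FALSE][1, , , ], 2:3, mean)
  conc <- sample$image
  for (ti in seq_len(d[2])) conc[, ti, , ] <- (conc[, ti, , ] - bl) / k
  list(conc = conc, baseline = bl, brain_mask = bl > cfg$brain_hu_min)
}

#' Select the arterial input function voxel
#'
#' Returns the concentration curve of the masked voxel with the highest peak
#' concentration; ties are broken by earliest time to peak, then by lowest
#' (slice, row, column) index, so the selection is deterministic.
#'
#' @param conc Concentration stack (slice, time, y, x).
#' @param mask Logical candidate mask (slice, y, x).
#' @return List with `curve` (length-T vector) and `index` (slice, y, x).
#' @export
select_aif <- function(conc, mask) {
  d <- dim(conc)
  if (!any(mask)) stop("empty AIF candidate mask")
  cand <- which(mask)                     # linear index into (slice, y, x)
  cm <- conc_matrix(conc)[, cand, drop = FALSE]   # T x ncand
  peaks <- apply(cm, 2, max)
  ttp <- apply(cm, 2, which.max)
  # order: peak desc, ttp asc, then lowest (row, col, slice)
  ai <- arrayInd(cand, d[c(1, 3, 4)])
  ord <- order(-peaks, ttp, ai[, 2], ai[, 3], ai[, 1])
  best <- ord[1]
  list(curve = cm[, best], index = ai[best, ])
}

# reshape (slice,time,y,x) -> T x (slice*y*x) matrix of voxel curves
conc_matrix <- function(conc) {
  d <- dim(conc)
  m <- matrix(aperm(conc, c(2, 1, 3, 4)), nrow = d[2])
  m
}

# trapezoid-quadrature lower-triangular convolution matrix of the AIF
aif_toeplitz <- function(aif_curve, dt) {
  n <- length(aif_curve)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- seq_len(i)
    w <- rep(1, i); w[1] <- 0.5; w[i] <- 0.5
    A[i, j] <- dt * w * aif_curve[i - j + 1]
  }
  A
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Voxelwise truncated-SVD deconvolution and perfusion maps
#'
#' Builds the lower-triangular Toeplitz convolution matrix of the AIF
#' (trapezoid quadrature, scaled by dt), zeroes singular values below
#' `svd_truncation` times the largest, and solves `C = A k` per voxel for the
#' flow-scaled residue `k(t) = CBF * R(t) / 6000`. Parameters:
#' CBF = 6000 max_t k(t); CBV = 100 * integral(C) / integral(AIF) (trapezoid,
#' independent of the deconvolution); MTT = 60 CBV / CBF; TTP = argmax_t C(t).
#'
#' @param conc Concentration stack (slice, time, y, x).
#' @param aif_curve AIF concentration curve on the same grid.
#' @param time_grid Uniform frame times in seconds.
#' @param cfg A [deconv_config()].
#' @param mask Logical brain mask (slice, y, x); voxels outside get zero/NA.
#' @return A `perfusion_maps` object: `cbf`, `cbv`, `mtt`, `ttp` arrays
#'   (slice, y, x), `brain_mask`, plus `k` (slice, time, y, x), the
#'   deconvolved flow-scaled residue stack.
#' @export
deconvolve <- function(conc, aif_curve, time_grid, cfg = deconv_config(),
                       mask = NULL) {
  d <- dim(conc)
  T <- d[2]
  if (length(aif_curve) != T) stop("AIF grid length mismatch")
  if (max(abs(aif_curve)) == 0) stop("all-zero AIF")
  dt <- time_grid[2] - time_grid[1]
  if (is.null(mask)) mask <- array(TRUE, dim = d[c(1, 3, 4)])
  A <- aif_toeplitz(aif_curve, dt)
  sv <- svd(A)
  dinv <- ifelse(sv$d < cfg$svd_truncation * max(sv$d), 0, 1 / sv$d)
  Ainv <- sv$v %*% (dinv * t(sv$u))
  cm <- conc_matrix(conc)                         # T x nvox
  vox <- which(mask)
  K <- Ainv %*% cm[, vox, drop = FALSE]
  cbf <- 6000 * apply(K, 2, max)
  cpos <- pmax(cm[, vox, drop = FALSE], 0)
  int_c <- dt * (colSums(cpos) - 0.5 * (cpos[1, ] + cpos[T, ]))
  int_a <- trapz(time_grid, pmax(aif_curve, 0))
  cbv <- 100 * int_c / int_a
  ttp <- (apply(cm[, vox, drop = FALSE], 2, which.max) - 1) * dt
  shape <- d[c(1, 3, 4)]
  cbf_map <- cbv_map <- array(0, dim = shape)
  mtt_map <- ttp_map <- array(NA_real_, dim = shape)
  cbf_map[vox] <- cbf
  cbv_map[vox] <- cbv
  mtt_map[vox] <- ifelse(cbf > 0, 60 * cbv / cbf, NA_real_)
  ttp_map[vox] <- ttp
  k_stack <- array(0, dim = d)
  km <- matrix(0, T, prod(shape)); km[, vox] <- K
  k_stack <- aperm(array(km, dim = c(T, shape)), c(2, 1, 3, 4))
  structure(list(cbf = cbf_map, cbv = cbv_map, mtt = mtt_map, ttp = ttp_map,
                 brain_mask = mask, k = k_stack),
            class = "perfusion_maps")
}

#' Ischemic core from a CBV threshold
#'
#' @param maps A `perfusion_maps` object.
#' @param threshold Core CBV threshold in mL/100 mL; voxels with
#'   `cbv < threshold` inside the brain mask form the core.
#' @return Logical core mask (slice, y, x).
#' @export
core_from_cbv <- function(maps, threshold = 1.2) {
  stopifnot(inherits(maps, "perfusion_maps"))
  maps$brain_mask & (maps$cbv < threshold)
}

#' Mask volume in millilitres
#'
#' @param mask Logical voxel mask.
#' @param voxel_dims `c(dx, dy, dz)` in mm.
#' @return Volume in mL: voxel count times voxel volume / 1000.
#' @export
volume_ml <- function(mask, voxel_dims) {
  stopifnot(all(voxel_dims > 0))
  sum(mask) * prod(voxel_dims) / 1000
}

#' Median core volume of a cohort
#'
#' @param volumes Numeric vector of core volumes in mL.
#' @return The standard sample median.
#' @export
median_core_volume <- function(volumes) {
  if (length(volumes) == 0) stop("empty volume list")
  median(volumes)
}

#' Dichotomize a core volume at a threshold
#'
#' Volumes strictly below the threshold are `small`, strictly above `large`.
#' A volume exactly at the threshold is labeled `large` (documented tie rule;
#' the defining inequalities are strict on both sides and silent on ties).
#'
#' @param volume Core volume(s) in mL.
#' @param threshold Dichotomization threshold in mL.
#' @return Character vector of labels `small` / `large`.
#' @export
dichotomize <- function(volume, threshold) {
  ifelse(volume < threshold, "small", "large")
}

#' Full kinetic analysis of one sample
#'
#' Concentration conversion, AIF selection, deconvolution and CBV-threshold
#' core volumetry in one call.
#'
#' @param sample A `ctp_sample`.
#' @param cfg A [deconv_config()].
#' @param cbv_threshold Core CBV threshold in mL/100 mL.
#' @return List with `maps` (`perfusion_maps`), `core_mask`, `volume_ml` and
#'   the selected `aif` curve.
#' @export
perfusion_analysis <- function(sample, cfg = deconv_config(),
                               cbv_threshold = 1.2) {
  sc <- signal_to_concentration(sample, cfg)
  aif <- select_aif(sc$conc, sc$brain_mask)
  maps <- deconvolve(sc$conc, aif$curve, sample$time_grid, cfg,
                     mask = sc$brain_mask)
  core <- core_from_cbv(maps, cbv_threshold)
  list(maps = maps, core_mask = core,
       volume_ml = volume_ml(core, sample$voxel_dims), aif = aif)
}

#' Kinetic labeling of a whole cohort
#'
#' Runs [perfusion_analysis()] on every sample, dichotomizes the estimated
#' core volumes at their median, and returns the labeling table.
#'
#' @param cohort A `ctp_cohort`.
#' @param cfg A [deconv_config()].
#' @param cbv_threshold Core CBV threshold in mL/100 mL.
#' @return Data frame with `sample_id`, `volume_ml`, `label`, plus the
#'   threshold used as attribute `threshold_ml`.
#' @export
label_cohort <- function(cohort, cfg = deconv_config(), cbv_threshold = 1.2) {
  stopifnot(inherits(cohort, "ctp_cohort"))
  vols <- vapply(cohort$samples, function(s)
    perfusion_analysis(s, cfg, cbv_threshold)$volume_ml, numeric(1))
  thr <- median_core_volume(vols)
  out <- data.frame(sample_id = cohort_ids(cohort), volume_ml = vols,
                    label = dichotomize(vols, thr))
  attr(out, "threshold_ml") <- thr
  out
}
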