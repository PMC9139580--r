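#' Lesion specification for the digital phantom
#'
#' Describes an elliptical hypoperfused lesion spanning both slices. Lesion
#' voxels keep their tissue class but have CBF and CBV scaled down by
#' `cbf_scale` and `cbv_scale`; the MTT is recomputed so the central volume
#' principle continues to hold exactly.
#'
#' @param center In-plane lesion center in mm relative to the image center,
#'   either a length-2 vector `c(x, y)` used for both slices or a 2-column
#'   matrix with one row per slice.
#' @param radii Ellipse semi-axes `c(rx, ry)` in mm.
#' @param cbf_scale,cbv_scale Multiplicative factors in (0, 1); values below 1
#'   make the lesion hypoperfused relative to its tissue class.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center = c(-35, 10), radii = c(15, 12),
                        cbf_scale = 0.3, cbv_scale = 0.25) {
  if (is.null(dim(center))) center <- matrix(center, nrow = 1)
  stopifnot(ncol(center) == 2, length(radii) == 2, all(radii > 0))
  if (cbf_scale <= 0 || cbf_scale >= 1) stop("'cbf_scale' must be in (0,1)")
  if (cbv_scale <= 0 || cbv_scale >= 1) stop("'cbv_scale' must be in (0,1)")
  structure(list(center = center, radii = radii,
                 cbf_scale = cbf_scale, cbv_scale = cbv_scale),
            class = "lesion_spec")
}

#' Phantom acquisition and tissue specification
#'
#' Defines the geometry, time grid, tissue classes, HU conversion and
#' degradation settings of the synthetic 2D+t CTP phantom. The defaults
#' reproduce the standardized acquisition grid: 1.5 s temporal resolution over
#' a 48 s scan (32 frames), two axial slices of 128 x 128 pixels covering a
#' 200 x 200 mm^2 field of view.
#'
#' Default tissue classes (baseline HU, CBF mL/100 mL/min, CBV mL/100 mL):
#' gray matter (35, 60, 4), white matter (25, 25, 2), vessel (45, 6000, 100,
#' a CBV-100 arterial surrogate whose peak enhancement dominates every tissue
#' voxel), background (0, none). The linear HU model `HU = baseline +
#' hu_per_conc * C(t)` with the default `hu_per_conc` gives a peak gray-matter
#' enhancement of roughly 8 HU, a typical clinical magnitude.
#'
#' @param grid_shape Image size `c(H, W)` in pixels.
#' @param fov_mm In-plane field of view in mm (square).
#' @param slice_thickness_mm Slice thickness in mm.
#' @param n_slices Number of axial slices (the pipeline works with 2).
#' @param dt Temporal resolution in seconds.
#' @param duration Scan duration in seconds; `duration/dt` must be an integer
#'   frame count.
#' @param tissue_classes Named list of tissue classes; each entry is a list
#'   with `hu0` (baseline HU) and `kin` (a [tissue_kinetics()], or `NULL` for
#'   background).
#' @param aif An [aif_model()] driving every voxel's enhancement.
#' @param hu_per_conc HU per concentration unit.
#' @param noise_sigma Additive Gaussian HU noise standard deviation.
#' @param motion_amplitude Maximum per-frame rigid shift in pixels.
#' @param brain_axes_mm,white_frac Geometry of the elliptical brain mask and
#'   the concentric white-matter core (fraction of the brain semi-axes).
#' @param seed Integer seed stored with the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128), fov_mm = 200,
                         slice_thickness_mm = 10, n_slices = 2,
                         dt = 1.5, duration = 48,
                         tissue_classes = default_tissue_classes(),
                         aif = aif_model(), hu_per_conc = 350,
                         noise_sigma = 1, motion_amplitude = 0,
                         brain_axes_mm = c(75, 90), white_frac = 0.6,
                         seed = 1L) {
  n_frames <- duration / dt
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop("'duration'/'dt' must be an integer frame count")
  stopifnot(length(grid_shape) == 2, all(grid_shape > 0), fov_mm > 0,
            slice_thickness_mm > 0, n_slices >= 1, noise_sigma >= 0,
            motion_amplitude >= 0)
  structure(list(grid_shape = as.integer(grid_shape), fov_mm = fov_mm,
                 pixel_spacing = fov_mm / grid_shape[2],
                 slice_thickness_mm = slice_thickness_mm,
                 n_slices = as.integer(n_slices), dt = dt, duration = duration,
                 n_frames = as.integer(round(n_frames)),
                 tissue_classes = tissue_classes, aif = aif,
                 hu_per_conc = hu_per_conc, noise_sigma = noise_sigma,
                 motion_amplitude = motion_amplitude,
                 brain_axes_mm = brain_axes_mm, white_frac = white_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_tissue_classes <- function() {
  list(background = list(hu0 = 0, kin = NULL),
       white = list(hu0 = 25, kin = tissue_kinetics(cbf = 25, cbv = 2)),
       gray = list(hu0 = 35, kin = tissue_kinetics(cbf = 60, cbv = 4)),
       vessel = list(hu0 = 45, kin = tissue_kinetics(cbf = 6000, cbv = 100)))
}

# mm coordinates of pixel centers relative to the image center
pixel_coords_mm <- function(spec) {
  H <- spec$grid_shape[1]; W <- spec$grid_shape[2]
  px <- spec$pixel_spacing
  list(x = ((1:W) - (W + 1) / 2) * px, y = ((1:H) - (H + 1) / 2) * px)
}

# integer class-id map for one slice: 1 bg, 2 white, 3 gray, 4 vessel
build_class_map <- function(spec) {
  co <- pixel_coords_mm(spec)
  H <- spec$grid_shape[1]; W <- spec$grid_shape[2]
  X <- matrix(co$x, H, W, byrow = TRUE)
  Y <- matrix(co$y, H, W)
  ax <- spec$brain_axes_mm
  brain <- (X / ax[1])^2 + (Y / ax[2])^2 <= 1
  white <- (X / (spec$white_frac * ax[1]))^2 +
           (Y / (spec$white_frac * ax[2]))^2 <= 1
  cls <- matrix(1L, H, W)
  cls[brain] <- 3L          # cortical ribbon: gray
  cls[white] <- 2L          # inner core: white
  # 2x2 arterial voxel block near the anterior midline, one per slice
  vx <- which.min(abs(co$x - 0)); vy <- which.min(abs(co$y - (-50)))
  cls[vy + 0:1, vx + 0:1] <- 4L
  cls
}

lesion_mask_for_slice <- function(spec, lesion, s) {
  co <- pixel_coords_mm(spec)
  H <- spec$grid_shape[1]; W <- spec$grid_shape[2]
  ctr <- lesion$center[min(s, nrow(lesion$center)), ]
  X <- matrix(co$x, H, W, byrow = TRUE)
  Y <- matrix(co$y, H, W)
  ((X - ctr[1]) / lesion$radii[1])^2 + ((Y - ctr[2]) / lesion$radii[2])^2 <= 1
}

#' Render a noiseless phantom sample with exact ground truth
#'
#' Builds the elliptical brain (concentric gray/white regions plus an arterial
#' voxel block per slice), assigns each voxel its class kinetics, scales
#' lesion voxels by the lesion's CBF/CBV factors (MTT recomputed so the
#' central volume identity is preserved), and renders the 4D HU stack
#' `baseline + hu_per_conc * C(t)` voxel by voxel. Ground-truth CBF/CBV/MTT
#' maps, the sub-threshold core mask and the true core volume are attached.
#'
#' @param spec A [phantom_spec()].
#' @param lesion A [lesion_spec()], or `NULL` for a healthy phantom.
#' @param sample_id Sample identifier string.
#' @param core_cbv_threshold CBV threshold (mL/100 mL) defining the true core.
#' @return A `ctp_sample`: list with `image` (slice, time, y, x), `time_grid`,
#'   `voxel_dims`, `truth` (maps, `core_mask`, `core_volume_ml`, `label`
#'   initially `NA`), `sample_id` and `meta`.
#' @export
render_phantom <- function(spec, lesion = lesion_spec(), sample_id = "S001",
                           core_cbv_threshold = 1.2) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$grid_shape[1]; W <- spec$grid_shape[2]
  S <- spec$n_slices; T <- spec$n_frames
  t <- (seq_len(T) - 1) * spec$dt
  cls_map <- build_class_map(spec)   # identical anatomy on both slices
  classes <- spec$tissue_classes
  hu0 <- c(classes$background$hu0, classes$white$hu0,
           classes$gray$hu0, classes$vessel$hu0)

  kin_of <- function(id, lesioned) {
    k <- switch(id, NULL, classes$white$kin, classes$gray$kin,
                classes$vessel$kin)
    if (is.null(k)) return(NULL)
    if (lesioned && id %in% 2:3)     # arteries are not scaled by the lesion
      k <- tissue_kinetics(cbf = k$cbf * lesion$cbf_scale,
                           cbv = k$cbv * lesion$cbv_scale)
    k
  }

  image <- array(0, dim = c(S, T, H, W))
  cbf_map <- array(0, dim = c(S, H, W))
  cbv_map <- array(0, dim = c(S, H, W))
  mtt_map <- array(NA_real_, dim = c(S, H, W))
  brain <- cls_map != 1L
  base <- matrix(hu0[cls_map], H, W)

  for (s in seq_len(S)) {
    les <- if (is.null(lesion)) matrix(FALSE, H, W)
           else lesion_mask_for_slice(spec, lesion, s)
    if (!is.null(lesion) && any(les & !brain))
      stop("lesion extends outside the brain mask")
    # voxel groups sharing one kinetics: (class, lesioned) pairs
    grp <- cls_map + 4L * (les & cls_map %in% 2:3)
    curves <- matrix(0, 8, T)
    cbf_v <- cbv_v <- rep(0, 8); mtt_v <- rep(NA_real_, 8)
    for (g in sort(unique(as.vector(grp)))) {
      k <- kin_of(((g - 1L) %% 4L) + 1L, g > 4L)
      if (is.null(k)) next
      # An arterial voxel carries the input itself: its concentration is the
      # AIF (delta-like residue), with the nominal CBV-100 surrogate kinetics
      # recorded in the truth maps.
      curves[g, ] <- if (g == 4L) eval_aif(spec$aif, t)
                     else tissue_curve(spec$aif, k, t)
      cbf_v[g] <- k$cbf; cbv_v[g] <- k$cbv; mtt_v[g] <- k$mtt
    }
    cbf_map[s, , ] <- matrix(cbf_v[grp], H, W)
    cbv_map[s, , ] <- matrix(cbv_v[grp], H, W)
    mtt_map[s, , ] <- matrix(mtt_v[grp], H, W)
    M <- curves[as.vector(grp), , drop = FALSE]    # (H*W) x T
    for (ti in seq_len(T))
      image[s, ti, , ] <- base + spec$hu_per_conc * matrix(M[, ti], H, W)
  }

  brain_mask <- array(rep(brain, S), dim = c(H, W, S))
  brain_mask <- aperm(brain_mask, c(3, 1, 2))
  core_mask <- brain_mask & (cbv_map < core_cbv_threshold) & (cbv_map > 0)
  voxel_dims <- c(spec$pixel_spacing, spec$pixel_spacing,
                  spec$slice_thickness_mm)
  truth <- list(cbf = cbf_map, cbv = cbv_map, mtt = mtt_map,
                brain_mask = brain_mask, core_mask = core_mask,
                core_volume_ml = sum(core_mask) * prod(voxel_dims) / 1000,
                cbv_threshold = core_cbv_threshold, label = NA_character_)
  new_ctp_sample(image = image, time_grid = t, voxel_dims = voxel_dims,
                 truth = truth, sample_id = sample_id,
                 meta = list(hu_per_conc = spec$hu_per_conc,
                             baseline_hu = base, fov_mm = spec$fov_mm))
}

#' Add i.i.d. Gaussian HU noise to a sample
#'
#' @param sample A `ctp_sample`.
#' @param sigma Noise standard deviation in HU (>= 0).
#' @param seed Integer seed; identical seeds give identical noise.
#' @return The noisy sample.
#' @export
add_noise <- function(sample, sigma, seed = 1L) {
  stopifnot(inherits(sample, "ctp_sample"), sigma >= 0)
  if (sigma == 0) return(sample)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample$image <- sample$image + array(rnorm(length(sample$image), 0, sigma),
                                       dim = dim(sample$image))
  sample$meta$noise_sigma <- sigma
  sample
}

#' Apply per-frame rigid motion to a sample
#'
#' Every frame after the first is shifted by an integer 2D offset drawn
#' uniformly from `[-amplitude, amplitude]` pixels (the same offset for both
#' slices of a frame, as for rigid head motion); frame 0 is untouched. Pixels
#' shifted in from outside the field of view are zero-filled. The applied
#' offsets are recorded in `meta$motion_offsets` (frames x (dy, dx)).
#'
#' @param sample A `ctp_sample`.
#' @param amplitude Maximum absolute shift in pixels (>= 0).
#' @param seed Integer seed.
#' @return The motion-corrupted sample.
#' @export
apply_motion <- function(sample, amplitude, seed = 1L) {
  stopifnot(inherits(sample, "ctp_sample"), amplitude >= 0)
  d <- dim(sample$image)
  T <- d[2]
  offsets <- matrix(0L, T, 2, dimnames = list(NULL, c("dy", "dx")))
  if (amplitude > 0 && T > 1) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    offsets[-1, ] <- matrix(sample.int(2 * amplitude + 1,
                                       2 * (T - 1), replace = TRUE) -
                            (amplitude + 1), ncol = 2)
    for (ti in 2:T)
      if (any(offsets[ti, ] != 0))
        for (s in seq_len(d[1]))
          sample$image[s, ti, , ] <- shift_integer(sample$image[s, ti, , ],
                                                   offsets[ti, 1],
                                                   offsets[ti, 2])
  }
  sample$meta$motion_offsets <- offsets
  sample
}

# integer shift with zero fill: content moves by (+dy, +dx)
shift_integer <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Lesion-size laws for cohort simulation
#'
#' `lesion_law_uniform()` draws ellipse semi-axes uniformly over a wide range,
#' producing a continuous spread of core volumes (the default cohort).
#' `lesion_law_separated()` draws from two well-separated size modes,
#' alternating between them so a cohort of even size contains exactly half of
#' each: the median core volume then falls inside the separation gap and the
#' dichotomized classes coincide with the size modes (a Bernoulli mode choice
#' would occasionally put the median inside one mode, labeling near-identical
#' lesions differently). This is the "strongly separated" condition used in
#' learnability experiments.
#'
#' Both return a function that, when called, draws one [lesion_spec()] using
#' the current RNG state.
#'
#' @param r_range,r_small,r_large Semi-axis ranges in mm.
#' @param cbf_scale_range,cbv_scale_range Ranges for the lesion scales.
#' @return A function drawing a `lesion_spec`.
#' @export
lesion_law_uniform <- function(r_range = c(4, 26),
                               cbf_scale_range = c(0.25, 0.4),
                               cbv_scale_range = c(0.2, 0.28)) {
  function() {
    rx <- runif(1, r_range[1], r_range[2])
    lesion_spec(center = jitter_center(), radii = c(rx, rx * runif(1, 0.7, 1.1)),
                cbf_scale = runif(1, cbf_scale_range[1], cbf_scale_range[2]),
                cbv_scale = runif(1, cbv_scale_range[1], cbv_scale_range[2]))
  }
}

#' @rdname lesion_law_uniform
#' @export
lesion_law_separated <- function(r_small = c(4, 7), r_large = c(18, 24),
                                 cbf_scale_range = c(0.25, 0.4),
                                 cbv_scale_range = c(0.2, 0.28)) {
  draw_count <- 0L
  function() {
    draw_count <<- draw_count + 1L
    rng <- if (draw_count %% 2L == 1L) r_small else r_large
    rx <- runif(1, rng[1], rng[2])
    lesion_spec(center = jitter_center(), radii = c(rx, rx * runif(1, 0.8, 1.0)),
                cbf_scale = runif(1, cbf_scale_range[1], cbf_scale_range[2]),
                cbv_scale = runif(1, cbv_scale_range[1], cbv_scale_range[2]))
  }
}

# small positional jitter keeps the largest default lesion inside the brain
jitter_center <- function() {
  c(runif(1, -38, -28) * sample(c(1, -1), 1), runif(1, -8, 12))
}

#' Simulate a labeled synthetic cohort
#'
#' Renders `n` seeded phantom samples with lesions drawn from `volume_law`,
#' applies the spec's noise and motion settings, computes the cohort median
#' true core volume, uses it as the dichotomization threshold, and labels
#' every sample (`small` / `large`; ties at the median are labeled `large`).
#'
#' @param n Number of samples (>= 2).
#' @param spec A [phantom_spec()].
#' @param volume_law A lesion-drawing function, e.g. [lesion_law_uniform()].
#' @param seed Integer seed controlling lesions, noise and motion.
#' @return A `ctp_cohort`: list with `samples`, `threshold_ml`, `seed`,
#'   `provenance`.
#' @export
simulate_cohort <- function(n, spec = phantom_spec(),
                            volume_law = lesion_law_uniform(), seed = 1L) {
  stopifnot(n >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lesions <- replicate(n, volume_law(), simplify = FALSE)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * n), ncol = 2)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    s <- render_phantom(spec, lesions[[i]], sample_id = sprintf("S%03d", i))
    if (spec$noise_sigma > 0)
      s <- add_noise(s, spec$noise_sigma, seed = sub_seeds[i, 1])
    if (spec$motion_amplitude > 0)
      s <- apply_motion(s, spec$motion_amplitude, seed = sub_seeds[i, 2])
    samples[[i]] <- s
  }
  volumes <- vapply(samples, function(s) s$truth$core_volume_ml, numeric(1))
  threshold <- median_core_volume(volumes)
  if (length(unique(volumes)) == 1)
    warning("degenerate volume law: all core volumes identical; ",
            "labels fall to the tie rule (large)")
  for (i in seq_len(n))
    samples[[i]]$truth$label <- dichotomize(volumes[i], threshold)
  structure(list(samples = samples, threshold_ml = threshold,
                 seed = as.integer(seed),
                 provenance = sprintf("ctpcore phantom cohort n=%d seed=%d", n,
                                      seed)),
            class = "ctp_cohort")
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
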