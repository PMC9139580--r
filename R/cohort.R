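#' Construct a CTP sample container
#'
#' A `ctp_sample` holds one subject's slice-reduced dynamic CT acquisition:
#' a 4D HU array indexed (slice, time, y, x), the time grid in seconds, the
#' voxel dimensions in mm, optional exact ground truth (from the phantom) and
#' free-form metadata.
#'
#' @param image 4D numeric array (slice, time, y, x).
#' @param time_grid Seconds per frame; length must match `dim(image)[2]`.
#' @param voxel_dims `c(dx, dy, dz)` in mm, strictly positive.
#' @param truth Optional list of ground-truth maps and core volume.
#' @param sample_id Identifier string.
#' @param meta Free-form metadata list.
#' @return An object of class `ctp_sample`.
#' @export
new_ctp_sample <- function(image, time_grid, voxel_dims, truth = NULL,
                           sample_id = "S001", meta = list()) {
  d <- dim(image)
  if (length(d) != 4) stop("'image' must be a 4D (slice, time, y, x) array")
  if (d[2] != length(time_grid))
    stop("frame count does not match 'time_grid'")
  if (length(voxel_dims) != 3 || any(voxel_dims <= 0))
    stop("'voxel_dims' must be three positive numbers")
  structure(list(image = image, time_grid = as.numeric(time_grid),
                 voxel_dims = as.numeric(voxel_dims), truth = truth,
                 sample_id = sample_id, meta = meta),
            class = "ctp_sample")
}

#' @export
print.ctp_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<ctp_sample %s> %d slice(s) x %d frames x %dx%d px, dt=%g s\n",
              x$sample_id, d[1], d[2], d[3], d[4],
              if (d[2] > 1) x$time_grid[2] - x$time_grid[1] else NA))
  if (!is.null(x$truth))
    cat(sprintf("  truth: core %.2f mL, label %s\n",
                x$truth$core_volume_ml, x$truth$label))
  invisible(x)
}

#' @export
print.ctp_cohort <- function(x, ...) {
  vols <- cohort_core_volumes(x)
  cat(sprintf("<ctp_cohort> n=%d, threshold=%.2f mL, labels: %s\n",
              length(x$samples), x$threshold_ml,
              paste(names(table(cohort_labels(x))),
                    table(cohort_labels(x)), collapse = ", ")))
  cat(sprintf("  core volumes: %.2f-%.2f mL (median %.2f)\n",
              min(vols), max(vols), stats::median(vols)))
  invisible(x)
}

#' Cohort accessors
#'
#' @param cohort A `ctp_cohort`.
#' @return `cohort_core_volumes()` the true core volume (mL) per sample;
#'   `cohort_labels()` the small/large label per sample; `cohort_ids()` the
#'   sample ids.
#' @export
cohort_core_volumes <- function(cohort) {
  vapply(cohort$samples, function(s) s$truth$core_volume_ml, numeric(1))
}

#' @rdname cohort_core_volumes
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$samples, function(s) s$truth$label, character(1))
}

#' @rdname cohort_core_volumes
#' @export
cohort_ids <- function(cohort) {
  vapply(cohort$samples, function(s) s$sample_id, character(1))
}

#' Read and write cohort containers
#'
#' Cohorts are stored as a single serialized R container file holding the 4D
#' stacks, ground-truth maps, geometry, seed and threshold. For interchange
#' with other tools use [write_ctp_nifti()] / [export_cohort_nifti()].
#'
#' @param cohort A `ctp_cohort`.
#' @param path File path (conventionally `.rds`).
#' @return `read_cohort()` returns the `ctp_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ctp_cohort"))
  saveRDS(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readRDS(path)
  if (!inherits(cohort, "ctp_cohort")) stop("not a ctp_cohort container")
  cohort
}

#' Export every sample of a cohort as per-slice NIfTI stacks
#'
#' Writes two 3D+t NIfTI files per sample (one per axial slice), matching the
#' two-stack layout used by the ISLES 2018 challenge data.
#'
#' @param cohort A `ctp_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
export_cohort_nifti <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- unlist(lapply(cohort$samples, function(s)
    write_ctp_nifti(s, file.path(dir, s$sample_id))))
  invisible(paths)
}
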