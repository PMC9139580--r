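#' Write a CTP sample as per-slice NIfTI stacks
#'
#' Each axial slice is written as one 3D+t NIfTI volume (x, y, 1, t), the
#' two-stack layout of the ISLES 2018 CTP data. The in-plane voxel size,
#' slice thickness and frame spacing are stored in `pixdim`; image values are
#' stored as float32.
#'
#' @param sample A `ctp_sample`.
#' @param prefix Output path prefix; files are written as
#'   `<prefix>_slice1.nii.gz`, `<prefix>_slice2.nii.gz`, ...
#' @return The written file paths.
#' @export
write_ctp_nifti <- function(sample, prefix) {
  stopifnot(inherits(sample, "ctp_sample"))
  d <- dim(sample$image)
  dt <- if (d[2] > 1) sample$time_grid[2] - sample$time_grid[1] else 1
  paths <- character(d[1])
  for (s in seq_len(d[1])) {
    # NIfTI is (x, y, z, t); our in-plane axes are (y, x)
    arr <- array(0, dim = c(d[4], d[3], 1L, d[2]))
    for (ti in seq_len(d[2])) arr[, , 1, ti] <- t(sample$image[s, ti, , ])
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(sample$voxel_dims[1], sample$voxel_dims[2],
                             sample$voxel_dims[3], dt)
    paths[s] <- paste0(prefix, sprintf("_slice%d.nii.gz", s))
    RNifti::writeNifti(img, paths[s], datatype = "float")
  }
  paths
}

#' Read per-slice NIfTI stacks into a CTP sample
#'
#' Assembles one `ctp_sample` from per-slice 3D+t NIfTI volumes (the ISLES
#' two-stack layout). The time grid is reconstructed from the temporal
#' `pixdim`; geometry comes from the header.
#'
#' @param paths Character vector of NIfTI paths, one per slice, in slice
#'   order. Each must be a 3D+t volume with a single z slice (or a 3D volume
#'   interpreted as one frame per third dimension).
#' @param sample_id Identifier for the assembled sample.
#' @return A `ctp_sample`.
#' @export
read_ctp_nifti <- function(paths, sample_id = "external") {
  stopifnot(length(paths) >= 1)
  vols <- lapply(paths, RNifti::readNifti)
  dims <- lapply(vols, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("inconsistent shapes between slice stacks: ",
         paste(basename(paths), collapse = ", "))
  d <- dims[[1]]
  if (length(d) == 3) d <- c(d[1], d[2], 1L, d[3])
  if (length(d) != 4 || d[3] != 1)
    stop("each file must be a single-slice 3D+t volume: ", basename(paths[1]))
  pd <- attr(vols[[1]], "pixdim")
  if (is.null(pd) || length(pd) < 4 || pd[4] <= 0)
    stop("missing temporal metadata (pixdim[4]) in ", basename(paths[1]))
  T <- d[4]
  image <- array(0, dim = c(length(paths), T, d[2], d[1]))
  for (s in seq_along(vols)) {
    v <- vols[[s]]
    dim(v) <- c(d[1], d[2], T)
    for (ti in seq_len(T)) image[s, ti, , ] <- t(v[, , ti])
  }
  new_ctp_sample(image = image, time_grid = (seq_len(T) - 1) * pd[4],
                 voxel_dims = pd[1:3], sample_id = sample_id,
                 meta = list(source = paths))
}
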