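test_that("standard time grid yields 32 frames", {
  tg <- time_grid(1.5, 48)
  expect_identical(tg$n_frames, 32L)
})

test_that("temporal interpolation is exact on matching grids and linear signals", {
  s <- render_phantom(small_spec(), small_lesion())
  # identical grid: bit-identical output
  same <- interpolate_time(s, time_grid(1.5, 18))
  expect_equal(same$image, s$image)
  # dt = 0.75 linear-in-time ramp -> exact on the 1.5 s grid
  t_src <- seq(0, by = 0.75, length.out = 25)
  img <- aperm(array(2 * t_src + 3, dim = c(25, 1, 4, 4)), c(2, 1, 3, 4))
  ramp <- new_ctp_sample(img, time_grid = t_src, voxel_dims = c(1, 1, 10))
  out <- interpolate_time(ramp, time_grid(1.5, 18))
  expect_equal(dim(out$image)[2], 12L)
  expect_equal(out$image[1, , 2, 2], seq(0, by = 1.5, length.out = 12) * 2 + 3)
})

test_that("sources shorter than the target duration are rejected", {
  s <- render_phantom(small_spec(), small_lesion())   # covers 16.5 s
  expect_error(interpolate_time(s, time_grid(1.5, 48)),
               "cannot be interpolated")
})

test_that("in-plane resampling is identity on the target geometry", {
  s <- render_phantom(small_spec(), small_lesion())   # 32 px over 200 mm
  out <- resample_inplane(s, out_px = 32, fov_mm = 200)
  expect_lt(max(abs(out$image - s$image)), 1e-6)
  expect_equal(out$voxel_dims[1:2], c(200 / 32, 200 / 32))
})

test_that("resampling preserves constants and approximately preserves means", {
  const <- new_ctp_sample(array(7, dim = c(1, 3, 64, 64)),
                          time_grid = c(0, 1.5, 3),
                          voxel_dims = c(200 / 64, 200 / 64, 10))
  out <- resample_inplane(const, out_px = 128, fov_mm = 200)
  expect_equal(dim(out$image)[3:4], c(128L, 128L))
  expect_lt(max(abs(out$image - 7)), 1e-9)
  # downsample a smooth 256-px image to 128 and back: mean preserved within 1%
  g <- expand.grid(y = 1:256, x = 1:256)
  smooth <- matrix(sin(g$y / 30) + cos(g$x / 22), 256, 256) + 2
  src <- new_ctp_sample(array(smooth, dim = c(1, 1, 256, 256)),
                        time_grid = 0, voxel_dims = c(200 / 256, 200 / 256, 10))
  down <- resample_inplane(src, out_px = 128, fov_mm = 200)
  up <- resample_inplane(down, out_px = 256, fov_mm = 200)
  expect_lt(abs(mean(up$image) - mean(smooth)) / mean(smooth), 0.01)
})

test_that("registration is near-identity on motion-free input", {
  s <- render_phantom(small_spec(), small_lesion())
  reg <- coregister(s)
  expect_lt(max(abs(reg$result$dy)), 0.1)
  expect_lt(max(abs(reg$result$dx)), 0.1)
  expect_lt(max(abs(reg$result$theta_deg)), 0.1)
})

test_that("registration recovers known integer shifts within half a pixel", {
  s <- render_phantom(noiseless_spec(), lesion_spec())
  moved <- apply_motion(s, 10, seed = 17)
  reg <- coregister(moved)
  off <- moved$meta$motion_offsets
  expect_lt(max(abs(reg$result$dy + off[, "dy"])), 0.5)
  expect_lt(max(abs(reg$result$dx + off[, "dx"])), 0.5)
  # metric never increases
  expect_true(all(reg$result$mse_after <= reg$result$mse_before + 1e-12))
  # re-registering the registered series is a no-op within tolerance
  reg2 <- coregister(reg$sample)
  expect_lt(max(abs(reg2$result$dy)), 0.5)
  expect_lt(max(abs(reg2$result$dx)), 0.5)
})

test_that("degenerate all-constant series registers as identity with a warning", {
  flat <- new_ctp_sample(array(1, dim = c(1, 3, 16, 16)),
                         time_grid = c(0, 1.5, 3), voxel_dims = c(1, 1, 10))
  expect_warning(reg <- coregister(flat), "constant")
  expect_true(all(reg$result$dy == 0 & reg$result$dx == 0))
})

test_that("standardization pipeline emits the (2, 32, 128, 128) model grid", {
  spec <- phantom_spec(grid_shape = c(96, 96), fov_mm = 180, dt = 1.0,
                       duration = 50, noise_sigma = 0)
  s <- render_phantom(spec, lesion_spec(radii = c(10, 8)))
  out <- standardize_sample(s, register = FALSE)
  expect_identical(dim(out$image), c(2L, 32L, 128L, 128L))
  expect_equal(out$time_grid, seq(0, by = 1.5, length.out = 32))
})

test_that("NIfTI export and import round-trip image values and geometry", {
  s <- render_phantom(small_spec(), small_lesion())
  dir <- tempfile()
  dir.create(dir)
  paths <- write_ctp_nifti(s, file.path(dir, "case"))
  expect_length(paths, 2)
  back <- read_ctp_nifti(paths, sample_id = "case")
  expect_equal(back$image, s$image, tolerance = 1e-6)
  expect_equal(back$voxel_dims, s$voxel_dims, tolerance = 1e-6)
  expect_equal(back$time_grid, s$time_grid, tolerance = 1e-6)
  # mismatched frame counts across stacks are a format error
  short <- s
  short$image <- s$image[, 1:6, , , drop = FALSE]
  short$time_grid <- s$time_grid[1:6]
  p2 <- write_ctp_nifti(short, file.path(dir, "short"))
  expect_error(read_ctp_nifti(c(paths[1], p2[2])), "inconsistent")
  unlink(dir, recursive = TRUE)
})
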