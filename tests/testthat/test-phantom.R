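test_that("noiseless phantom starts at the baseline HU map", {
  s <- default_phantom()
  for (sl in 1:2)
    expect_equal(s$image[sl, 1, , ], s$meta$baseline_hu)
})

test_that("true core volume equals the brute-force voxel count", {
  s <- default_phantom()
  brute <- sum(s$truth$brain_mask & s$truth$cbv > 0 & s$truth$cbv < 1.2)
  expect_equal(s$truth$core_volume_ml,
               brute * prod(s$voxel_dims) / 1000)
  expect_gt(s$truth$core_volume_ml, 0)
})

test_that("a mildly hypoperfused lesion above the CBV threshold has no core", {
  # white matter CBV 2 * 0.7 = 1.4 >= 1.2 everywhere
  les <- lesion_spec(cbv_scale = 0.7, cbf_scale = 0.7)
  s <- render_phantom(noiseless_spec(), les)
  expect_equal(s$truth$core_volume_ml, 0)
  expect_false(any(s$truth$core_mask))
})

test_that("vessel peak enhancement strictly dominates every tissue voxel", {
  s <- default_phantom()
  enh <- apply(s$image[1, , , ], c(2, 3), max) - s$meta$baseline_hu
  vessel <- s$truth$cbv == 100
  expect_true(min(enh[vessel[1, , ]]) > max(enh[!vessel[1, , ]]))
})

test_that("central volume identity holds exactly in the truth maps", {
  s <- default_phantom()
  inside <- s$truth$cbv > 0
  expect_equal(max(abs(60 * s$truth$cbv[inside] / s$truth$cbf[inside] -
                       s$truth$mtt[inside])), 0)
})

test_that("lesions outside the brain mask are rejected", {
  expect_error(render_phantom(noiseless_spec(),
                              lesion_spec(center = c(90, 90))),
               "outside")
})

test_that("noise injection is seeded, unbiased, and sized as requested", {
  s <- render_phantom(small_spec(), small_lesion())
  expect_identical(add_noise(s, 0, seed = 5)$image, s$image)
  n1 <- add_noise(s, 2, seed = 9)
  n2 <- add_noise(s, 2, seed = 9)
  expect_identical(n1$image, n2$image)
  expect_false(identical(n1$image, add_noise(s, 2, seed = 10)$image))
  s_big <- default_phantom()
  noisy <- add_noise(s_big, 2, seed = 1)
  resid <- noisy$image - s_big$image
  expect_lt(abs(sd(resid) - 2) / 2, 0.05)
  expect_lt(abs(mean(resid)), 0.05)
})

test_that("motion corruption is bounded, seeded, and leaves frame 0 alone", {
  s <- render_phantom(small_spec(), small_lesion())
  expect_identical(apply_motion(s, 0, seed = 1)$image, s$image)
  m1 <- apply_motion(s, 5, seed = 3)
  m2 <- apply_motion(s, 5, seed = 3)
  expect_identical(m1$image, m2$image)
  off <- m1$meta$motion_offsets
  expect_true(all(off[1, ] == 0))
  expect_true(all(abs(off) <= 5))
  expect_true(all(off == round(off)))
  expect_identical(m1$image[, 1, , ], s$image[, 1, , ])
})

test_that("simulated cohorts are deterministic and labeled by the median split", {
  spec <- small_spec(noise_sigma = 0.5)
  co1 <- simulate_cohort(6, spec, lesion_law_uniform(), seed = 21)
  co2 <- simulate_cohort(6, spec, lesion_law_uniform(), seed = 21)
  expect_identical(co1, co2)
  vols <- cohort_core_volumes(co1)
  expect_equal(co1$threshold_ml, median(vols))
  expect_identical(cohort_labels(co1), dichotomize(vols, co1$threshold_ml))
  # even n, continuous law: exact balance
  expect_equal(unname(table(cohort_labels(co1))["large"]), 3)
  expect_false(any(duplicated(cohort_ids(co1))))
})

test_that("separated lesion law yields two well-separated volume modes", {
  spec <- small_spec()
  co <- simulate_cohort(12, spec, lesion_law_separated(), seed = 2)
  v <- sort(cohort_core_volumes(co))
  cut <- which.max(diff(v))          # split the two size modes at the gap
  expect_gt(v[cut + 1], 3 * v[cut])
  expect_equal(sum(cohort_labels(co) == "large"), 6)
})

test_that("cohort containers round-trip through the on-disk format", {
  co <- simulate_cohort(3, small_spec(), seed = 4)
  path <- tempfile(fileext = ".rds")
  write_cohort(co, path)
  expect_identical(read_cohort(path), co)
  unlink(path)
})
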