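test_that("concentration conversion inverts the forward HU model", {
  s <- default_phantom()
  sc <- signal_to_concentration(s)
  # gray-matter voxel: recovered curve equals the simulator's tissue curve
  gm <- which(s$truth$cbf == 60 & s$truth$brain_mask, arr.ind = TRUE)[1, ]
  expected <- tissue_curve(aif_model(), tissue_kinetics(60, 4), s$time_grid)
  expect_equal(sc$conc[gm[1], , gm[2], gm[3]], expected, tolerance = 1e-10)
  # constant-in-time (background) voxel -> all-zero concentration
  bg <- which(!s$truth$brain_mask, arr.ind = TRUE)[1, ]
  expect_equal(max(abs(sc$conc[bg[1], , bg[2], bg[3]])), 0)
  expect_error(signal_to_concentration(s, deconv_config(baseline_frames = 32)),
               "baseline_frames")
})

test_that("AIF selection finds the arterial voxel deterministically", {
  s <- default_phantom()
  sc <- signal_to_concentration(s)
  sel <- select_aif(sc$conc, sc$brain_mask)
  expect_equal(s$truth$cbv[sel$index[1], sel$index[2], sel$index[3]], 100)
  expect_equal(max(sel$curve), 1, tolerance = 1e-9)
  # single-voxel mask returns that voxel's curve
  one <- array(FALSE, dim = dim(sc$brain_mask))
  one[1, 40, 40] <- TRUE
  expect_equal(select_aif(sc$conc, one)$curve, sc$conc[1, , 40, 40])
  # identical candidates: lowest (row, col) wins
  conc <- array(0, dim = c(1, 4, 3, 3))
  conc[1, , 2, 3] <- c(0, 1, 2, 1)
  conc[1, , 3, 2] <- c(0, 1, 2, 1)
  sel2 <- select_aif(conc, array(TRUE, dim = c(1, 3, 3)))
  expect_equal(unname(sel2$index), c(1, 2, 3))
  expect_error(select_aif(conc, array(FALSE, dim = c(1, 3, 3))), "empty")
})

test_that("deconvolving a curve by itself gives CBV 100 and unit-area residue", {
  t <- seq(0, 46.5, by = 1.5)
  aif <- eval_aif(aif_model(), t)
  conc <- aperm(array(aif, dim = c(32, 1, 1, 1)), c(2, 1, 3, 4))
  maps <- deconvolve(conc, aif, t, deconv_config())
  expect_equal(maps$cbv[1, 1, 1], 100, tolerance = 1e-6)
  k <- maps$k[1, , 1, 1]
  expect_equal(sum(k * 1.5) - 1.5 * (k[1] + k[32]) / 2, 1, tolerance = 0.02)
  expect_error(deconvolve(conc, aif * 0, t, deconv_config()), "AIF")
})

test_that("deconvolution is linear: doubling the signal doubles CBF and CBV", {
  s <- default_phantom()
  sc <- signal_to_concentration(s)
  aif <- select_aif(sc$conc, sc$brain_mask)
  m1 <- deconvolve(sc$conc, aif$curve, s$time_grid, mask = sc$brain_mask)
  m2 <- deconvolve(2 * sc$conc, aif$curve, s$time_grid, mask = sc$brain_mask)
  msk <- sc$brain_mask
  expect_equal(m2$cbf[msk], 2 * m1$cbf[msk], tolerance = 1e-9)
  expect_equal(m2$cbv[msk], 2 * m1$cbv[msk], tolerance = 1e-9)
  expect_equal(m2$mtt[msk], m1$mtt[msk], tolerance = 1e-9)
})

test_that("noiseless phantom parameters are recovered within tolerance", {
  s <- default_phantom()
  pa <- perfusion_analysis(s)
  tr <- s$truth
  gmwm <- tr$brain_mask & tr$cbv > 0 & tr$cbv < 100
  rel_cbv <- abs(pa$maps$cbv[gmwm] - tr$cbv[gmwm]) / tr$cbv[gmwm]
  rel_cbf <- abs(pa$maps$cbf[gmwm] - tr$cbf[gmwm]) / tr$cbf[gmwm]
  expect_lt(max(rel_cbv), 0.02)
  expect_lt(max(rel_cbf), 0.10)
  # MTT satisfies the central volume identity wherever CBF > 0
  expect_equal(pa$maps$mtt[gmwm], 60 * pa$maps$cbv[gmwm] / pa$maps$cbf[gmwm])
  # core volumetry agrees exactly with the simulator truth
  expect_identical(pa$core_mask, tr$core_mask)
  expect_identical(pa$volume_ml, tr$core_volume_ml)
})

test_that("TTP reflects delayed, dispersed tissue arrival", {
  s <- default_phantom()
  pa <- perfusion_analysis(s)
  vessel <- s$truth$cbv == 100
  gm <- s$truth$cbf == 60
  expect_true(all(pa$maps$ttp[gm] > mean(pa$maps$ttp[vessel])))
})

test_that("core mask grows monotonically with the CBV threshold", {
  s <- default_phantom()
  pa <- perfusion_analysis(s)
  prev <- 0
  for (thr in c(0, 0.5, 1.2, 2.5, 5)) {
    n <- sum(core_from_cbv(pa$maps, thr))
    expect_gte(n, prev)
    prev <- n
  }
  expect_equal(sum(core_from_cbv(pa$maps, 0)), 0)
})

test_that("healthy phantom has an empty core", {
  s <- render_phantom(small_spec(), lesion = NULL)
  pa <- perfusion_analysis(s)
  expect_false(any(pa$core_mask))
  expect_equal(pa$volume_ml, 0)
})

test_that("volume_ml is voxel count times voxel volume", {
  expect_equal(volume_ml(array(FALSE, c(2, 4, 4)), c(1, 1, 10)), 0)
  m <- array(FALSE, c(1, 40, 25))
  m[1, , ] <- TRUE
  expect_equal(volume_ml(m, c(1, 1, 10)), 10)
})

test_that("median threshold and dichotomization follow the strict/tie rules", {
  expect_equal(median_core_volume(c(10, 30, 50)), 30)
  expect_identical(dichotomize(10, 30), "small")
  expect_identical(dichotomize(50, 30), "large")
  expect_identical(dichotomize(30, 30), "large")   # tie rule
  expect_error(median_core_volume(numeric(0)), "empty")
  # continuous even-n cohort: exact class balance
  v <- runif(20, 1, 60)
  labs <- dichotomize(v, median_core_volume(v))
  expect_equal(sum(labs == "large"), 10)
})

test_that("cohort labeling is deterministic and median-balanced", {
  co <- simulate_cohort(4, small_spec(), seed = 31)
  lab1 <- label_cohort(co)
  lab2 <- label_cohort(co)
  expect_identical(lab1, lab2)
  expect_equal(sum(lab1$label == "large"), 2)
  # estimated volumes match the simulator truth exactly on noiseless data
  expect_equal(lab1$volume_ml, cohort_core_volumes(co))
})
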