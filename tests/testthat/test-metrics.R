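test_that("SNR, CNR and conspicuity reproduce their closed forms", {
  f <- closed_form_fixture()
  expect_equal(snr(f$v, f$lesion, f$noise), 10, tolerance = 1e-12)
  expect_equal(cnr(f$v, f$lesion, f$nawm, f$noise), 2, tolerance = 1e-12)
  expect_equal(conspicuity(f$v, f$lesion, f$nawm), 20 / 180, tolerance = 1e-12)

  # equal means: CNR 0, conspicuity 0; CNR symmetric under mask swap
  v2 <- f$v; v2[f$nawm] <- 100
  expect_equal(cnr(v2, f$lesion, f$nawm, f$noise), 0)
  expect_equal(conspicuity(v2, f$lesion, f$nawm), 0)
  expect_equal(cnr(f$v, f$nawm, f$lesion, f$noise),
               cnr(f$v, f$lesion, f$nawm, f$noise))
})

test_that("intensity metrics are invariant to global positive scaling", {
  f <- closed_form_fixture()
  for (a in c(0.2, 3, 117)) {
    expect_equal(snr(a * f$v, f$lesion, f$noise), 10, tolerance = 1e-10)
    expect_equal(cnr(a * f$v, f$lesion, f$nawm, f$noise), 2, tolerance = 1e-10)
    expect_equal(conspicuity(a * f$v, f$lesion, f$nawm), 1 / 9,
                 tolerance = 1e-10)
  }
})

test_that("SNR recovers a known signal/noise ratio in Monte Carlo", {
  dims <- c(30, 30, 30)
  v <- array(0, dims)
  signal <- noise <- array(FALSE, dims)
  signal[1:10, , ] <- TRUE
  noise[21:30, , 15:25] <- TRUE  # ~10^4 voxels
  withr::with_seed(99, {
    v[signal] <- 50
    v[noise] <- rnorm(sum(noise), mean = 0, sd = 5)
  })
  expect_equal(snr(v, signal, noise), 10, tolerance = 0.03)
})

test_that("metric preconditions are enforced", {
  f <- closed_form_fixture()
  empty <- array(FALSE, c(6, 6, 6))
  expect_error(snr(f$v, empty, f$noise), "no voxels")
  flat <- f$v; flat[f$noise] <- 1
  expect_error(snr(flat, f$lesion, f$noise), "zero variance")
  expect_error(conspicuity(array(0, c(6, 6, 6)), f$lesion, f$nawm), "zero")
})

test_that("lesion splitting matches a BFS flood-fill oracle", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:3, 2:3, 2:3] <- TRUE           # cube A
  m[7:8, 7:8, 7:8] <- TRUE           # cube B, separated
  lab <- split_lesions(m)
  expect_identical(sort(unique(as.vector(lab[m]))), c(1L, 2L))
  expect_identical(sum(lab == 1), 8L)
  expect_identical(sum(lab == 2), 8L)
  expect_identical(lab, flood_fill_26(m))

  # corner contact joins under 26-connectivity
  m2 <- array(FALSE, c(6, 6, 6))
  m2[1:2, 1:2, 1:2] <- TRUE
  m2[3, 3, 3] <- TRUE
  expect_identical(max(split_lesions(m2)), 1L)
  expect_identical(split_lesions(m2), flood_fill_26(m2))

  # empty mask: no labels; random blob parity with the oracle
  expect_identical(max(split_lesions(array(FALSE, c(4, 4, 4)))), 0L)
  withr::with_seed(4, {
    m3 <- array(runif(12^3) < 0.2, c(12, 12, 12))
  })
  expect_identical(split_lesions(m3), flood_fill_26(m3))
  expect_error(split_lesions(array(2, c(4, 4, 4))), "binary")
})

test_that("Laplacian sharpness matches a direct stencil and kills ramps", {
  expect_equal(laplacian_sharpness(array(5, c(5, 5, 5))), 0)

  ramp <- array(0, c(7, 7, 7))
  for (i in 1:7) ramp[i, , ] <- i
  interior <- array(FALSE, c(7, 7, 7)); interior[2:6, 2:6, 2:6] <- TRUE
  expect_equal(laplacian_sharpness(ramp, interior), 0)

  v <- withr::with_seed(23, array(rnorm(125), c(5, 5, 5)))
  lap <- laplacian_direct(v)
  expect_equal(laplacian_sharpness(v), sd(as.vector(lap)), tolerance = 1e-12)
  roi <- array(FALSE, c(5, 5, 5)); roi[2:4, 2:4, 2:4] <- TRUE
  expect_equal(laplacian_sharpness(v, roi), sd(lap[roi]), tolerance = 1e-12)
})

test_that("per-lesion sharpness composes dilation with the global measure", {
  v <- withr::with_seed(31, array(rnorm(10^3, 10, 1), c(10, 10, 10)))
  m <- array(FALSE, c(10, 10, 10)); m[4:5, 4:5, 4:5] <- TRUE
  labs <- split_lesions(m)
  out <- lesion_sharpness(v, labs, dilation_voxels = 1)
  expect_identical(nrow(out), 1L)
  expect_identical(out$voxel_count, 8L)
  expect_equal(out$log_sharpness,
               log(laplacian_sharpness(v, dilate_mask(m, 1))),
               tolerance = 1e-12)

  # dilation 0 scores the lesion voxels themselves
  out0 <- lesion_sharpness(v, labs, dilation_voxels = 0)
  expect_equal(out0$log_sharpness, log(laplacian_sharpness(v, m)),
               tolerance = 1e-12)

  # edge-free lesion in a constant background: NA, not an error
  flat <- array(1, c(10, 10, 10))
  expect_true(is.na(lesion_sharpness(flat, labs)$log_sharpness))
})

test_that("dilation grows by the full 26-neighbourhood", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  d <- dilate_mask(m, 1)
  expect_identical(sum(d), 27L)
  expect_true(d[2, 2, 2] && d[4, 4, 4])
  expect_identical(dilate_mask(m, 0), m)
})

test_that("noise degrades SNR and CNR monotonically", {
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 40), n_lesions = 3, seed = 12))
  vals <- vapply(c(0.01, 0.05, 0.15), function(sig) {
    scan <- simulate_acquisition(ph$truth,
                                 acquisition_sim(geom_ax(), sig, seed = 77))
    c(snr(scan, ph$rois$lesion_mask, ph$rois$noise_mask),
      cnr(scan, ph$rois$lesion_mask, ph$rois$nawm_mask, ph$rois$noise_mask))
  }, numeric(2))
  expect_true(all(diff(vals[1, ]) < 0))
  expect_true(all(diff(vals[2, ]) < 0))
})

test_that("quality reports assemble all metrics with tidy/glance accessors", {
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 40), n_lesions = 3, seed = 12))
  scan <- simulate_acquisition(ph$truth,
                               acquisition_sim(geom_ax(), 0.02, seed = 5))
  rep <- quality_report(scan, ph$rois, method_name = "sim")
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_true(all(is.finite(c(g$snr, g$cnr, g$conspicuity, g$image_sharpness))))
  expect_gte(g$conspicuity, -1); expect_lte(g$conspicuity, 1)
  t <- tidy(rep)
  expect_identical(nrow(t), 3L)
  expect_identical(g$n_lesions, 3L)
})
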