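test_that("forward spectrum matches the direct triple-sum DFT after centring", {
  for (shape in list(c(4, 4, 4), c(3, 4, 5))) {
    v <- rand_vol(shape, seed = sum(shape))
    S <- forward_spectrum(v)$data
    S_direct <- center_spectrum_direct(dft3_direct(v$data))
    expect_lt(max(abs(S - S_direct)), 1e-9)
  }
})

test_that("inverse spectrum matches the direct inverse DFT and round-trips", {
  v <- rand_vol(c(4, 4, 4), seed = 7)
  S <- forward_spectrum(v)
  # direct inverse of the direct forward transform (uncentred domain)
  back_direct <- Mod(dft3_direct(dft3_direct(v$data), inverse = TRUE))
  expect_lt(max(abs(inverse_spectrum(S)$data - back_direct)), 1e-9)
  expect_lt(max(abs(inverse_spectrum(S)$data - v$data)), 1e-9)

  # spectrum of zeros inverts to zeros
  z <- forward_spectrum(volume(array(0, c(4, 4, 4)) + 0))
  z$data[] <- 0 + 0i
  expect_true(all(inverse_spectrum(z)$data == 0))
})

test_that("a constant volume has a DC-only centered spectrum", {
  n <- 6
  v <- volume(array(3.5, c(n, n, n)))
  S <- forward_spectrum(v)$data
  centre <- n %/% 2 + 1
  expect_equal(Mod(S[centre, centre, centre]), 3.5 * n^3, tolerance = 1e-9)
  S[centre, centre, centre] <- 0
  expect_lt(max(Mod(S)), 1e-9)
})

test_that("real inputs give Hermitian-symmetric centered spectra", {
  v <- rand_vol(c(5, 5, 5), seed = 13)  # odd extents: every index has a mirror
  S <- forward_spectrum(v)$data
  c0 <- 5 %/% 2 + 1
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    mi <- 2 * c0 - i; mj <- 2 * c0 - j; mk <- 2 * c0 - k
    expect_lt(Mod(S[i, j, k] - Conj(S[mi, mj, mk])), 1e-8)
  }
})

test_that("spectral energy obeys Parseval against the image domain", {
  v <- rand_vol(c(8, 6, 10), seed = 17)
  S <- forward_spectrum(v)$data
  expect_equal(sum(Mod(S)^2), prod(dim(v$data)) * sum(v$data^2),
               tolerance = 1e-10)
})

test_that("band-count arithmetic follows the slice/in-plane ratio", {
  expect_equal(compute_band_count(5.0, 1.7, 160), list(factor = 2.94, n_lines = 54L))
  expect_equal(compute_band_count(5.0, 5.0, 160), list(factor = 1, n_lines = 160L))
  expect_equal(compute_band_count(3.4, 1.7, 128), list(factor = 2, n_lines = 64L))
  expect_error(compute_band_count(1.0, 1.7, 128), ">=")
  expect_error(compute_band_count(-5, -1, 128), ">=")
})

test_that("fusion plans resolve axis and width from the donor geometry", {
  plan <- make_fusion_plan(geom_cor(), geom_ax(), c(160, 160, 160),
                           band_width = 64)
  expect_identical(plan$replacement_axis, 3L)
  expect_identical(plan$band_width, 64L)

  auto <- make_fusion_plan(geom_cor(), geom_ax(), c(160, 160, 160))
  expect_identical(auto$band_width, 54L)

  # degenerate but legal: full-axis replacement
  full <- make_fusion_plan(geom_cor(), geom_ax(), c(16, 16, 16), band_width = 16)
  expect_identical(full$band_width, 16L)

  expect_error(make_fusion_plan(geom_cor(), geom_cor(), c(16, 16, 16)),
               "not orthogonal")
  expect_error(make_fusion_plan(geom_cor(), geom_ax(), c(16, 16, 16),
                                band_width = 17), "exceeds")
})

test_that("the fused spectrum equals the independent mask-splice oracle", {
  base <- rand_vol(c(8, 8, 8), seed = 31)
  donor <- rand_vol(c(8, 8, 8), seed = 32)
  S_b <- forward_spectrum(base)$data
  S_d <- forward_spectrum(donor)$data
  for (w in c(1, 3, 8)) {
    plan <- make_fusion_plan(geom_cor(), geom_ax(), c(8, 8, 8), band_width = w)
    got <- splice_spectra(forward_spectrum(base), forward_spectrum(donor), plan)
    M <- band_mask_direct(c(8, 8, 8), axis = 3, w = w)
    expect_identical(got$data, M * S_d + (1 - M) * S_b)
  }
})

test_that("fusing a volume with itself or a full band degenerates correctly", {
  v <- rand_vol(c(8, 8, 8), seed = 41)
  d <- rand_vol(c(8, 8, 8), seed = 42)
  plan <- make_fusion_plan(geom_cor(), geom_ax(), c(8, 8, 8), band_width = 4)
  expect_equal(fuse_volumes(v, v, plan)$data, v$data, tolerance = 1e-10)
  full <- make_fusion_plan(geom_cor(), geom_ax(), c(8, 8, 8), band_width = 8)
  expect_equal(fuse_volumes(v, d, full)$data, d$data, tolerance = 1e-10)
})

test_that("the splice is idempotent and positively linear", {
  base <- rand_vol(c(8, 8, 8), seed = 51)
  donor <- rand_vol(c(8, 8, 8), seed = 52)
  plan <- make_fusion_plan(geom_cor(), geom_ax(), c(8, 8, 8), band_width = 4)
  # splicing an already-spliced spectrum changes nothing: the band is the
  # donor's and the off-band part is the first splice's
  s1 <- splice_spectra(forward_spectrum(base), forward_spectrum(donor), plan)
  s2 <- splice_spectra(s1, forward_spectrum(donor), plan)
  expect_identical(s2$data, s1$data)

  # re-fusing co-registered simulated scans reproduces the first fusion up
  # to the magnitude-step residue, which must stay small
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 32), n_lesions = 2, seed = 6))
  sims <- simulate_orthogonal_pair(ph$truth,
                                   acquisition_sim(geom_cor(), 0),
                                   acquisition_sim(geom_ax(), 0))
  plan32 <- make_fusion_plan(geom_cor(), geom_ax(), rep(32L, 3))
  f1 <- fuse_volumes(sims$a, sims$b, plan32)
  f2 <- fuse_volumes(f1, sims$b, plan32)
  # the only change comes from re-rectifying ringing lobes at the magnitude
  # step; bounded at a few percent RMS on a coarse, sharp-edged phantom
  expect_lt(sqrt(mean((f2$data - f1$data)^2)), 0.05 * sqrt(mean(f1$data^2)))

  a <- 2.75
  f_rand <- fuse_volumes(base, donor, plan)
  sb <- base; sb$data <- a * base$data
  sd_ <- donor; sd_$data <- a * donor$data
  expect_equal(fuse_volumes(sb, sd_, plan)$data, a * f_rand$data,
               tolerance = 1e-9)
})

test_that("fusion rejects mismatched grids and spacings", {
  a <- rand_vol(c(8, 8, 8)); b <- rand_vol(c(8, 8, 6))
  plan <- make_fusion_plan(geom_cor(), geom_ax(), c(8, 8, 8), band_width = 4)
  expect_error(fuse_volumes(a, b, plan), "grids differ")
  b2 <- rand_vol(c(8, 8, 8)); b2$spacing <- c(1, 1, 2)
  expect_error(fuse_volumes(a, b2, plan), "spacings differ")
})

test_that("noiseless fusion recovers the union of measured k-space", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 32), n_lesions = 2, seed = 6))
  sims <- simulate_orthogonal_pair(ph$truth,
                                   acquisition_sim(geom_cor(), 0),
                                   acquisition_sim(geom_ax(), 0))
  plan <- make_fusion_plan(geom_cor(), geom_ax(), rep(32L, 3))
  S_f <- splice_spectra(forward_spectrum(sims$a), forward_spectrum(sims$b),
                        plan)$data
  S_t <- forward_spectrum(ph$truth)$data
  w <- compute_band_count(5, 1.7, 32)$n_lines
  M_cor <- band_mask_direct(rep(32L, 3), axis = 2, w = w)  # base measured
  M_ax <- band_mask_direct(rep(32L, 3), axis = 3, w = w)   # donor measured
  union <- pmax(M_cor * (1 - M_ax), M_ax) > 0  # donor band + base off-band
  expect_lt(max(Mod(S_f[union] - S_t[union])), 1e-6 * max(Mod(S_t)))
})

test_that("the band sweep peaks at the width the donor truly measured", {
  ph <- make_phantom(phantom_spec(shape = c(48, 48, 48), seed = 8))
  sims <- simulate_orthogonal_pair(ph$truth,
                                   acquisition_sim(geom_cor(), 0),
                                   acquisition_sim(geom_ax(), 0))
  w_true <- compute_band_count(5, 1.7, 48)$n_lines
  widths <- (w_true - 6):(w_true + 6)
  sw <- band_sweep(sims$a, sims$b, geom_cor(), geom_ax(), widths)
  expect_identical(nrow(sw), length(widths))
  expect_true(all(is.finite(sw$score)))
  # the RMSE-optimal width is the donor's true sampling width; the
  # sharpness maximizer must land within 2 planes of it
  expect_lte(abs(attr(sw, "optimum") - w_true), 2)
  # full-axis width reduces the fusion to the donor (as a magnitude image)
  sw_full <- band_sweep(sims$a, sims$b, geom_cor(), geom_ax(), 48)
  expect_equal(sw_full$score, laplacian_sharpness(abs(sims$b$data)),
               tolerance = 1e-8)
})
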