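# Digital phantom and acquisition simulator. A piecewise-constant head-like
# phantom (ellipsoidal tissue, spherical FLAIR-hyperintense lesions, bar
# inserts at several spatial scales) is imaged by ideal k-space truncation
# along the slice axis plus complex Gaussian noise before the magnitude
# (Rician statistics), so fusion and metrics can be exercised end to end
# with known ground truth.

#' Specify a digital phantom
#'
#' Defaults describe the study conditions used throughout the package: a
#' 96 voxel cube at 1.7 mm isotropic, air background 0, white-matter-like
#' tissue 1, FLAIR-hyperintense lesions at 1.6, eight lesions of 4--8 mm
#' radius, and bar inserts at three spatial scales.
#'
#' @param shape integer length-3 grid extents.
#' @param voxel_mm isotropic voxel size of the ground-truth grid, in mm.
#' @param background_level,tissue_level,lesion_level piecewise intensities;
#'   `tissue_level` must differ from `lesion_level`.
#' @param n_lesions number of spherical lesions (>= 0).
#' @param lesion_radius_range_mm length-2 range of lesion radii in mm.
#' @param seed integer RNG seed; identical specs give identical phantoms.
#' @return A `fousr_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), voxel_mm = 1.7,
                         background_level = 0, tissue_level = 1,
                         lesion_level = 1.6, n_lesions = 8,
                         lesion_radius_range_mm = c(4, 8), seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), voxel_mm > 0)
  if (any(c(background_level, tissue_level, lesion_level) < 0))
    stopf("intensities must be nonnegative")
  if (tissue_level == lesion_level)
    stopf("tissue_level must differ from lesion_level, else lesions are invisible")
  n_lesions <- as.integer(n_lesions)
  stopifnot(n_lesions >= 0L, length(lesion_radius_range_mm) == 2L,
            all(lesion_radius_range_mm > 0),
            lesion_radius_range_mm[1] <= lesion_radius_range_mm[2])
  structure(list(shape = shape, voxel_mm = voxel_mm,
                 background_level = background_level,
                 tissue_level = tissue_level, lesion_level = lesion_level,
                 n_lesions = n_lesions,
                 lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
                 seed = as.integer(seed)),
            class = "fousr_phantom_spec")
}

#' Region-of-interest set for quality evaluation
#'
#' Bundles the lesion, NAWM and background-noise masks (plus per-lesion
#' cluster labels) that the quality metrics consume. Masks must share one
#' grid; lesion and NAWM masks must be disjoint.
#'
#' @param lesion_mask,nawm_mask,noise_mask binary 3D arrays on one grid.
#' @param lesion_labels optional integer label array; computed with
#'   [split_lesions()] when omitted and the lesion mask is nonempty.
#' @return A `fousr_roi_set`.
#' @export
roi_set <- function(lesion_mask, nawm_mask, noise_mask, lesion_labels = NULL) {
  lesion_mask <- as_mask(lesion_mask, "lesion_mask")
  nawm_mask <- as_mask(nawm_mask, "nawm_mask")
  noise_mask <- as_mask(noise_mask, "noise_mask")
  if (!identical(dim(lesion_mask), dim(nawm_mask)) ||
      !identical(dim(lesion_mask), dim(noise_mask)))
    stopf("all masks must share one grid")
  if (any(lesion_mask & nawm_mask))
    stopf("lesion and NAWM masks overlap; NAWM must exclude lesions")
  if (is.null(lesion_labels)) {
    lesion_labels <- if (any(lesion_mask)) split_lesions(lesion_mask)
                     else array(0L, dim(lesion_mask))
  } else {
    lesion_labels <- as_vol_array(lesion_labels, "lesion_labels")
    if (!identical(dim(lesion_labels), dim(lesion_mask)))
      stopf("lesion_labels grid differs from the masks")
    if (any(lesion_labels > 0 & !lesion_mask))
      stopf("positive lesion labels must lie inside lesion_mask")
  }
  structure(list(lesion_mask = lesion_mask, nawm_mask = nawm_mask,
                 noise_mask = noise_mask,
                 lesion_labels = lesion_labels),
            class = "fousr_roi_set")
}

#' Generate a ground-truth phantom and its ROI set
#'
#' Builds a piecewise-constant volume: an ellipsoid of tissue in a uniform
#' background, bar inserts at three spatial scales in the lower half
#' (emulating a resolution insert), and non-overlapping spherical lesions
#' in the upper half. The returned ROI set carries the exact lesion mask
#' and labels, the NAWM mask (tissue minus lesions and inserts), and a
#' background-noise mask far outside the tissue.
#'
#' @param spec a [phantom_spec()].
#' @return List with `truth` (a [volume()]), `rois` (a [roi_set()]), and
#'   `lesions`, a tibble of the placed lesion centres and radii in mm.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "fousr_phantom_spec"))
  dm <- spec$shape
  ext <- dm * spec$voxel_mm
  ctr <- ext / 2
  # normalized ellipsoid radius of every voxel centre (head-like semi-axes)
  semi <- c(0.40, 0.46, 0.42) * ext
  cx <- (seq_len(dm[1]) - 0.5) * spec$voxel_mm - ctr[1]
  cy <- (seq_len(dm[2]) - 0.5) * spec$voxel_mm - ctr[2]
  cz <- (seq_len(dm[3]) - 0.5) * spec$voxel_mm - ctr[3]
  rx2 <- (cx / semi[1])^2; ry2 <- (cy / semi[2])^2; rz2 <- (cz / semi[3])^2
  rnorm2 <- outer(outer(rx2, ry2, `+`), rz2, `+`)
  tissue <- rnorm2 <= 1
  truth <- array(spec$background_level, dm)
  truth[tissue] <- spec$tissue_level

  # bar inserts: three groups of parallel slabs, bar width 1/2/3 voxels,
  # confined to the lower-z half of the tissue
  bar_level <- 0.5 * spec$tissue_level
  zmask <- cz / (0.5 * ext[3])          # normalized z in [-1, 1]
  bars <- array(FALSE, dm)
  xvox <- seq_len(dm[1])
  for (g in 1:3) {
    period <- 2L * g                     # bars of width g, gaps of width g
    stripe <- ((xvox - 1L) %/% g) %% 2L == 0L
    zlo <- -0.55 + (g - 1) * 0.15; zhi <- zlo + 0.10
    zsel <- zmask >= zlo & zmask < zhi
    sel <- outer(outer(stripe, rep(TRUE, dm[2]), `&`), zsel, `&`)
    bars <- bars | (sel & tissue & rnorm2 <= 0.8)
  }
  truth[bars] <- bar_level

  # spherical lesions in the upper-z half: fully inside the tissue, clear of
  # the bar inserts, and separated from each other by >= 2 voxels so the
  # 26-connectivity cluster count always equals n_lesions
  lesion <- array(FALSE, dm)
  lesion_log <- list()
  sep_mm <- 2 * spec$voxel_mm
  withr::with_seed(spec$seed, {
    placed <- 0L
    tries <- 0L
    max_tries <- 500L * max(spec$n_lesions, 1L)
    while (placed < spec$n_lesions) {
      tries <- tries + 1L
      if (tries > max_tries)
        stopf("could not place %d non-overlapping lesions after %d tries",
              spec$n_lesions, max_tries)
      r_mm <- runif(1, spec$lesion_radius_range_mm[1],
                    spec$lesion_radius_range_mm[2])
      cen <- c(runif(1, -0.45, 0.45), runif(1, -0.45, 0.45), runif(1, 0.1, 0.5))
      cen_mm <- cen * ext / 2
      # require the whole sphere inside the tissue ellipsoid with margin
      pad <- r_mm / min(semi)
      if (sum((cen_mm / semi)^2) > max(0.82 - pad, 0)^2) next
      if (placed > 0L) {
        prior <- do.call(rbind, lesion_log)
        gaps <- sqrt(colSums((t(prior[, 1:3, drop = FALSE]) -
                              (cen_mm + ctr))^2)) - prior[, 4] - r_mm
        if (any(gaps < sep_mm)) next
      }
      d2 <- outer(outer((cx - cen_mm[1])^2, (cy - cen_mm[2])^2, `+`),
                  (cz - cen_mm[3])^2, `+`)
      sph <- d2 <= r_mm^2
      if (!any(sph)) next
      if (any(sph & bars)) next
      lesion <- lesion | sph
      placed <- placed + 1L
      lesion_log[[placed]] <- c(cen_mm + ctr, r_mm)
    }
  })
  truth[lesion] <- spec$lesion_level

  noise_mask <- rnorm2 > 1.35^2
  rois <- roi_set(lesion_mask = lesion,
                  nawm_mask = tissue & !lesion & !bars,
                  noise_mask = noise_mask)
  lesions <- if (length(lesion_log) > 0) {
    m <- do.call(rbind, lesion_log)
    tibble::tibble(lesion_id = seq_len(nrow(m)), x_mm = m[, 1], y_mm = m[, 2],
                   z_mm = m[, 3], radius_mm = m[, 4])
  } else {
    tibble::tibble(lesion_id = integer(), x_mm = numeric(), y_mm = numeric(),
                   z_mm = numeric(), radius_mm = numeric())
  }
  list(truth = volume(truth, spacing = rep(spec$voxel_mm, 3), name = "phantom-truth"),
       rois = rois, lesions = lesions)
}

#' Specify one simulated anisotropic acquisition
#'
#' @param geometry an [acquisition_geometry()].
#' @param noise_sigma standard deviation of the complex Gaussian noise added
#'   to the real and imaginary channels before the magnitude (>= 0), in the
#'   intensity units of the ground truth.
#' @param seed integer RNG seed for the noise draw, or `NULL`.
#' @return A `fousr_acquisition_sim`.
#' @export
acquisition_sim <- function(geometry, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(geometry, "fousr_geometry"))
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stopf("noise_sigma must be >= 0")
  structure(list(geometry = geometry, noise_sigma = as.numeric(noise_sigma),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "fousr_acquisition_sim")
}

#' Simulate a thick-slice acquisition from a ground-truth volume
#'
#' Models the anisotropic acquisition as ideal k-space truncation: the
#' centered spectrum of the truth is kept only on the central band of
#' `round(extent * in_plane_mm / slice_mm)` planes along the slice axis and
#' zeroed elsewhere, then inverted. Complex Gaussian noise of standard
#' deviation `sim$noise_sigma` is added to the real and imaginary channels
#' before taking the magnitude, giving Rician noise in the image (Rayleigh
#' in signal-free background). A noiseless simulation returns the signed
#' real image instead of its magnitude, so that the truncation is exact in
#' k-space (the small negative ringing lobes are kept, not rectified).
#'
#' @param truth a [volume()] at isotropic resolution no coarser than the
#'   in-plane resolution of the simulated scan.
#' @param sim an [acquisition_sim()].
#' @param name provenance tag.
#' @return A simulated [volume()] on the truth's grid.
#' @export
simulate_acquisition <- function(truth, sim, name = "simulated-scan") {
  stopifnot(inherits(truth, "fousr_volume"), inherits(sim, "fousr_acquisition_sim"))
  g <- sim$geometry
  if (max(truth$spacing) > g$in_plane_mm + 1e-9)
    stopf("ground truth (%.3g mm) is coarser than the simulated in-plane resolution (%.3g mm)",
          max(truth$spacing), g$in_plane_mm)
  dm <- dim(truth$data)
  ax <- g$slice_axis
  w <- as.integer(round_half_away(dm[ax] * g$in_plane_mm / g$slice_mm))
  w <- max(1L, min(w, dm[ax]))
  s <- forward_spectrum(truth)
  keep <- band_indices(dm[ax], w)
  ii <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  ii[[ax]] <- setdiff(seq_len(dm[ax]), keep)
  if (length(ii[[ax]]) > 0)
    s$data[ii[[1]], ii[[2]], ii[[3]]] <- 0 + 0i
  img <- fft(ifftshift3(s$data), inverse = TRUE) / length(s$data)
  data <- if (sim$noise_sigma > 0) {
    img <- with_seed_opt(sim$seed, {
      n <- length(img)
      img + complex(real = rnorm(n, 0, sim$noise_sigma),
                    imaginary = rnorm(n, 0, sim$noise_sigma))
    })
    Mod(img)
  } else {
    Re(img)
  }
  volume(data, spacing = truth$spacing, axis_labels = truth$axis_labels,
         name = name)
}

#' Simulate a co-registered orthogonal scan pair
#'
#' Runs [simulate_acquisition()] twice on the same ground truth with
#' geometries whose slice axes differ, producing a perfectly co-registered
#' pair on one grid (registration is an external precondition of fusion).
#'
#' @param truth a [volume()].
#' @param sim_a,sim_b [acquisition_sim()]s with different slice axes.
#' @return Named list with volumes `a` and `b`.
#' @export
simulate_orthogonal_pair <- function(truth, sim_a, sim_b) {
  stopifnot(inherits(sim_a, "fousr_acquisition_sim"),
            inherits(sim_b, "fousr_acquisition_sim"))
  if (sim_a$geometry$slice_axis == sim_b$geometry$slice_axis)
    stopf("the two simulated scans share a slice axis; acquisitions must be orthogonal")
  list(a = simulate_acquisition(truth, sim_a, name = "sim-scan-a"),
       b = simulate_acquisition(truth, sim_b, name = "sim-scan-b"))
}

#' Noise level giving a target single-scan SNR
#'
#' Closed-form helper: in signal-free background the magnitude noise is
#' Rayleigh with standard deviation `sigma * sqrt(2 - pi/2)`, so a scan
#' whose lesion mean is `signal_level` reaches `SNR = target` when
#' `sigma = signal_level / (target * sqrt(2 - pi/2))`.
#'
#' @param target_snr desired mean-lesion-signal to noise-sd ratio.
#' @param signal_level mean lesion intensity of the noiseless scan.
#' @return Complex-channel noise standard deviation.
#' @export
noise_sigma_for_snr <- function(target_snr, signal_level = 1.6) {
  stopifnot(target_snr > 0, signal_level > 0)
  signal_level / (target_snr * sqrt(2 - pi / 2))
}
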