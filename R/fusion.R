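# Spectrum fusion: both scans are transformed to centered k-space, an inner
# band of spectral planes along the donor's slice axis is taken from the
# donor, everything else from the base, and the splice is inverted back to
# image space. Each scan thereby contributes exactly the k-space region its
# acquisition genuinely measured.

# circularly shift so the zero-frequency coefficient sits at floor(N/2)
# (0-based) on each axis, and back.
fftshift3 <- function(a) {
  dm <- dim(a)
  idx <- lapply(dm, function(n) ((seq_len(n) - 1L - n %/% 2L) %% n) + 1L)
  a[idx[[1]], idx[[2]], idx[[3]]]
}

ifftshift3 <- function(a) {
  dm <- dim(a)
  s <- vapply(dm, function(n) as.integer(ceiling(n / 2)), integer(1))
  idx <- lapply(1:3, function(ax) ((seq_len(dm[ax]) - 1L - s[ax]) %% dm[ax]) + 1L)
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# 1-based indices of the centered band of width w on an axis of extent n:
# 0-based [c - floor(w/2), c - floor(w/2) + w), c = floor(n/2).
band_indices <- function(n, w) {
  n <- as.integer(n); w <- as.integer(w)
  if (w < 1L || w > n)
    stopf("band width %d invalid for axis extent %d", w, n)
  start0 <- n %/% 2L - w %/% 2L
  (start0 + 1L):(start0 + w)
}

#' Centered 3D spectrum of a volume
#'
#' Applies the unnormalized 3D discrete Fourier transform and centres it so
#' the zero-frequency coefficient sits at index `floor(N/2)` (0-based) on
#' each axis. Parseval: the spectral energy equals the image-domain energy
#' times the number of voxels.
#'
#' @param vol a [volume()] (real-valued).
#' @return A `fousr_spectrum`: complex 3D array `data` plus the originating
#'   grid's `source_spacing`.
#' @export
forward_spectrum <- function(vol) {
  data <- as_vol_array(vol)
  check_3d(data)
  sp <- if (inherits(vol, "fousr_volume")) vol$spacing else c(1, 1, 1)
  structure(list(data = fftshift3(fft(data)), source_spacing = sp),
            class = "fousr_spectrum")
}

#' Invert a centered spectrum back to a magnitude image
#'
#' Undoes the centring, applies the inverse discrete Fourier transform, and
#' returns the complex magnitude as the image, matching magnitude-MRI
#' conventions (fusing two independently measured magnitude images can leave
#' a small imaginary residue). The round trip with [forward_spectrum()] is
#' the identity for nonnegative inputs.
#'
#' @param freq a `fousr_spectrum`.
#' @param name provenance tag for the output volume.
#' @return A [volume()].
#' @export
inverse_spectrum <- function(freq, name = "") {
  if (!inherits(freq, "fousr_spectrum")) stopf("freq must be a fousr_spectrum")
  check_3d(freq$data, "spectrum data")
  img <- fft(ifftshift3(freq$data), inverse = TRUE) / length(freq$data)
  volume(Mod(img), spacing = freq$source_spacing, name = name)
}

#' @export
print.fousr_spectrum <- function(x, ...) {
  cat(sprintf("<fousr_spectrum> %s voxels, source spacing %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$source_spacing, digits = 4), collapse = " x ")))
  invisible(x)
}

#' Acquisition geometry of one anisotropic scan
#'
#' @param in_plane_mm in-plane resolution in mm (> 0).
#' @param slice_mm through-plane slice thickness in mm (>= `in_plane_mm`).
#' @param slice_axis 1-based index (1--3) of the under-sampled axis.
#' @return An `fousr_geometry` object.
#' @export
#' @examples
#' acquisition_geometry(1.7, 5, slice_axis = 3)
acquisition_geometry <- function(in_plane_mm, slice_mm, slice_axis) {
  if (!is.numeric(in_plane_mm) || in_plane_mm <= 0)
    stopf("in_plane_mm must be positive")
  if (!is.numeric(slice_mm) || slice_mm < in_plane_mm)
    stopf("slice_mm must be >= in_plane_mm (anisotropic or isotropic, never finer)")
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stopf("slice_axis must be 1, 2 or 3")
  structure(list(in_plane_mm = as.numeric(in_plane_mm),
                 slice_mm = as.numeric(slice_mm), slice_axis = slice_axis),
            class = "fousr_geometry")
}

#' Number of reliably measured spectral lines of an anisotropic scan
#'
#' The ratio of slice thickness to in-plane resolution gives the fold
#' reduction of through-plane sampling; the axis extent divided by that
#' ratio gives how many central k-space planes along the slice axis the
#' scan genuinely measured. For the 5 mm / 1.7 mm protocol on a 160-line
#' axis this is a 2.94-fold factor and 54 lines.
#'
#' @param slice_mm slice thickness in mm.
#' @param in_plane_mm in-plane resolution in mm (`0 < in_plane_mm <= slice_mm`).
#' @param axis_extent integer number of voxels along the slice axis (>= 2).
#' @return List with `factor` (ratio rounded to 2 decimals, for reporting)
#'   and `n_lines` (integer count of measured central planes).
#' @export
#' @examples
#' compute_band_count(5, 1.7, 160)  # factor 2.94, n_lines 54
compute_band_count <- function(slice_mm, in_plane_mm, axis_extent) {
  if (!is.numeric(in_plane_mm) || in_plane_mm <= 0 ||
      !is.numeric(slice_mm) || slice_mm < in_plane_mm)
    stopf("need slice_mm >= in_plane_mm > 0")
  axis_extent <- as.integer(axis_extent)
  if (axis_extent < 2L) stopf("axis_extent must be >= 2")
  ratio <- slice_mm / in_plane_mm
  list(factor = round(ratio, 2),
       n_lines = as.integer(round_half_away(axis_extent / ratio)))
}

#' Plan a spectrum splice between two orthogonal scans
#'
#' The replacement axis is the donor's slice axis: the donor contributes the
#' centered band of planes it truly measured along that axis, the base
#' contributes the rest. With `band_width = "auto"` the width comes from
#' [compute_band_count()] applied to the replacement axis; an integer
#' override (such as the empirically tuned 64 of the 160-line ULF protocol)
#' may be given instead.
#'
#' @param base_geom,donor_geom [acquisition_geometry()] of the two scans;
#'   slice axes must differ (orthogonal acquisitions) and in-plane
#'   resolutions must agree.
#' @param grid_shape integer length-3 shape of the common preprocessed grid.
#' @param band_width `"auto"` or a positive integer no larger than the
#'   replacement-axis extent.
#' @param base_name,donor_name provenance tags.
#' @return A `fousr_fusion_plan` with `replacement_axis` and `band_width`.
#' @export
make_fusion_plan <- function(base_geom, donor_geom, grid_shape,
                             band_width = "auto",
                             base_name = "base", donor_name = "donor") {
  stopifnot(inherits(base_geom, "fousr_geometry"),
            inherits(donor_geom, "fousr_geometry"))
  if (base_geom$slice_axis == donor_geom$slice_axis)
    stopf("base and donor share slice axis %d: the scans are not orthogonal",
          base_geom$slice_axis)
  if (abs(base_geom$in_plane_mm - donor_geom$in_plane_mm) > 1e-9)
    stopf("base and donor in-plane resolutions differ")
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  ax <- donor_geom$slice_axis
  if (identical(band_width, "auto")) {
    bw <- compute_band_count(donor_geom$slice_mm, donor_geom$in_plane_mm,
                             grid_shape[ax])$n_lines
  } else {
    bw <- as.integer(band_width)
    if (length(bw) != 1L || is.na(bw) || bw < 1L)
      stopf("band_width must be \"auto\" or a positive integer")
  }
  if (bw > grid_shape[ax])
    stopf("band width %d exceeds replacement-axis extent %d", bw, grid_shape[ax])
  structure(list(replacement_axis = ax, band_width = bw,
                 base_name = base_name, donor_name = donor_name),
            class = "fousr_fusion_plan")
}

#' @export
print.fousr_fusion_plan <- function(x, ...) {
  cat(sprintf("<fousr_fusion_plan> replace %d centered planes along axis %d (%s <- %s)\n",
              x$band_width, x$replacement_axis, x$base_name, x$donor_name))
  invisible(x)
}

#' Fuse two co-registered orthogonal scans by spectrum splicing
#'
#' Both volumes are transformed to centered k-space; the inner
#' `plan$band_width` spectral planes along `plan$replacement_axis` are taken
#' from the donor and everything else from the base; the splice is inverted
#' and the magnitude returned. Inputs must already be preprocessed onto one
#' grid (isotropic, padded, normalized) and voxelwise co-registered.
#'
#' @param base,donor [volume()]s with identical shape and spacing.
#' @param plan a [make_fusion_plan()].
#' @param name provenance tag of the fused volume.
#' @return The fused [volume()], same shape and spacing as the inputs.
#' @export
fuse_volumes <- function(base, donor, plan, name = "FouSR") {
  stopifnot(inherits(base, "fousr_volume"), inherits(donor, "fousr_volume"),
            inherits(plan, "fousr_fusion_plan"))
  if (!identical(dim(base$data), dim(donor$data)))
    stopf("base and donor grids differ (%s vs %s)",
          paste(dim(base$data), collapse = "x"),
          paste(dim(donor$data), collapse = "x"))
  if (max(abs(base$spacing - donor$spacing)) > 1e-6)
    stopf("base and donor voxel spacings differ")
  s_base <- forward_spectrum(base)
  s_donor <- forward_spectrum(donor)
  fused <- splice_spectra(s_base, s_donor, plan)
  out <- inverse_spectrum(fused, name = name)
  out$axis_labels <- base$axis_labels
  out
}

#' Splice two centered spectra according to a fusion plan
#'
#' Low-level k-space operation behind [fuse_volumes()]: donor coefficients
#' on the centered band, base coefficients elsewhere.
#'
#' @param s_base,s_donor `fousr_spectrum` objects on identical grids.
#' @param plan a [make_fusion_plan()].
#' @return A `fousr_spectrum`.
#' @export
splice_spectra <- function(s_base, s_donor, plan) {
  stopifnot(inherits(s_base, "fousr_spectrum"),
            inherits(s_donor, "fousr_spectrum"),
            inherits(plan, "fousr_fusion_plan"))
  dm <- dim(s_base$data)
  if (!identical(dm, dim(s_donor$data))) stopf("spectrum grids differ")
  ax <- plan$replacement_axis
  band <- band_indices(dm[ax], plan$band_width)
  out <- s_base$data
  ii <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  ii[[ax]] <- band
  out[ii[[1]], ii[[2]], ii[[3]]] <- s_donor$data[ii[[1]], ii[[2]], ii[[3]]]
  structure(list(data = out, source_spacing = s_base$source_spacing),
            class = "fousr_spectrum")
}

#' Sweep the replacement band width and score each fusion
#'
#' Repeats the splice for each candidate width and scores the fused image
#' with the variance-of-Laplacian sharpness measure, mirroring the stepwise
#' tuning used to pick a protocol-specific width. The selected optimum is
#' the width with the maximal score; ties go to the smallest width (less
#' donor contrast contamination).
#'
#' @param base,donor preprocessed [volume()]s on one grid.
#' @param base_geom,donor_geom [acquisition_geometry()] of the scans.
#' @param widths nonempty integer vector of candidate band widths, each
#'   valid for the replacement axis.
#' @param score scoring rule; currently `"laplacian_sharpness"`.
#' @return A tibble of class `fousr_band_sweep` with columns `width` and
#'   `score`, sorted by width, carrying the chosen `optimum` as an
#'   attribute (see [glance.fousr_band_sweep()]).
#' @export
band_sweep <- function(base, donor, base_geom, donor_geom, widths,
                       score = "laplacian_sharpness") {
  score <- match.arg(score, "laplacian_sharpness")
  widths <- as.integer(widths)
  if (length(widths) == 0L || anyNA(widths)) stopf("widths must be nonempty integers")
  s_base <- forward_spectrum(base)
  s_donor <- forward_spectrum(donor)
  widths <- sort(unique(widths))
  scores <- vapply(widths, function(w) {
    plan <- make_fusion_plan(base_geom, donor_geom, dim(base$data), w)
    laplacian_sharpness(inverse_spectrum(splice_spectra(s_base, s_donor, plan)))
  }, numeric(1))
  out <- tibble::tibble(width = widths, score = scores)
  best <- widths[which.max(scores)]  # which.max takes the first = smallest width
  attr(out, "optimum") <- best
  class(out) <- c("fousr_band_sweep", class(out))
  out
}

#' @rdname band_sweep
#' @param x a `fousr_band_sweep`.
#' @param ... unused.
#' @export
tidy.fousr_band_sweep <- function(x, ...) tibble::tibble(width = x$width, score = x$score)

#' One-row summary of a band sweep
#'
#' @param x a [band_sweep()] result.
#' @param ... unused.
#' @return Tibble with the optimal `width`, its `score`, and the number of
#'   candidates examined.
#' @export
glance.fousr_band_sweep <- function(x, ...) {
  best <- attr(x, "optimum")
  tibble::tibble(optimum = best, score = x$score[match(best, x$width)],
                 n_widths = nrow(x))
}
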