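#' 3D image volume
#'
#' The basic container of the package: a 3D real-valued array plus per-axis
#' voxel spacing in millimetres, ordered anatomical axis labels, and a
#' free-text provenance tag. Grids are index-addressed; voxel `[1,1,1]` is
#' the grid corner.
#'
#' @param data 3D numeric array, each axis of length >= 2.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param axis_labels character length-3, distinct anatomical axis names.
#'   The canonical order produced by [read_volume()] is `c("LR","PA","IS")`
#'   (RAS+ voxel axes).
#' @param name free-text provenance tag.
#' @return A `fousr_volume` object.
#' @export
#' @examples
#' v <- volume(array(rnorm(4^3), c(4, 4, 4)), spacing = c(1.7, 1.7, 5))
#' v$spacing
volume <- function(data, spacing = c(1, 1, 1),
                   axis_labels = c("LR", "PA", "IS"), name = "") {
  storage.mode(data) <- "double"
  check_3d(data)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive numbers")
  axis_labels <- as.character(axis_labels)
  if (length(axis_labels) != 3L || anyDuplicated(axis_labels))
    stopf("axis_labels must be 3 distinct names")
  structure(list(data = data, spacing = spacing,
                 axis_labels = axis_labels, name = as.character(name)[1]),
            class = "fousr_volume")
}

#' @export
print.fousr_volume <- function(x, ...) {
  cat(sprintf("<fousr_volume> %s\n", if (nzchar(x$name)) x$name else "(unnamed)"))
  cat(sprintf("  grid    : %s voxels\n", paste(dim(x$data), collapse = " x ")))
  cat(sprintf("  spacing : %s mm (%s)\n",
              paste(format(x$spacing, digits = 4), collapse = " x "),
              paste(x$axis_labels, collapse = "/")))
  rng <- range(x$data)
  cat(sprintf("  range   : [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.fousr_volume <- function(x) dim(x$data)

#' Read a NIfTI volume in canonical orientation
#'
#' Loads a NIfTI-1 file (`.nii` / `.nii.gz`) and reorients the data grid to
#' the canonical RAS+ axis order so that any two scans loaded this way share
#' axis semantics regardless of how they were stored. Spacing is taken from
#' the file header.
#'
#' @param path path to an existing NIfTI-1 file.
#' @param name provenance tag; defaults to the file name.
#' @return A [volume()].
#' @export
read_volume <- function(path, name = basename(path)) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stopf("file not found: %s", paste(path, collapse = ", "))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("unreadable NIfTI header in '%s': %s",
                                            path, conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stopf("'%s' is not a 3D image (found %d dimensions)", path, length(dim(img)))
  if (isTRUE(attr(RNifti::xform(img), "code") > 0))
    RNifti::orientation(img) <- "RAS"
  sp <- RNifti::pixdim(img)[1:3]
  volume(array(as.numeric(img), dim(img)), spacing = sp, name = name)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [volume()].
#' @param path output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist. An existing file is replaced.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "fousr_volume"))
  if (!dir.exists(dirname(path)))
    stopf("parent directory does not exist: %s", dirname(path))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  # RAS+ affine so the canonical orientation is explicit in the header
  RNifti::qform(img) <- structure(diag(c(vol$spacing, 1)), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to isotropic resolution
#'
#' Regrids onto an isotropic grid of voxel size `target_mm`. The output
#' extent per axis is `round(extent_mm / target_mm)` (half away from zero),
#' and interpolation is separable nearest-neighbour or trilinear between
#' voxel centres, clamped at the edges.
#'
#' @param vol a [volume()].
#' @param target_mm target isotropic voxel size in mm (> 0).
#' @param method `"nearest"` (default, preserves the input intensity set) or
#'   `"linear"`.
#' @return A [volume()] with spacing `c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(vol, target_mm = 1.7,
                               method = c("nearest", "linear")) {
  stopifnot(inherits(vol, "fousr_volume"))
  method <- match.arg(method)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stopf("target_mm must be a single positive number")
  dm <- dim(vol$data)
  n_out <- as.integer(round_half_away(dm * vol$spacing / target_mm))
  if (any(n_out < 2L))
    stopf("target spacing %.3g mm collapses an axis below 2 voxels", target_mm)
  # continuous 1-based input index of each output voxel centre
  idx <- lapply(1:3, function(ax) {
    pos_mm <- (seq_len(n_out[ax]) - 0.5) * target_mm
    pmin(pmax(pos_mm / vol$spacing[ax] + 0.5, 1), dm[ax])
  })
  if (method == "nearest") {
    i <- lapply(1:3, function(ax) pmin(as.integer(round_half_away(idx[[ax]])), dm[ax]))
    out <- vol$data[i[[1]], i[[2]], i[[3]]]
  } else {
    out <- vol$data
    for (ax in 1:3) {
      lo <- pmin(floor(idx[[ax]]), dim(out)[ax] - 1L)
      f <- idx[[ax]] - lo
      pick <- function(k) {
        ii <- list(seq_len(dim(out)[1]), seq_len(dim(out)[2]), seq_len(dim(out)[3]))
        ii[[ax]] <- k
        out[ii[[1]], ii[[2]], ii[[3]]]
      }
      a_lo <- pick(lo)
      w <- array(f[slice.index(a_lo, ax)], dim(a_lo))
      out <- a_lo * (1 - w) + pick(lo + 1) * w
    }
  }
  dim(out) <- n_out
  volume(out, spacing = rep(target_mm, 3), axis_labels = vol$axis_labels,
         name = vol$name)
}

#' Zero-pad a volume to a target grid shape
#'
#' Centres the input in a zero background; the offset along each axis is
#' `floor((target - current) / 2)`. Original voxel values are untouched.
#'
#' @param vol a [volume()].
#' @param shape integer length-3 target extents, each >= the current extent.
#' @return A padded [volume()] with unchanged spacing.
#' @export
pad_to_shape <- function(vol, shape) {
  stopifnot(inherits(vol, "fousr_volume"))
  shape <- as.integer(shape)
  dm <- dim(vol$data)
  if (length(shape) != 3L || any(shape < dm))
    stopf("target shape (%s) must be >= current shape (%s) on every axis",
          paste(shape, collapse = "x"), paste(dm, collapse = "x"))
  if (all(shape == dm)) return(vol)
  out <- array(0, shape)
  off <- (shape - dm) %/% 2L
  out[off[1] + seq_len(dm[1]), off[2] + seq_len(dm[2]), off[3] + seq_len(dm[3])] <-
    vol$data
  volume(out, spacing = vol$spacing, axis_labels = vol$axis_labels,
         name = vol$name)
}

#' Normalize intensities to the 98th percentile of nonzero voxels
#'
#' Divides every intensity by the 98th percentile (linear-interpolation
#' definition) computed over nonzero voxels only, so that zero-padded or
#' skull-stripped backgrounds do not dominate the reference level. Values
#' above the percentile are not clipped.
#'
#' @param vol a [volume()] with at least one nonzero voxel.
#' @return A rescaled [volume()]; its 98th percentile over the same support
#'   is 1 up to floating error.
#' @export
normalize_p98 <- function(vol) {
  stopifnot(inherits(vol, "fousr_volume"))
  nz <- vol$data[vol$data != 0]
  if (length(nz) == 0L) stopf("cannot normalize an all-zero volume")
  q <- quantile(nz, 0.98, names = FALSE, type = 7)
  if (q <= 0) stopf("98th percentile of nonzero voxels is not positive")
  volume(vol$data / q, spacing = vol$spacing, axis_labels = vol$axis_labels,
         name = vol$name)
}
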