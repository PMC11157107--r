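# Image-quality evaluation: SNR, CNR, lesion conspicuity, and
# variance-of-Laplacian sharpness (whole image and per dilated lesion).
# All metrics are invariant to global positive intensity scaling.

#' Label connected lesion clusters
#'
#' Splits a binary 3D lesion mask into connected components under
#' 26-connectivity. Labels are consecutive from 1 and deterministically
#' ordered by each component's first voxel in array (column-major) scan
#' order; 0 marks background.
#'
#' @param lesion_mask binary 3D array, logical or 0/1 (or a [volume()]).
#' @return Integer array of the same shape with component labels.
#' @export
split_lesions <- function(lesion_mask) {
  fg <- as_mask(lesion_mask, "lesion_mask")
  lab <- array(Inf, dim(fg))
  lab[fg] <- which(fg)  # seed every foreground voxel with its linear index
  offs <- offsets26()
  max_iter <- sum(fg) + 1L
  for (iter in seq_len(max_iter)) {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      new <- pmin(new, shift_fill(lab, offs[r, ], fill = Inf))
    }
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, dim(fg))
  if (any(fg)) {
    roots <- lab[fg]
    out[fg] <- match(roots, sort(unique(roots)))
  }
  out
}

#' Dilate a binary mask with the 3x3x3 structuring element
#'
#' @param mask binary 3D array (or [volume()]).
#' @param iterations number of one-voxel dilation passes (>= 0).
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, iterations = 1) {
  m <- as_mask(mask)
  iterations <- as.integer(iterations)
  if (iterations < 0L) stopf("iterations must be >= 0")
  offs <- offsets26()
  for (i in seq_len(iterations)) {
    grown <- m
    for (r in seq_len(nrow(offs)))
      grown <- grown | shift_fill(m, offs[r, ], fill = FALSE)
    m <- grown
  }
  m
}

mask_stats <- function(vol, mask, what) {
  v <- as_vol_array(vol)
  m <- as_mask(mask, what)
  if (!identical(dim(v), dim(m))) stopf("%s shape differs from the volume", what)
  if (!any(m)) stopf("%s selects no voxels", what)
  v[m]
}

#' Signal-to-noise ratio
#'
#' Mean intensity over the signal region divided by the standard deviation
#' of intensities in a background-noise region.
#'
#' @param vol a [volume()] or 3D array.
#' @param signal_mask,noise_mask nonempty binary masks on the volume's grid.
#' @return Nonnegative scalar.
#' @export
snr <- function(vol, signal_mask, noise_mask) {
  sig <- mask_stats(vol, signal_mask, "signal_mask")
  noi <- mask_stats(vol, noise_mask, "noise_mask")
  s <- sd(noi)
  if (!is.finite(s) || s == 0) stopf("noise region has zero variance")
  mean(sig) / s
}

#' Contrast-to-noise ratio
#'
#' Absolute difference between the mean lesion and mean normal-appearing
#' white matter (NAWM) intensities, relative to the standard deviation of
#' background noise.
#'
#' @inheritParams snr
#' @param lesion_mask,nawm_mask nonempty binary masks.
#' @return Nonnegative scalar.
#' @export
cnr <- function(vol, lesion_mask, nawm_mask, noise_mask) {
  les <- mask_stats(vol, lesion_mask, "lesion_mask")
  nawm <- mask_stats(vol, nawm_mask, "nawm_mask")
  noi <- mask_stats(vol, noise_mask, "noise_mask")
  s <- sd(noi)
  if (!is.finite(s) || s == 0) stopf("noise region has zero variance")
  abs(mean(les) - mean(nawm)) / s
}

#' Lesion conspicuity
#'
#' `(mean lesion - mean NAWM) / (mean lesion + mean NAWM)`: a noise-free
#' visibility index in `[-1, 1]` for nonnegative intensities.
#'
#' @inheritParams cnr
#' @return Scalar in `[-1, 1]` when both means are nonnegative.
#' @export
conspicuity <- function(vol, lesion_mask, nawm_mask) {
  les <- mean(mask_stats(vol, lesion_mask, "lesion_mask"))
  nawm <- mean(mask_stats(vol, nawm_mask, "nawm_mask"))
  if (les + nawm == 0) stopf("lesion and NAWM means sum to zero")
  (les - nawm) / (les + nawm)
}

# 6-neighbour discrete Laplacian with edge replication.
laplacian3 <- function(v) {
  acc <- -6 * v
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    d <- integer(3); d[ax] <- s
    acc <- acc + shift_clamp(v, d)
  }
  acc
}

#' Variance-of-Laplacian image sharpness
#'
#' Applies the 6-neighbour discrete 3D Laplacian (edge-replicated borders)
#' and returns the standard deviation of the response over the region of
#' interest (the whole grid if none is given). Blurred images have gentler
#' second differences and hence lower scores; a constant or linear ramp
#' scores 0 in its interior.
#'
#' @param vol a [volume()] or 3D array with >= 3 voxels per axis.
#' @param roi optional nonempty binary mask restricting the statistic.
#' @return Nonnegative scalar.
#' @export
laplacian_sharpness <- function(vol, roi = NULL) {
  v <- as_vol_array(vol)
  check_3d(v)
  if (any(dim(v) < 3L)) stopf("volume must have >= 3 voxels per axis")
  lap <- laplacian3(v)
  vals <- if (is.null(roi)) as.vector(lap) else {
    m <- as_mask(roi, "roi")
    if (!identical(dim(m), dim(v))) stopf("roi shape differs from the volume")
    if (!any(m)) stopf("roi selects no voxels")
    lap[m]
  }
  if (length(vals) < 2L) return(0)
  sd(vals)
}

#' Per-lesion boundary sharpness
#'
#' For each labelled lesion, dilates its mask (26-connectivity structuring
#' element) to capture the boundary, computes [laplacian_sharpness()] over
#' the dilated region, and natural-log transforms the result. A lesion with
#' zero sharpness (no edge at all) yields `NA` rather than an error.
#'
#' @param vol a [volume()] or 3D array.
#' @param lesion_labels integer label array from [split_lesions()], on the
#'   volume's grid, with at least one positive label.
#' @param dilation_voxels number of one-voxel dilation passes (default 1).
#' @return Tibble with `lesion_id`, `voxel_count` (undilated), and
#'   `log_sharpness`.
#' @export
lesion_sharpness <- function(vol, lesion_labels, dilation_voxels = 1) {
  v <- as_vol_array(vol)
  labs <- as_vol_array(lesion_labels, "lesion_labels")
  if (!identical(dim(labs), dim(v))) stopf("lesion_labels shape differs from the volume")
  ids <- sort(unique(labs[labs > 0]))
  if (length(ids) == 0L) stopf("lesion_labels contains no lesions")
  rows <- lapply(ids, function(k) {
    m <- labs == k
    roi <- dilate_mask(m, dilation_voxels)
    s <- laplacian_sharpness(v, roi)
    tibble::tibble(lesion_id = as.integer(k), voxel_count = sum(m),
                   log_sharpness = if (s > 0) log(s) else NA_real_)
  })
  do.call(rbind, rows)
}
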