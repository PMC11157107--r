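#' Full quality report for one reconstruction
#'
#' Computes the evaluation suite for a single volume against an ROI set:
#' SNR (mean lesion signal over background-noise sd), CNR, lesion
#' conspicuity, whole-image variance-of-Laplacian sharpness, and per-lesion
#' log sharpness on dilated lesion masks.
#'
#' @param vol a [volume()].
#' @param rois a [roi_set()] on the volume's grid.
#' @param method_name label for the reconstruction being scored.
#' @param dilation_voxels dilation passes for per-lesion ROIs (default 1).
#' @param sharpness_roi optional binary mask (e.g. a brain mask) restricting
#'   the whole-image sharpness; whole grid if `NULL`.
#' @return A `fousr_quality` object; see [tidy.fousr_quality()] and
#'   [glance.fousr_quality()].
#' @export
quality_report <- function(vol, rois, method_name = vol$name,
                           dilation_voxels = 1, sharpness_roi = NULL) {
  stopifnot(inherits(vol, "fousr_volume"), inherits(rois, "fousr_roi_set"))
  if (!identical(dim(vol$data), dim(rois$lesion_mask)))
    stopf("ROI grid differs from the volume")
  les <- lesion_sharpness(vol, rois$lesion_labels, dilation_voxels)
  structure(list(
    method_name = method_name,
    snr = snr(vol, rois$lesion_mask, rois$noise_mask),
    cnr = cnr(vol, rois$lesion_mask, rois$nawm_mask, rois$noise_mask),
    conspicuity = conspicuity(vol, rois$lesion_mask, rois$nawm_mask),
    image_sharpness = laplacian_sharpness(vol, sharpness_roi),
    lesion_sharpness = les
  ), class = "fousr_quality")
}

#' @export
print.fousr_quality <- function(x, ...) {
  cat(sprintf("<fousr_quality> %s\n", x$method_name))
  cat(sprintf("  SNR %.3f | CNR %.3f | conspicuity %.4f | sharpness %.5f\n",
              x$snr, x$cnr, x$conspicuity, x$image_sharpness))
  cat(sprintf("  %d lesions, mean log sharpness %.3f\n",
              nrow(x$lesion_sharpness),
              mean(x$lesion_sharpness$log_sharpness, na.rm = TRUE)))
  invisible(x)
}

#' Per-lesion records of a quality report
#'
#' @param x a [quality_report()].
#' @param ... unused.
#' @return Tibble with one row per lesion: `method`, `lesion_id`,
#'   `voxel_count`, `log_sharpness`.
#' @export
tidy.fousr_quality <- function(x, ...) {
  tibble::tibble(method = x$method_name, x$lesion_sharpness)
}

#' One-row summary of a quality report
#'
#' @param x a [quality_report()].
#' @param ... unused.
#' @return Tibble with `method`, `snr`, `cnr`, `conspicuity`,
#'   `image_sharpness`, `n_lesions`, `mean_log_lesion_sharpness`.
#' @export
glance.fousr_quality <- function(x, ...) {
  tibble::tibble(method = x$method_name, snr = x$snr, cnr = x$cnr,
                 conspicuity = x$conspicuity,
                 image_sharpness = x$image_sharpness,
                 n_lesions = nrow(x$lesion_sharpness),
                 mean_log_lesion_sharpness =
                   mean(x$lesion_sharpness$log_sharpness, na.rm = TRUE))
}
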