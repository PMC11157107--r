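# ggplot2 displays for the tabular result types.

#' Plot a band-width sweep
#'
#' Sharpness score against replacement band width, with the selected
#' optimum marked.
#'
#' @param object a [band_sweep()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fousr_band_sweep <- function(object, ...) {
  best <- attr(object, "optimum")
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$width, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = "replacement band width (k-space planes)",
                  y = "variance-of-Laplacian sharpness",
                  title = sprintf("Band sweep (optimum: %d planes)", best))
}

#' Plot intensity profiles
#'
#' One line per reconstruction method along the sampled grid line.
#'
#' @param object an [intensity_profile()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fousr_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position_mm,
                                       y = .data$intensity,
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (mm)", y = "intensity", colour = NULL)
}

#' Plot a set of quality reports
#'
#' Bar panel per metric across methods, from the glance rows of one or
#' more [quality_report()]s.
#'
#' @param object a `fousr_quality` object.
#' @param others optional list of further `fousr_quality` objects to
#'   compare against.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fousr_quality <- function(object, others = list(), ...) {
  all_reports <- c(list(object), others)
  wide <- do.call(rbind, lapply(all_reports, glance))
  long <- tibble::tibble(
    method = rep(wide$method, 4L),
    metric = rep(c("SNR", "CNR", "conspicuity", "image sharpness"),
                 each = nrow(wide)),
    value = c(wide$snr, wide$cnr, wide$conspicuity, wide$image_sharpness))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 .data
NULL
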