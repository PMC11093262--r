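# ggplot2 front-ends for each result type

#' @exportS3Method ggplot2::autoplot
autoplot.mwe_cs_fit <- function(object, ...) {
  ggplot2::ggplot(object$distribution, ggplot2::aes(.data$s, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sedimentation coefficient (S)",
                  y = "c(s) (signal / S)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mwe_c2d <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$s, .data$wavelength,
                               fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "sedimentation coefficient (S)",
                  y = "emission wavelength (nm)", fill = "c(s, λ)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mwe_zscan <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$z, .data$counts,
                                             colour = factor(.data$wavelength))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z position (mm)", y = "counts",
                  colour = "wavelength (nm)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mwe_snr_curve <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$mean, .data$snr)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "signal amplitude (counts)", y = "SNR")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mwe_scan <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$radius, .data$counts,
                                  colour = .data$wavelength,
                                  group = .data$wavelength)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (cm)", y = "counts",
                  colour = "wavelength (nm)")
}

#' Overlay c(s) distributions
#'
#' @param fits Named list of `mwe_cs_fit` objects.
#' @return A ggplot.
#' @export
plot_cs_overlay <- function(fits) {
  d <- dplyr::bind_rows(purrr::imap(fits, function(f, nm)
    dplyr::mutate(f$distribution, label = nm)))
  ggplot2::ggplot(d, ggplot2::aes(.data$s, .data$density,
                                  colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sedimentation coefficient (S)",
                  y = "c(s) (signal / S)", colour = NULL)
}
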