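# ggplot2 display methods. NMR convention: ppm decreases left to right.

#' Plot an NMR spectrum
#'
#' @param object An `nmr_spectrum`.
#' @param ... Unused.
#' @return A ggplot object with a reversed ppm axis.
#' @method autoplot nmr_spectrum
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  validate_spectrum(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity",
                  title = sprintf("%g MHz", spectrometer_mhz(object))) +
    ggplot2::theme_minimal()
}

#' Overlay several spectra
#'
#' @param grids Named list of `nmr_spectrum` objects (names become the
#'   legend).
#' @return A ggplot object.
#' @export
plot_spectra <- function(grids) {
  if (is.null(names(grids))) {
    names(grids) <- paste0("spectrum_", seq_along(grids))
  }
  df <- purrr::imap_dfr(grids, function(g, nm) {
    tibble::tibble(which = nm, ppm = g$ppm, intensity = g$intensity)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm, y = .data$intensity,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-region similarity scores
#'
#' One bar per region of interest at its ppm center, with the pass
#' threshold drawn as a dashed line and excluded regions greyed out.
#'
#' @param object A `similarity_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot similarity_report
#' @export
autoplot.similarity_report <- function(object, ...) {
  df <- tidy(object) %>%
    dplyr::mutate(center = (.data$ppm_high + .data$ppm_low) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$score,
                                   fill = .data$excluded)) +
    ggplot2::geom_col(width = 0.08) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey20",
                                          `TRUE` = "grey80")) +
    ggplot2::labs(x = "region center (ppm)", y = "cosine score",
                  fill = "excluded") +
    ggplot2::theme_minimal()
}
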