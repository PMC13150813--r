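#' Create an annotated peak list
#'
#' The peak list is the unit stored and rendered by the database: each
#' peak has a chemical-shift position (ppm), a height (arbitrary units),
#' a full width at half maximum (Hz), and an optional multiplet
#' assignment grouping peaks that arise from the same proton(s).
#'
#' @param position_ppm Numeric vector of peak positions in ppm.
#' @param height Numeric vector of peak heights (finite), recycled.
#' @param width_hz Numeric vector of FWHM line widths in Hz (> 0, or `NA`
#'   for unknown widths awaiting [apply_placeholder_widths()]), recycled.
#' @param multiplet_id Optional character vector of multiplet labels
#'   (`NA` = unassigned; unassigned peaks are treated as singleton
#'   multiplets downstream), recycled.
#' @param source_kind `"annotated"` (measured peak list) or
#'   `"spin_system"` (derived from a quantum simulation).
#' @param provenance Optional entry/spectrum accession.
#' @return A tibble of class `peak_list` with columns `position_ppm`,
#'   `height`, `width_hz`, `multiplet_id`.
#' @examples
#' peak_list(c(1.2, 3.4), height = c(1, 2), width_hz = 1)
#' @export
peak_list <- function(position_ppm, height = 1, width_hz = NA_real_,
                      multiplet_id = NA_character_,
                      source_kind = c("annotated", "spin_system"),
                      provenance = NULL) {
  source_kind <- arg_match(source_kind)
  if (length(position_ppm) && (!is.numeric(position_ppm) ||
                               !all(is.finite(position_ppm)))) {
    abort_validation("`position_ppm` must be finite numeric.")
  }
  out <- tibble::tibble(position_ppm = as.numeric(position_ppm),
                        height = as.numeric(height),
                        width_hz = as.numeric(width_hz),
                        multiplet_id = as.character(multiplet_id))
  if (any(!is.finite(out$height))) {
    abort_validation("Peak heights must be finite.")
  }
  if (any(!is.na(out$width_hz) & out$width_hz <= 0)) {
    abort_validation("Peak widths must be > 0 Hz (or NA when unknown).")
  }
  attr(out, "source_kind") <- source_kind
  attr(out, "provenance") <- provenance
  class(out) <- c("peak_list", class(out))
  out
}

#' Coerce a data frame to a peak list
#'
#' @param x A data frame with at least a `position_ppm` column; `height`,
#'   `width_hz` and `multiplet_id` are filled with defaults when absent.
#' @inheritParams peak_list
#' @return A [peak_list()] tibble.
#' @export
as_peak_list <- function(x, source_kind = c("annotated", "spin_system"),
                         provenance = NULL) {
  if (inherits(x, "peak_list")) {
    return(x)
  }
  if (!is.data.frame(x) || !"position_ppm" %in% names(x)) {
    abort_validation("`x` must be a data frame with a `position_ppm` column.")
  }
  peak_list(position_ppm = x$position_ppm,
            height = x$height %||% 1,
            width_hz = x$width_hz %||% NA_real_,
            multiplet_id = x$multiplet_id %||% NA_character_,
            source_kind = source_kind, provenance = provenance)
}

# Assert widths are usable for rendering.
check_widths <- function(peaks) {
  if (any(is.na(peaks$width_hz))) {
    abort_validation(paste0(
      "Peak list has missing widths; assign them (e.g. the 1 Hz ",
      "placeholder via apply_placeholder_widths()) before rendering."))
  }
  invisible(peaks)
}

# Group key treating unassigned peaks as singleton multiplets.
multiplet_key <- function(peaks) {
  key <- peaks$multiplet_id
  lone <- is.na(key)
  key[lone] <- paste0(".peak", seq_len(nrow(peaks)))[lone]
  key
}
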