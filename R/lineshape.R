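# Lorentzian rendering of peak lists onto uniform spectral grids.

#' Height-parameterized Lorentzian profile
#'
#' Evaluates `height * g^2 / (x^2 + g^2)` with `g = width/2`, i.e. a
#' Lorentzian whose value at the center is exactly `height` and whose
#' full width at half maximum is `width`. The analytic area is
#' `pi * height * width / 2`.
#'
#' @param x Offset(s) from the line center (same units as `width`).
#' @param height Peak amplitude.
#' @param width Full width at half maximum (> 0).
#' @return Intensity at each `x`.
#' @examples
#' lorentzian(0, 1, 0.002)      # = 1, the height
#' lorentzian(0.001, 1, 0.002)  # = 0.5, half height at half width
#' @export
lorentzian <- function(x, height, width) {
  stopifnot_scalar_number(width, "width", positive = TRUE)
  g <- width / 2
  height * g^2 / (x^2 + g^2)
}

new_spectrum <- function(ppm, intensity, spectrometer_mhz) {
  out <- tibble::tibble(ppm = ppm, intensity = intensity)
  attr(out, "spectrometer_mhz") <- spectrometer_mhz
  class(out) <- c("nmr_spectrum", class(out))
  out
}

#' Spectrometer frequency of a spectrum grid
#'
#' @param spectrum An `nmr_spectrum` tibble (see [render_spectrum()]).
#' @return Frequency in MHz.
#' @export
spectrometer_mhz <- function(spectrum) {
  f <- attr(spectrum, "spectrometer_mhz")
  if (is.null(f)) {
    abort_validation("Spectrum has no `spectrometer_mhz` attribute.")
  }
  f
}

validate_spectrum <- function(spectrum) {
  if (!is.data.frame(spectrum) ||
      !all(c("ppm", "intensity") %in% names(spectrum))) {
    abort_validation("A spectrum needs `ppm` and `intensity` columns.")
  }
  if (nrow(spectrum) < 2L) {
    abort_validation("A spectrum grid needs at least 2 points.")
  }
  steps <- diff(spectrum$ppm)
  if (any(steps >= 0)) {
    abort_validation("`ppm` must be strictly decreasing (display convention).")
  }
  if (max(abs(steps - steps[1])) > 1e-9) {
    abort_validation("`ppm` axis must be uniformly spaced (to 1e-9 ppm).")
  }
  invisible(spectrum)
}

ppm_step <- function(spectrum) abs(spectrum$ppm[2] - spectrum$ppm[1])

#' Render a peak list as a spectrum grid
#'
#' Sums one height-parameterized [lorentzian()] per peak over a uniform
#' ppm grid running from `ppm_first` down to `ppm_last` (NMR display
#' convention: leftmost = highest ppm). Peak widths are carried in Hz and
#' converted to ppm as `width_hz / spectrometer_mhz`, so the same peak
#' list sharpens (in ppm) at higher field. Peaks outside the window still
#' contribute their tails; nothing is truncated, and no noise or
#' apodization is added.
#'
#' @param peaks A [peak_list()] (or data frame coercible via
#'   [as_peak_list()]); may be empty.
#' @param spectrometer_mhz Spectrometer frequency in MHz (> 0).
#' @param ppm_first,ppm_last Window bounds; `ppm_first > ppm_last`.
#' @param n_points Number of grid points (>= 2); the grid includes both
#'   endpoints with spacing `(ppm_first - ppm_last) / (n_points - 1)`.
#' @return An `nmr_spectrum` tibble with columns `ppm` (strictly
#'   decreasing) and `intensity`, carrying `spectrometer_mhz` as an
#'   attribute.
#' @examples
#' pl <- peak_list(1.0, height = 1, width_hz = 1)
#' sp <- render_spectrum(pl, 600, ppm_first = 2, ppm_last = 0, n_points = 512)
#' max(sp$intensity)
#' @export
render_spectrum <- function(peaks, spectrometer_mhz, ppm_first, ppm_last,
                            n_points) {
  stopifnot_scalar_number(spectrometer_mhz, "spectrometer_mhz", positive = TRUE)
  stopifnot_scalar_number(ppm_first, "ppm_first")
  stopifnot_scalar_number(ppm_last, "ppm_last")
  if (ppm_first <= ppm_last) {
    abort_validation("`ppm_first` must exceed `ppm_last` (empty window).")
  }
  if (!is.numeric(n_points) || n_points < 2) {
    abort_validation("`n_points` must be >= 2.")
  }
  peaks <- as_peak_list(peaks)
  axis <- seq(ppm_first, ppm_last, length.out = as.integer(n_points))
  intensity <- numeric(length(axis))
  if (nrow(peaks)) {
    check_widths(peaks)
    for (k in seq_len(nrow(peaks))) {
      w_ppm <- peaks$width_hz[k] / spectrometer_mhz
      intensity <- intensity +
        lorentzian(axis - peaks$position_ppm[k], peaks$height[k], w_ppm)
    }
  }
  new_spectrum(axis, intensity, spectrometer_mhz)
}

#' Render a peak list onto the grid of an existing spectrum
#'
#' Convenience wrapper producing a simulation that exactly matches an
#' experimental grid in sweep width, point count and spectrometer
#' frequency, as required for pointwise similarity scoring.
#'
#' @inheritParams render_spectrum
#' @param template An `nmr_spectrum` whose axis and field to reuse.
#' @return An `nmr_spectrum` on the template's axis.
#' @export
render_like <- function(peaks, template) {
  validate_spectrum(template)
  render_spectrum(peaks, spectrometer_mhz(template),
                  ppm_first = template$ppm[1],
                  ppm_last = template$ppm[nrow(template)],
                  n_points = nrow(template))
}

#' Concentration-weighted mixture of spectra
#'
#' A mixture spectrum is the pointwise concentration-weighted sum of the
#' component signatures; all grids must share axis and field.
#'
#' @param grids List of `nmr_spectrum` objects on identical axes.
#' @param concentrations Non-negative weights, one per grid.
#' @return An `nmr_spectrum`.
#' @export
mix_spectra <- function(grids, concentrations) {
  if (!length(grids) || length(grids) != length(concentrations)) {
    abort_validation("`concentrations` must match `grids` in length (>= 1).")
  }
  if (any(concentrations < 0)) {
    abort_validation("`concentrations` must be non-negative.")
  }
  ref <- grids[[1]]
  validate_spectrum(ref)
  total <- numeric(nrow(ref))
  for (k in seq_along(grids)) {
    g <- grids[[k]]
    validate_spectrum(g)
    if (nrow(g) != nrow(ref) || max(abs(g$ppm - ref$ppm)) > 1e-9 ||
        spectrometer_mhz(g) != spectrometer_mhz(ref)) {
      abort_validation("All grids must share the same axis and field.")
    }
    total <- total + concentrations[k] * g$intensity
  }
  new_spectrum(ref$ppm, total, spectrometer_mhz(ref))
}

#' Write / read a spectrum as two-column delimited text
#'
#' The on-disk form is a plain text file: a comment header carrying the
#' spectrometer frequency, then one `ppm intensity` pair per line at 12
#' significant digits, giving an exact numeric round trip at that
#' precision.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param path File path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns an `nmr_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  validate_spectrum(spectrum)
  lines <- c(sprintf("# spectrometer_mhz %.12g", spectrometer_mhz(spectrum)),
             sprintf("%.12g %.12g", spectrum$ppm, spectrum$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*spectrometer_mhz", lines, value = TRUE)
  if (!length(hdr)) {
    abort_parse("Spectrum file lacks a '# spectrometer_mhz' header line.")
  }
  mhz <- as.numeric(sub("^#\\s*spectrometer_mhz\\s+", "", hdr[1]))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != 2L)) {
    abort_parse("Spectrum file rows must have exactly two columns.")
  }
  vals <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  sp <- new_spectrum(vals[, 1], vals[, 2], mhz)
  validate_spectrum(sp)
  sp
}
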