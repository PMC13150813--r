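# Shared fixtures and independent oracles, built in code at test time.

# Closed-form AB (two coupled spin-1/2) spectrum: the textbook
# diagonalization of the 2-spin problem, independent of the package's
# matrix machinery. Total intensity 2 (one per proton).
ab_closed_form <- function(shift1_ppm, shift2_ppm, j_hz, mhz) {
  nu1 <- shift1_ppm * mhz
  nu2 <- shift2_ppm * mhz
  dnu <- nu1 - nu2
  nc <- (nu1 + nu2) / 2
  C <- sqrt(dnu^2 + j_hz^2)
  s <- j_hz / C # sin(2*theta)
  tibble::tibble(
    frequency_hz = c(nc - (C + j_hz) / 2, nc - (C - j_hz) / 2,
                     nc + (C - j_hz) / 2, nc + (C + j_hz) / 2),
    intensity = c((1 - s) / 2, (1 + s) / 2, (1 + s) / 2, (1 - s) / 2))
}

# First-order multiplet of one proton split by couplings `js` (Hz) to
# sets of `counts` equivalent neighbours: binomial splitting-tree
# construction (the weak-coupling rule), intensities summing to 1.
first_order_multiplet <- function(center_hz, js, counts) {
  freq <- center_hz
  inten <- 1
  for (k in seq_along(js)) {
    m <- counts[k]
    weights <- choose(m, 0:m) / 2^m
    offsets <- (0:m - m / 2) * js[k]
    freq <- as.vector(outer(freq, offsets, `+`))
    inten <- as.vector(outer(inten, weights, `*`))
    key <- as.factor(round(freq, 9))
    merged_i <- tapply(inten, key, sum)
    merged_f <- tapply(freq, key, mean)
    ord <- order(merged_f)
    freq <- as.numeric(merged_f[ord])
    inten <- as.numeric(merged_i[ord])
  }
  tibble::tibble(frequency_hz = freq, intensity = inten)
}

# A tiny two-multiplet annotated peak list (a doublet and a singlet).
toy_peaks <- function() {
  peak_list(position_ppm = c(1.195, 1.205, 3.6),
            height = c(0.5, 0.5, 1),
            width_hz = c(1, 1, 1),
            multiplet_id = c("M1", "M1", "M2"))
}

toy_grid <- function(peaks = toy_peaks(), mhz = 600, n = 4096) {
  render_spectrum(peaks, mhz, ppm_first = 10, ppm_last = 0, n_points = n)
}

shift_peaks_for_test <- function(peaks, offset_ppm) {
  peaks$position_ppm <- peaks$position_ppm + offset_ppm
  peaks
}

scale_widths_for_test <- function(peaks, factor) {
  peaks$width_hz <- peaks$width_hz * factor
  peaks
}

expect_tibble_equal <- function(a, b, tol = 1e-8) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
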