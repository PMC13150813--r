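# Synthetic fixtures: seeded spin systems, complete database entries,
# and experimental-like spectra carrying the features real spectra have
# and ideal simulations lack (noise, baseline roll, reference and
# residual-solvent signals, referencing offsets, line broadening).

#' Specification for synthetic fixture generation
#'
#' Collects every knob of the synthetic generator in one list; a given
#' `seed` fixes all randomness, so identical specs yield identical
#' fixtures.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_spins Number of protons in generated spin systems (1-12).
#' @param shift_range_ppm Length-2 ppm range shifts are drawn from.
#' @param coupling_mean_hz,coupling_sd_hz Normal distribution of drawn
#'   scalar couplings (defaults 7 +- 2 Hz, typical vicinal couplings).
#' @param noise_sd White-noise standard deviation as a fraction of the
#'   maximum clean intensity (default 0.01).
#' @param baseline_amplitude Amplitude of a slowly varying sinusoidal
#'   baseline, as a fraction of the maximum (default 0.01).
#' @param ppm_offset Global referencing offset applied to the spectrum
#'   (default 0).
#' @param width_scale Multiplicative line broadening (default 1).
#' @param include_reference_peak Add a 1 Hz reference-compound peak at
#'   0.00 ppm (default `TRUE`).
#' @param include_solvent Add a broad (20 Hz) residual-solvent signal at
#'   4.70 ppm (default `TRUE`).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_spins = 4, shift_range_ppm = c(0.5, 9),
                           coupling_mean_hz = 7, coupling_sd_hz = 2,
                           noise_sd = 0.01, baseline_amplitude = 0.01,
                           ppm_offset = 0, width_scale = 1,
                           include_reference_peak = TRUE,
                           include_solvent = TRUE) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_validation("`seed` must be a single integer.")
  }
  if (n_spins < 1 || n_spins > 12) {
    abort_validation("`n_spins` must lie in [1, 12].")
  }
  if (any(c(noise_sd, baseline_amplitude, width_scale) < 0) ||
      coupling_sd_hz < 0) {
    abort_validation("Noise, baseline, width and coupling-sd must be >= 0.")
  }
  structure(list(seed = as.integer(seed), n_spins = as.integer(n_spins),
                 shift_range_ppm = sort(shift_range_ppm),
                 coupling_mean_hz = coupling_mean_hz,
                 coupling_sd_hz = coupling_sd_hz, noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 ppm_offset = ppm_offset, width_scale = width_scale,
                 include_reference_peak = isTRUE(include_reference_peak),
                 include_solvent = isTRUE(include_solvent)),
            class = "synthetic_spec")
}

#' Read a synthetic spec from a key-value config file
#'
#' Plain-text `key = value` lines (logical values `true`/`false`);
#' unknown keys raise an error, missing keys keep their defaults.
#'
#' @param path Config file path.
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort_parse(sprintf("Malformed config line: %s", ln))
    }
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(formals(synthetic_spec))) {
      abort_parse(sprintf("Unknown config key: %s", key))
    }
    args[[key]] <- if (val %in% c("true", "false")) {
      val == "true"
    } else {
      nums <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (any(is.na(nums))) {
        abort_parse(sprintf("Non-numeric value for key %s: %s", key, val))
      }
      nums
    }
  }
  do.call(synthetic_spec, args)
}

#' Generate a random spin system
#'
#' Draws `n_spins` chemical shifts uniformly from the spec's shift range
#' and scalar couplings (normal around the spec's mean) for a random
#' connected subset of spin pairs, so every generated system is a single
#' coupled network. Fully deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [spin_system()].
#' @export
make_spin_system <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_spins
    shifts <- sort(stats::runif(n, spec$shift_range_ppm[1],
                                spec$shift_range_ppm[2]))
    J <- matrix(0, n, n)
    if (n > 1L) {
      # random spanning tree keeps the network connected
      for (k in 2:n) {
        j <- sample.int(k - 1L, 1L)
        J[k, j] <- J[j, k] <- stats::rnorm(1, spec$coupling_mean_hz,
                                           spec$coupling_sd_hz)
      }
      # sprinkle a few extra couplings beyond the tree
      extra <- which(upper.tri(J) & J == 0)
      pick <- extra[stats::runif(length(extra)) < 0.25]
      for (e in pick) {
        J[e] <- stats::rnorm(1, spec$coupling_mean_hz, spec$coupling_sd_hz)
      }
      J[lower.tri(J)] <- t(J)[lower.tri(J)]
    }
    spin_system(shifts, J, entry_ref = sprintf("SYN%06d", spec$seed %% 1000000L))
  })
}

#' Degrade a clean spectrum into an experimental-like one
#'
#' Applies, seeded and in order: line broadening by `width_scale`
#' (re-rendered from `peaks` when given, otherwise by convolution with a
#' Lorentzian kernel), a global `ppm_offset` referencing shift (by axis
#' re-interpolation), an additive slowly varying baseline, a reference
#' peak at 0.00 ppm, a broad residual-solvent signal at 4.70 ppm, and
#' white Gaussian noise with sd = `noise_sd` x the clean maximum.
#'
#' @param clean A clean `nmr_spectrum` (e.g. from [render_spectrum()]).
#' @param spec A [synthetic_spec()] supplying the perturbation sizes.
#' @param peaks Optional [peak_list()] that produced `clean`; when
#'   given, broadening re-renders exactly instead of convolving.
#' @param assumed_width_hz Line width assumed by the convolution
#'   fallback (default 1 Hz, the placeholder convention).
#' @return An `nmr_spectrum` on the same axis.
#' @export
make_experimental_like <- function(clean, spec, peaks = NULL,
                                   assumed_width_hz = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spectrum(clean)
  mhz <- spectrometer_mhz(clean)
  intensity <- clean$intensity
  top <- max(abs(intensity))
  if (top == 0) top <- 1

  if (spec$width_scale != 1) {
    if (!is.null(peaks)) {
      intensity <- render_like(scale_widths(as_peak_list(peaks),
                                            spec$width_scale),
                               clean)$intensity
    } else {
      # Lorentzian FWHMs add under convolution: kernel width (s-1)*w0
      step <- ppm_step(clean)
      kw <- (spec$width_scale - 1) * assumed_width_hz / mhz
      half <- min(ceiling(50 * kw / step), nrow(clean))
      kx <- seq(-half, half) * step
      kernel <- lorentzian(kx, 1, kw)
      kernel <- kernel / sum(kernel)
      padded <- c(rep(intensity[1], half), intensity,
                  rep(intensity[length(intensity)], half))
      conv <- stats::filter(padded, kernel, sides = 2)
      intensity <- as.numeric(conv[(half + 1):(half + length(intensity))])
    }
  }
  if (spec$ppm_offset != 0) {
    # shifted(ppm) = original(ppm - offset); flat extrapolation at edges
    shifted <- stats::approx(clean$ppm, intensity,
                             xout = clean$ppm - spec$ppm_offset,
                             rule = 2)$y
    intensity <- shifted
  }
  ppm <- clean$ppm
  if (spec$baseline_amplitude > 0) {
    frac <- (ppm - min(ppm)) / (max(ppm) - min(ppm))
    intensity <- intensity +
      spec$baseline_amplitude * top * sin(2 * pi * 1.5 * frac + 0.7)
  }
  if (spec$include_reference_peak) {
    intensity <- intensity + lorentzian(ppm - 0, 0.5 * top, 1 / mhz)
  }
  if (spec$include_solvent) {
    intensity <- intensity + lorentzian(ppm - 4.70, top, 20 / mhz)
  }
  if (spec$noise_sd > 0) {
    intensity <- intensity + withr::with_seed(
      spec$seed + 1L, stats::rnorm(length(intensity), 0,
                                   spec$noise_sd * top))
  }
  new_spectrum(ppm, intensity, mhz)
}

#' Generate a complete synthetic metabolite entry
#'
#' Builds a valid database entry around a seeded random spin system: a
#' synthetic InChI-like identifier (distinct per seed), one sample with
#' typical acquisition metadata, and one spectrum storing both the spin
#' system (atom-assigned multiplets + couplings) and the peak list
#' simulated from it at the recorded field.
#'
#' @param spec A [synthetic_spec()].
#' @param spectrometer_mhz Field recorded on the spectrum (default 600).
#' @param default_width_hz Width for simulated peaks (default 1 Hz).
#' @return A validated [metabolite_entry()].
#' @export
make_entry <- function(spec, spectrometer_mhz = 600, default_width_hz = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ss <- make_spin_system(spec)
  tag <- withr::with_seed(spec$seed, paste0(
    paste(sample(c(LETTERS, 0:9), 14, replace = TRUE), collapse = ""),
    "-", spec$seed))
  id <- sprintf("SYN%06d", spec$seed %% 1000000L)
  pk <- simulate_peaks(ss, spectrometer_mhz,
                       default_width_hz = default_width_hz)
  metabolite_entry(
    entry_id = id,
    inchi = paste0("InChI=1S/XSYN", spec$n_spins, "H", spec$n_spins,
                   "/t", tag),
    name = paste0("synthetic metabolite ", id),
    synonyms = tibble::tibble(name = paste0("syn-", tolower(id))),
    samples = tibble::tibble(
      sample_id = "S1", ph = 7.0, solvent = "D2O",
      reference_compound = "DSS", temperature_k = 298,
      source_db = "synthetic", source_accession = id),
    spectra = tibble::tibble(
      spectrum_id = "SP1", sample_id = "S1",
      spectrometer_mhz = spectrometer_mhz, source_kind = "spin_system",
      verified = FALSE),
    multiplets = tibble::tibble(
      multiplet_id = ss$atom_labels, spectrum_id = "SP1",
      center_ppm = ss$shifts_ppm, atom_assignment = ss$atom_labels),
    peaks = tibble::tibble(
      peak_id = paste0("P", seq_len(nrow(pk))), spectrum_id = "SP1",
      multiplet_id = pk$multiplet_id, position_ppm = pk$position_ppm,
      height = pk$height, width_hz = pk$width_hz,
      width_placeholder = TRUE),
    couplings = {
      nz <- which(upper.tri(ss$couplings_hz) & ss$couplings_hz != 0,
                  arr.ind = TRUE)
      tibble::tibble(spectrum_id = rep("SP1", nrow(nz)),
                     atom_1 = ss$atom_labels[nz[, 1]],
                     atom_2 = ss$atom_labels[nz[, 2]],
                     j_hz = ss$couplings_hz[nz])
    })
}
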