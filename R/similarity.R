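# Region-of-interest cosine-similarity scoring of spectra.

#' Cosine similarity between two intensity vectors
#'
#' Returns `sum(a*b) / (||a|| * ||b||)`: 1 for a perfect match, -1 for a
#' perfectly inverted one, and invariant to positive rescaling of either
#' argument.
#'
#' @param a,b Equal-length numeric vectors, each with at least one
#'   nonzero entry.
#' @return A score in `[-1, 1]`.
#' @examples
#' x <- dnorm(seq(-3, 3, length.out = 101))
#' cosine_score(x, x)    #  1
#' cosine_score(x, -x)   # -1
#' @export
cosine_score <- function(a, b) {
  if (length(a) != length(b)) {
    abort_validation("`a` and `b` must have equal length.")
  }
  if (!length(a)) {
    abort_validation("Vectors must be non-empty.")
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    rlang::abort("Cosine score undefined for an all-zero vector.",
                 class = "spinmatch_error_undefined_score")
  }
  sum(a * b) / (na * nb)
}

#' Regions of interest around simulated multiplets
#'
#' Builds one ppm interval per multiplet (unassigned peaks count as
#' singleton multiplets): the span of the multiplet's outermost peak
#' positions extended on both sides by `margin_factor` times the widest
#' member line width (converted to ppm). Overlapping intervals are
#' merged. Scoring only inside these regions keeps solvent and reference
#' signals from contaminating the similarity score.
#'
#' @param peaks A non-empty [peak_list()] with usable widths.
#' @param spectrometer_mhz Field in MHz used for the Hz-to-ppm width
#'   conversion.
#' @param margin_factor Margin in units of the widest member width
#'   (default 10: covers Lorentzian tails without swallowing neighbours).
#' @return A tibble of class `roi_list` with columns `ppm_high`,
#'   `ppm_low`, `origin` (comma-separated multiplet labels), sorted
#'   downfield-first.
#' @export
regions_of_interest <- function(peaks, spectrometer_mhz, margin_factor = 10) {
  peaks <- as_peak_list(peaks)
  if (!nrow(peaks)) {
    abort_validation("Cannot build regions of interest from an empty peak list.")
  }
  check_widths(peaks)
  stopifnot_scalar_number(spectrometer_mhz, "spectrometer_mhz", positive = TRUE)
  key <- multiplet_key(peaks)
  iv <- peaks %>%
    dplyr::mutate(.key = key, width_ppm = .data$width_hz / spectrometer_mhz) %>%
    dplyr::group_by(.data$.key) %>%
    dplyr::summarise(
      ppm_low = min(.data$position_ppm) -
        margin_factor * max(.data$width_ppm),
      ppm_high = max(.data$position_ppm) +
        margin_factor * max(.data$width_ppm),
      .groups = "drop")
  # merge overlaps, remembering which multiplets ended up in each region
  merged <- merge_intervals(iv[c("ppm_low", "ppm_high")])
  origin <- vapply(seq_len(nrow(merged)), function(k) {
    members <- iv$.key[iv$ppm_low <= merged$ppm_high[k] &
                         iv$ppm_high >= merged$ppm_low[k]]
    paste(sort(members), collapse = ",")
  }, character(1))
  out <- tibble::tibble(ppm_high = merged$ppm_high,
                        ppm_low = merged$ppm_low,
                        origin = origin)
  class(out) <- c("roi_list", class(out))
  out
}

roi_slice <- function(spectrum, ppm_low, ppm_high) {
  which(spectrum$ppm >= ppm_low & spectrum$ppm <= ppm_high)
}

#' Signal-to-noise ratio of a region
#'
#' Ratio of the maximum intensity inside the region of interest to the
#' standard deviation of the intensities in a peak-free noise interval.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param roi A one-row data frame (or list) with `ppm_low`/`ppm_high`.
#' @param noise_interval Numeric length-2 ppm bounds `(low, high)` of a
#'   peak-free stretch containing at least 16 grid points.
#' @return The SNR (a single number).
#' @export
spectrum_snr <- function(spectrum, roi, noise_interval) {
  validate_spectrum(spectrum)
  sig <- roi_slice(spectrum, roi$ppm_low, roi$ppm_high)
  noi <- roi_slice(spectrum, min(noise_interval), max(noise_interval))
  if (length(noi) < 16L) {
    abort_validation("`noise_interval` must contain at least 16 grid points.")
  }
  if (!length(sig)) {
    abort_validation("Region of interest contains no grid points.")
  }
  s <- stats::sd(spectrum$intensity[noi])
  if (s == 0) {
    rlang::abort("SNR undefined: noise interval has zero standard deviation.",
                 class = "spinmatch_error_undefined_snr")
  }
  max(spectrum$intensity[sig]) / s
}

# Widest stretch of the grid not covered by any ROI; NULL when none has
# >= 16 points. Used as the default noise interval.
widest_peak_free_interval <- function(spectrum, rois) {
  lo <- spectrum$ppm[nrow(spectrum)]
  hi <- spectrum$ppm[1]
  free <- subtract_intervals(lo, hi, rois[c("ppm_low", "ppm_high")])
  if (!nrow(free)) {
    return(NULL)
  }
  free <- dplyr::arrange(free, dplyr::desc(.data$ppm_high - .data$ppm_low))
  best <- free[1, ]
  if (length(roi_slice(spectrum, best$ppm_low, best$ppm_high)) < 16L) {
    return(NULL)
  }
  c(best$ppm_low, best$ppm_high)
}

#' Score a simulated spectrum against an experimental one
#'
#' Computes the cosine similarity of the two spectra over each region of
#' interest, excludes regions whose experimental signal-to-noise ratio
#' falls below `snr_min`, and averages the remaining region scores
#' (unweighted) into the overall score, compared against `threshold`
#' (default 0.9, the accepted bound for a sufficient match; it
#' corresponds to a query/match line-width ratio of 2.5).
#'
#' When the noise level of the experimental grid is exactly zero (ideal
#' noiseless simulations) the SNR rule is skipped rather than erroring,
#' since it exists to guard against noise-dominated regions.
#'
#' @param sim,exp `nmr_spectrum` objects on the same axis.
#' @param rois A tibble from [regions_of_interest()] (or with the same
#'   columns).
#' @param threshold Pass bound on the overall score (default 0.9).
#' @param snr_min Minimum experimental SNR for a region to count
#'   (default 10, the accepted limit of quantification).
#' @param noise_interval Length-2 ppm bounds of a peak-free noise
#'   stretch; default: the widest stretch of the grid outside every ROI.
#' @return A `similarity_report`: a tibble with one row per region
#'   (`ppm_high`, `ppm_low`, `origin`, `score`, `snr`, `excluded`) and
#'   attributes `overall`, `threshold`, `passed`; see
#'   [glance.similarity_report()].
#' @export
score_spectra <- function(sim, exp, rois, threshold = 0.9, snr_min = 10,
                          noise_interval = NULL) {
  validate_spectrum(sim)
  validate_spectrum(exp)
  if (nrow(sim) != nrow(exp) || max(abs(sim$ppm - exp$ppm)) > 1e-9) {
    abort_validation("`sim` and `exp` must share the same ppm axis.")
  }
  if (!is.data.frame(rois) || !nrow(rois)) {
    abort_validation("`rois` must be a non-empty data frame.")
  }
  if (is.null(noise_interval)) {
    noise_interval <- widest_peak_free_interval(exp, rois)
  }
  noise_sd <- if (is.null(noise_interval)) {
    NA_real_
  } else {
    idx <- roi_slice(exp, min(noise_interval), max(noise_interval))
    if (length(idx) >= 16L) stats::sd(exp$intensity[idx]) else NA_real_
  }

  score <- snr <- rep(NA_real_, nrow(rois))
  excluded <- rep(FALSE, nrow(rois))
  for (k in seq_len(nrow(rois))) {
    idx <- roi_slice(exp, rois$ppm_low[k], rois$ppm_high[k])
    if (!length(idx)) {
      excluded[k] <- TRUE
      next
    }
    # apply the SNR rule only when the noise estimate is meaningfully
    # above the numerical floor; ideal noiseless grids skip it
    if (!is.na(noise_sd) && noise_sd > 1e-9 * max(abs(exp$intensity))) {
      snr[k] <- max(exp$intensity[idx]) / noise_sd
      if (snr[k] < snr_min) {
        excluded[k] <- TRUE
        next
      }
    }
    a <- sim$intensity[idx]
    b <- exp$intensity[idx]
    if (sum(a^2) == 0 || sum(b^2) == 0) {
      excluded[k] <- TRUE
      next
    }
    score[k] <- cosine_score(a, b)
  }
  if (all(excluded)) {
    rlang::abort("Every region of interest was excluded; no score available.",
                 class = "spinmatch_error_empty_report")
  }
  out <- tibble::tibble(
    ppm_high = rois$ppm_high, ppm_low = rois$ppm_low,
    origin = if ("origin" %in% names(rois)) rois$origin else NA_character_,
    score = score, snr = snr, excluded = excluded)
  overall <- mean(score[!excluded])
  attr(out, "overall") <- overall
  attr(out, "threshold") <- threshold
  attr(out, "passed") <- overall >= threshold
  attr(out, "noise_interval") <- noise_interval
  class(out) <- c("similarity_report", class(out))
  out
}

#' Overall score of a similarity report
#' @param report A `similarity_report` from [score_spectra()].
#' @return The mean of the retained region scores.
#' @export
overall_score <- function(report) {
  stopifnot(inherits(report, "similarity_report"))
  attr(report, "overall")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report: overall %.4f %s threshold %.2f (%s)>\n",
              attr(x, "overall"),
              if (attr(x, "passed")) ">=" else "<",
              attr(x, "threshold"),
              if (attr(x, "passed")) "passed" else "failed"))
  NextMethod()
}

#' Tidy / summarise a similarity report
#'
#' `tidy()` returns the per-region rows as a plain tibble; `glance()`
#' returns a one-row summary (overall score, threshold, pass flag,
#' region counts).
#'
#' @param x A `similarity_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy similarity_report
#' @export
tidy.similarity_report <- function(x, ...) {
  out <- x
  for (a in c("overall", "threshold", "passed", "noise_interval")) {
    attr(out, a) <- NULL
  }
  class(out) <- setdiff(class(out), "similarity_report")
  tibble::as_tibble(out)
}

#' @rdname tidy.similarity_report
#' @method glance similarity_report
#' @export
glance.similarity_report <- function(x, ...) {
  tibble::tibble(overall = attr(x, "overall"),
                 threshold = attr(x, "threshold"),
                 passed = attr(x, "passed"),
                 n_rois = nrow(x),
                 n_excluded = sum(x$excluded))
}

#' Serialize a similarity report as a flat text record
#'
#' Writes `key value` header lines (overall, threshold, passed) followed
#' by one tab-separated row per region.
#'
#' @param report A `similarity_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "similarity_report"))
  g <- glance(report)
  rows <- tidy(report)
  lines <- c(
    sprintf("overall\t%.6f", g$overall),
    sprintf("threshold\t%.6f", g$threshold),
    sprintf("passed\t%s", tolower(as.character(g$passed))),
    "roi\tppm_high\tppm_low\tscore\tsnr\texcluded",
    sprintf("roi\t%.6f\t%.6f\t%s\t%s\t%s",
            rows$ppm_high, rows$ppm_low,
            ifelse(is.na(rows$score), ".", sprintf("%.6f", rows$score)),
            ifelse(is.na(rows$snr), ".", sprintf("%.3f", rows$snr)),
            tolower(as.character(rows$excluded))))
  writeLines(lines, path)
  invisible(path)
}
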