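# Internal helpers shared across modules.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "spinmatch_error_validation", ...)
}

abort_parse <- function(msg, ...) {
  rlang::abort(msg, class = "spinmatch_error_parse", ...)
}

abort_complexity <- function(msg, ...) {
  rlang::abort(msg, class = "spinmatch_error_complexity", ...)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_validation(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Merge possibly overlapping closed intervals given as a tibble with
# columns ppm_low/ppm_high; returns intervals sorted by descending ppm_high.
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(intervals)
  }
  iv <- dplyr::arrange(intervals, .data$ppm_low)
  lows <- iv$ppm_low
  highs <- iv$ppm_high
  out_low <- lows[1]
  out_high <- highs[1]
  for (k in seq_len(nrow(iv))[-1]) {
    i <- length(out_low)
    if (lows[k] <= out_high[i]) {
      out_high[i] <- max(out_high[i], highs[k])
    } else {
      out_low <- c(out_low, lows[k])
      out_high <- c(out_high, highs[k])
    }
  }
  tibble::tibble(ppm_low = out_low, ppm_high = out_high) %>%
    dplyr::arrange(dplyr::desc(.data$ppm_high))
}

# Set-difference of one interval against a list of intervals; returns a
# tibble of the surviving sub-intervals (possibly empty).
subtract_intervals <- function(low, high, cut) {
  pieces <- tibble::tibble(ppm_low = low, ppm_high = high)
  if (nrow(cut) == 0L) {
    return(pieces)
  }
  for (k in seq_len(nrow(cut))) {
    cl <- cut$ppm_low[k]
    ch <- cut$ppm_high[k]
    kept_low <- numeric()
    kept_high <- numeric()
    for (j in seq_len(nrow(pieces))) {
      pl <- pieces$ppm_low[j]
      ph <- pieces$ppm_high[j]
      if (ch <= pl || cl >= ph) { # no overlap
        kept_low <- c(kept_low, pl)
        kept_high <- c(kept_high, ph)
        next
      }
      if (pl < cl) {
        kept_low <- c(kept_low, pl)
        kept_high <- c(kept_high, cl)
      }
      if (ph > ch) {
        kept_low <- c(kept_low, ch)
        kept_high <- c(kept_high, ph)
      }
    }
    pieces <- tibble::tibble(ppm_low = kept_low, ppm_high = kept_high)
    if (nrow(pieces) == 0L) break
  }
  pieces
}

# Format a double so it survives a text round trip at >= 9 significant
# digits; NA becomes the STAR null token ".".
format_number <- function(x) {
  ifelse(is.na(x), ".", vapply(x, function(v) sprintf("%.12g", v), character(1)))
}
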