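#' Create a spin-system matrix
#'
#' A spin system is the field-independent abstraction of a metabolite's
#' \eqn{^1}H NMR signature: one chemical shift (ppm, DSS-referenced) per
#' proton and a symmetric matrix of scalar couplings \eqn{J_{ij}} (Hz).
#' Together they are sufficient to simulate the spectrum at any
#' spectrometer frequency.
#'
#' @param shifts_ppm Numeric vector of proton chemical shifts in ppm.
#' @param couplings_hz Symmetric numeric matrix of scalar couplings in Hz
#'   with zero diagonal, one row/column per shift. A single spin may pass
#'   an empty (0 x 0 or 1 x 1 zero) matrix or leave the default.
#' @param atom_labels Character vector of unique proton identifiers;
#'   defaults to `H1`, `H2`, ...
#' @param entry_ref Optional accession of the owning database entry.
#'
#' @return An object of class `spin_system`: a list with elements
#'   `atom_labels`, `shifts_ppm`, `couplings_hz`, `entry_ref`.
#' @examples
#' # an AB pair: two protons 0.01 ppm apart coupled by 7 Hz
#' spin_system(c(1.00, 1.01), matrix(c(0, 7, 7, 0), 2))
#' @export
spin_system <- function(shifts_ppm, couplings_hz = NULL, atom_labels = NULL,
                        entry_ref = NULL) {
  if (!is.numeric(shifts_ppm) || length(shifts_ppm) < 1L ||
      !all(is.finite(shifts_ppm))) {
    abort_validation("`shifts_ppm` must be a non-empty finite numeric vector.")
  }
  n <- length(shifts_ppm)
  if (is.null(couplings_hz)) {
    couplings_hz <- matrix(0, n, n)
  }
  couplings_hz <- as.matrix(couplings_hz)
  if (n == 1L && length(couplings_hz) == 0L) {
    couplings_hz <- matrix(0, 1, 1)
  }
  if (!is.numeric(couplings_hz) || nrow(couplings_hz) != n ||
      ncol(couplings_hz) != n || !all(is.finite(couplings_hz))) {
    abort_validation(sprintf(
      "`couplings_hz` must be a finite %d x %d numeric matrix.", n, n))
  }
  if (max(abs(couplings_hz - t(couplings_hz))) > 1e-9) {
    abort_validation("`couplings_hz` must be symmetric.")
  }
  if (any(abs(diag(couplings_hz)) > 1e-12)) {
    abort_validation("`couplings_hz` must have a zero diagonal.")
  }
  if (is.null(atom_labels)) {
    atom_labels <- paste0("H", seq_len(n))
  }
  if (length(atom_labels) != n || anyDuplicated(atom_labels)) {
    abort_validation("`atom_labels` must be unique and match the shift count.")
  }
  if (any(shifts_ppm < -1 | shifts_ppm > 12)) {
    warn("Chemical shifts outside the usual [-1, 12] ppm proton window.",
         class = "spinmatch_warning_shift_range")
  }
  dimnames(couplings_hz) <- list(atom_labels, atom_labels)
  structure(
    list(atom_labels = as.character(atom_labels),
         shifts_ppm = as.numeric(shifts_ppm),
         couplings_hz = couplings_hz,
         entry_ref = entry_ref),
    class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system: %d proton(s)%s>\n", length(x$shifts_ppm),
              if (is.null(x$entry_ref)) "" else paste0(", ", x$entry_ref)))
  print(tibble::tibble(atom = x$atom_labels, shift_ppm = x$shifts_ppm))
  nz <- which(upper.tri(x$couplings_hz) & x$couplings_hz != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    cat("Couplings (Hz):\n")
    print(tibble::tibble(atom_1 = x$atom_labels[nz[, 1]],
                         atom_2 = x$atom_labels[nz[, 2]],
                         j_hz = x$couplings_hz[nz]))
  }
  invisible(x)
}

#' Tidy a spin system into a shift table
#'
#' @param x A [spin_system()].
#' @param ... Unused.
#' @return A tibble with one row per proton (`atom`, `shift_ppm`) plus a
#'   long coupling table attached as attribute `"couplings"`.
#' @method tidy spin_system
#' @export
tidy.spin_system <- function(x, ...) {
  out <- tibble::tibble(atom = x$atom_labels, shift_ppm = x$shifts_ppm)
  nz <- which(upper.tri(x$couplings_hz) & x$couplings_hz != 0, arr.ind = TRUE)
  attr(out, "couplings") <- tibble::tibble(
    atom_1 = x$atom_labels[nz[, 1]],
    atom_2 = x$atom_labels[nz[, 2]],
    j_hz = x$couplings_hz[nz])
  out
}

n_spins <- function(ss) length(ss$shifts_ppm)
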