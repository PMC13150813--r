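# Quantum-mechanical simulation of spin-1/2 systems.
#
# The spectrum of a J-coupled proton network is obtained by
# diagonalizing the isotropic spin Hamiltonian in the product basis
#   H = sum_i nu_i Iz(i) + sum_{i<j} J_ij [Ix(i)Ix(j)+Iy(i)Iy(j)+Iz(i)Iz(j)]
# with nu_i = shift_ppm[i] * spectrometer_mhz (lab-frame offsets in Hz;
# larger ppm = higher frequency). Single-quantum transition intensities
# are |<f| sum_i Ix(i) |i>|^2 between eigenstates whose total magnetic
# quantum number differs by one, normalized so that each proton carries
# unit total intensity. Strong-coupling (second-order) line positions
# and "roof effect" intensity distortions emerge naturally.

state_bits <- function(n) {
  states <- 0:(2^n - 1)
  bits <- matrix(0, 2^n, n)
  for (i in seq_len(n)) {
    bits[, i] <- bitwAnd(states, bitwShiftL(1L, i - 1L)) > 0L
  }
  bits
}

check_spin_count <- function(n, max_spins) {
  if (n > max_spins) {
    abort_complexity(sprintf(paste0(
      "Spin system has %d spins but `max_spins` is %d: exact ",
      "diagonalization grows roughly O(N^3) per transition and ",
      "exponentially in memory, so larger systems are refused."),
      n, max_spins))
  }
}

# Diagonal (Zeeman + zz-coupling) energy of every product state, in Hz.
diagonal_energies <- function(bits, nu, J) {
  n <- length(nu)
  m <- bits - 0.5
  e <- as.vector(m %*% nu)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (J[i, j] != 0) e <- e + J[i, j] * m[, i] * m[, j]
      }
    }
  }
  e
}

#' Spin Hamiltonian of a proton network
#'
#' Builds the full \eqn{2^n \times 2^n} isotropic spin-1/2 Hamiltonian of
#' a spin system in the product (Zeeman) basis, in Hz. The matrix is real
#' symmetric; scalar coupling contributes the secular \eqn{I_zI_z} term on
#' the diagonal and flip-flop (\eqn{I_xI_x + I_yI_y}) elements of
#' \eqn{J_{ij}/2} between states related by an up/down exchange of spins
#' \eqn{i,j}.
#'
#' @param ss A [spin_system()].
#' @param spectrometer_mhz Spectrometer frequency in MHz (> 0); chemical
#'   shifts in ppm scale to Hz as `shift_ppm * spectrometer_mhz`.
#' @param max_spins Refuse systems larger than this (default 12): exact
#'   diagonalization cost grows exponentially with spin count.
#' @return A `2^n x 2^n` numeric matrix (Hz).
#' @examples
#' ab <- spin_system(c(1.00, 1.01), matrix(c(0, 7, 7, 0), 2))
#' spin_hamiltonian(ab, 600)
#' @export
spin_hamiltonian <- function(ss, spectrometer_mhz, max_spins = 12) {
  stopifnot(inherits(ss, "spin_system"))
  stopifnot_scalar_number(spectrometer_mhz, "spectrometer_mhz", positive = TRUE)
  n <- n_spins(ss)
  check_spin_count(n, max_spins)
  nu <- ss$shifts_ppm * spectrometer_mhz
  J <- ss$couplings_hz
  bits <- state_bits(n)
  states <- 0:(2^n - 1)
  H <- diag(diagonal_energies(bits, nu, J), 2^n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (J[i, j] == 0) next
        sel <- bits[, i] > 0 & bits[, j] == 0
        s <- states[sel]
        p <- s - bitwShiftL(1L, i - 1L) + bitwShiftL(1L, j - 1L)
        H[cbind(s + 1L, p + 1L)] <- H[cbind(s + 1L, p + 1L)] + J[i, j] / 2
        H[cbind(p + 1L, s + 1L)] <- H[cbind(p + 1L, s + 1L)] + J[i, j] / 2
      }
    }
  }
  H
}

#' Single-quantum transitions of a spin system
#'
#' Eigen-decomposes the spin Hamiltonian blockwise by total magnetic
#' quantum number (which the Hamiltonian conserves) and computes, for
#' every eigenstate pair in adjacent blocks, the transition frequency and
#' the intensity \eqn{|\langle f|\sum_i I_x(i)|i\rangle|^2}. Intensities
#' are normalized so the total over all transitions equals the number of
#' spins (an isolated proton contributes exactly 1). Transitions weaker
#' than `intensity_cutoff` relative to the strongest are dropped, and
#' transitions closer than `merge_tol_hz` are merged by summing
#' intensities (this collapses equivalent-spin multiplets to single
#' lines).
#'
#' @inheritParams spin_hamiltonian
#' @param intensity_cutoff Relative intensity floor (default `1e-9`).
#' @param merge_tol_hz Frequency tolerance for merging degenerate
#'   transitions, in Hz (default `1e-6`).
#' @return A tibble with columns `frequency_hz`, `intensity`, and `atom`
#'   (the proton whose flip dominates the transition amplitude, used
#'   downstream as the multiplet label).
#' @examples
#' ab <- spin_system(c(1.00, 1.01), matrix(c(0, 7, 7, 0), 2))
#' spin_transitions(ab, 600)
#' @export
spin_transitions <- function(ss, spectrometer_mhz, max_spins = 12,
                             intensity_cutoff = 1e-9, merge_tol_hz = 1e-6) {
  stopifnot(inherits(ss, "spin_system"))
  stopifnot_scalar_number(spectrometer_mhz, "spectrometer_mhz", positive = TRUE)
  n <- n_spins(ss)
  check_spin_count(n, max_spins)
  nu <- ss$shifts_ppm * spectrometer_mhz
  J <- ss$couplings_hz
  bits <- state_bits(n)
  states <- 0:(2^n - 1)
  diagE <- diagonal_energies(bits, nu, J)
  pop <- as.integer(rowSums(bits))
  pos <- integer(2^n) # state value -> local index inside its block

  blocks <- vector("list", n + 1L)
  for (k in 0:n) {
    idx <- which(pop == k)
    pos[idx] <- seq_along(idx)
    dim_k <- length(idx)
    Hk <- diag(diagE[idx], dim_k)
    if (n > 1L && dim_k > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          if (J[i, j] == 0) next
          sel <- idx[bits[idx, i] > 0 & bits[idx, j] == 0]
          if (!length(sel)) next
          s <- states[sel]
          p <- s - bitwShiftL(1L, i - 1L) + bitwShiftL(1L, j - 1L)
          r <- pos[sel]
          c <- pos[p + 1L]
          Hk[cbind(r, c)] <- Hk[cbind(r, c)] + J[i, j] / 2
          Hk[cbind(c, r)] <- Hk[cbind(c, r)] + J[i, j] / 2
        }
      }
    }
    eg <- eigen(Hk, symmetric = TRUE)
    blocks[[k + 1L]] <- list(idx = idx, values = eg$values, vectors = eg$vectors)
  }

  freq <- numeric()
  raw <- numeric()
  spin <- integer()
  for (k in 0:(n - 1L)) {
    a <- blocks[[k + 1L]] # lower block (k spins up)
    b <- blocks[[k + 2L]] # upper block (k + 1 spins up)
    na <- length(a$idx)
    nb <- length(b$idx)
    # per-spin raising elements <b|Ix(i)|a> = 1/2 where bit i flips 0 -> 1
    amps <- array(0, c(nb, na, n))
    for (i in seq_len(n)) {
      sel <- a$idx[bits[a$idx, i] == 0]
      if (!length(sel)) next
      s <- states[sel]
      p <- s + bitwShiftL(1L, i - 1L)
      Xi <- matrix(0, nb, na)
      Xi[cbind(pos[p + 1L], pos[sel])] <- 0.5
      amps[, , i] <- crossprod(b$vectors, Xi %*% a$vectors)
    }
    A <- rowSums(amps, dims = 2)
    f <- outer(b$values, a$values, `-`)
    dom <- max.col(matrix(abs(amps), nb * na, n), ties.method = "first")
    freq <- c(freq, as.vector(f))
    raw <- c(raw, as.vector(A)^2)
    spin <- c(spin, dom)
  }

  inten <- raw * n / sum(raw)
  keep <- inten >= intensity_cutoff * max(inten)
  tr <- tibble::tibble(frequency_hz = freq[keep], intensity = inten[keep],
                       spin = spin[keep]) %>%
    dplyr::arrange(.data$frequency_hz)

  # merge degenerate lines
  gap <- c(Inf, diff(tr$frequency_hz))
  grp <- cumsum(gap >= merge_tol_hz)
  tr %>%
    dplyr::group_by(grp = grp) %>%
    dplyr::summarise(
      frequency_hz = sum(.data$frequency_hz * .data$intensity) /
        sum(.data$intensity),
      atom = ss$atom_labels[.data$spin[which.max(.data$intensity)]],
      intensity = sum(.data$intensity),
      .groups = "drop") %>%
    dplyr::select("frequency_hz", "intensity", "atom")
}

#' Simulate a peak list from a spin system
#'
#' Runs the quantum-mechanical transition calculation at the requested
#' spectrometer frequency and converts each transition to an annotated
#' peak: position in ppm (`frequency_hz / spectrometer_mhz`), height
#' proportional to transition intensity, and a uniform line width. Line
#' width is not part of the quantum simulation; it enters only here, as
#' the width later used by Lorentzian rendering.
#'
#' @inheritParams spin_transitions
#' @param default_width_hz Full width at half maximum assigned to every
#'   peak, in Hz (> 0). Databases lacking measured widths conventionally
#'   use a 1 Hz placeholder.
#' @return A [peak_list()] tibble with `source_kind = "spin_system"`;
#'   `multiplet_id` tags each peak with the proton group dominating its
#'   transition amplitude.
#' @examples
#' ab <- spin_system(c(1.00, 1.01), matrix(c(0, 7, 7, 0), 2))
#' simulate_peaks(ab, 600)
#' @export
simulate_peaks <- function(ss, spectrometer_mhz, default_width_hz = 1,
                           max_spins = 12, intensity_cutoff = 1e-9,
                           merge_tol_hz = 1e-6) {
  stopifnot_scalar_number(default_width_hz, "default_width_hz", positive = TRUE)
  tr <- spin_transitions(ss, spectrometer_mhz, max_spins = max_spins,
                         intensity_cutoff = intensity_cutoff,
                         merge_tol_hz = merge_tol_hz)
  peak_list(position_ppm = tr$frequency_hz / spectrometer_mhz,
            height = tr$intensity,
            width_hz = default_width_hz,
            multiplet_id = tr$atom,
            source_kind = "spin_system",
            provenance = ss$entry_ref)
}
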