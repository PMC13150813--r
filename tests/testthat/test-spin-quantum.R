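test_that("single-spin Hamiltonian is the Zeeman term", {
  ss <- spin_system(1.0)
  H <- spin_hamiltonian(ss, 600)
  expect_equal(dim(H), c(2L, 2L))
  expect_equal(sort(diag(H)), c(-300, 300))
  expect_equal(H[1, 2], 0)

  tr <- spin_transitions(ss, 600)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$frequency_hz, 600)
  expect_equal(tr$intensity, 1)
})

test_that("uncoupled spins give a diagonal Hamiltonian", {
  ss <- spin_system(c(1, 2), matrix(0, 2, 2))
  H <- spin_hamiltonian(ss, 600)
  expect_equal(H, diag(diag(H)))
})

test_that("invalid spin systems are refused", {
  expect_error(spin_system(c(1, 2), matrix(c(0, 7, 3, 0), 2)),
               class = "spinmatch_error_validation")
  expect_error(spin_system(c(1, 2), matrix(c(1, 7, 7, 0), 2)),
               class = "spinmatch_error_validation")
  expect_error(spin_system(c(1, 2), matrix(0, 3, 3)),
               class = "spinmatch_error_validation")
  big <- spin_system(seq(0.5, 8, length.out = 13))
  expect_error(spin_hamiltonian(big, 600),
               class = "spinmatch_error_complexity")
  expect_error(spin_transitions(big, 600),
               class = "spinmatch_error_complexity")
})

test_that("two-spin systems match the closed-form AB solution", {
  cases <- list(
    list(shifts = c(1.00, 1.01), j = 7),    # strongly coupled, dnu ~ J
    list(shifts = c(1.000, 7/600 + 1), j = 7), # dnu = J exactly
    list(shifts = c(1.0, 2.0), j = 7),      # AX limit
    list(shifts = c(3.0, 3.002), j = 12))
  for (cs in cases) {
    ab <- spin_system(cs$shifts, matrix(c(0, cs$j, cs$j, 0), 2))
    got <- spin_transitions(ab, 600)
    want <- ab_closed_form(cs$shifts[1], cs$shifts[2], cs$j, 600)
    want <- want[order(want$frequency_hz), ]
    expect_equal(got$frequency_hz, want$frequency_hz, tolerance = 1e-8)
    expect_equal(got$intensity, want$intensity, tolerance = 1e-8)
  }
})

test_that("AX doublets follow the first-order rule", {
  # dnu = 600 Hz >> J = 7 Hz
  ax <- spin_system(c(1.0, 2.0), matrix(c(0, 7, 7, 0), 2))
  tr <- spin_transitions(ax, 600)
  expect_equal(nrow(tr), 4L)
  # two 1:1 doublets split by 7 Hz
  a <- tr[tr$frequency_hz < 900, ]
  x <- tr[tr$frequency_hz > 900, ]
  expect_equal(diff(a$frequency_hz), 7, tolerance = 1e-6)
  expect_equal(diff(x$frequency_hz), 7, tolerance = 1e-6)
  # intensities near-equal; the residual roof effect at dnu/J ~ 86 is
  # (1+J/C)/(1-J/C) ~ 1.024
  expect_lt(max(tr$intensity) / min(tr$intensity), 1.05)
})

test_that("equivalent spins collapse to a single line of total intensity n", {
  for (n in c(2, 3, 4)) {
    J <- matrix(7, n, n)
    diag(J) <- 0
    ss <- spin_system(rep(2.0, n), J)
    tr <- spin_transitions(ss, 600)
    expect_equal(nrow(tr), 1L)
    expect_equal(tr$frequency_hz, 1200, tolerance = 1e-6)
    expect_equal(tr$intensity, n, tolerance = 1e-8)
  }
})

test_that("weak coupling reproduces the binomial multiplet construction", {
  # A X3 system: one proton at 6 ppm coupled (2 Hz) to three equivalent
  # protons at 1 ppm; dnu = 3000 Hz = 1500 * J, deep in the weak limit.
  # Residual second-order structure splits the quartet components by
  # ~J^2/dnu ~ 0.001 Hz, so compare line clusters against the binomial
  # construction.
  n <- 4
  J <- matrix(0, n, n)
  J[1, 2:4] <- J[2:4, 1] <- 2
  ss <- spin_system(c(6, 1, 1, 1), J)
  tr <- spin_transitions(ss, 600)
  a <- tr[tr$frequency_hz > 2000, ] # the A quartet
  want <- first_order_multiplet(6 * 600, js = 2, counts = 3)
  cluster <- vapply(a$frequency_hz, function(f) {
    which.min(abs(want$frequency_hz - f))
  }, integer(1))
  got_f <- as.numeric(tapply(a$frequency_hz * a$intensity, cluster, sum) /
                        tapply(a$intensity, cluster, sum))
  got_i <- as.numeric(tapply(a$intensity, cluster, sum))
  expect_equal(got_f, want$frequency_hz, tolerance = 0.01 / 3600)
  expect_equal(got_i, want$intensity, tolerance = 0.01)
  # the X3 doublet: total intensity 3, split by 2 Hz
  x <- tr[tr$frequency_hz < 2000, ]
  expect_equal(sum(x$intensity), 3, tolerance = 0.01)
  expect_equal(diff(range(x$frequency_hz)), 2, tolerance = 0.01)
})

test_that("total intensity is conserved across fields", {
  ss <- make_spin_system(synthetic_spec(seed = 11, n_spins = 5))
  t1 <- spin_transitions(ss, 400)
  t2 <- spin_transitions(ss, 900)
  expect_equal(sum(t1$intensity), 5, tolerance = 1e-8)
  expect_equal(sum(t1$intensity), sum(t2$intensity), tolerance = 1e-8)
})

test_that("the AB roof effect decreases monotonically with field", {
  ab <- spin_system(c(1.00, 1.02), matrix(c(0, 7, 7, 0), 2))
  fields <- seq(100, 900, by = 100)
  asym <- vapply(fields, function(f) {
    tr <- spin_transitions(ab, f)
    (max(tr$intensity) - min(tr$intensity)) / sum(range(tr$intensity))
  }, numeric(1))
  expect_true(all(diff(asym) < 0))
})

test_that("simulated peak lists scale correctly with field", {
  ss <- spin_system(c(1.0, 2.0, 5.0),
                    rbind(c(0, 7, 0), c(7, 0, 0), c(0, 0, 0)))
  p600 <- simulate_peaks(ss, 600)
  p800 <- simulate_peaks(ss, 800)
  # uncoupled spin keeps its ppm position exactly
  expect_equal(p600$position_ppm[p600$multiplet_id == "H3"],
               p800$position_ppm[p800$multiplet_id == "H3"],
               tolerance = 1e-10)
  # doublet splitting is constant in Hz, so shrinks in ppm by 600/800
  split <- function(p, m) diff(range(p$position_ppm[p$multiplet_id == m]))
  expect_equal(split(p800, "H1") / split(p600, "H1"), 600 / 800,
               tolerance = 1e-6)
  # total height invariant with field
  expect_equal(sum(p600$height), sum(p800$height), tolerance = 1e-8)
  expect_equal(attr(p600, "source_kind"), "spin_system")
})
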