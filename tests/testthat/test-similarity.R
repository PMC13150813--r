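test_that("cosine score has the stated endpoint semantics", {
  sp <- toy_grid()
  expect_equal(cosine_score(sp$intensity, sp$intensity), 1, tolerance = 1e-12)
  expect_equal(cosine_score(sp$intensity, -sp$intensity), -1,
               tolerance = 1e-12)
  expect_error(cosine_score(1:3, 1:4), class = "spinmatch_error_validation")
  expect_error(cosine_score(c(0, 0), c(1, 1)),
               class = "spinmatch_error_undefined_score")
})

test_that("cosine score is symmetric and scale invariant", {
  withr::with_seed(1, {
    for (k in 1:10) {
      a <- rnorm(200)
      b <- rnorm(200)
      c <- runif(1, 0.01, 100)
      expect_identical(cosine_score(a, b), cosine_score(b, a))
      expect_equal(cosine_score(a, c * b), cosine_score(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("co-centered Lorentzians follow the analytic width-ratio law", {
  w <- 1 / 600 # 1 Hz at 600 MHz, in ppm
  x <- seq(0.5, -0.5, length.out = 200001) # ~600 widths
  for (r in c(1.5, 2, 2.5, 4)) {
    a <- lorentzian(x, 1, w)
    b <- lorentzian(x, 1, r * w)
    expect_equal(cosine_score(a, b), 2 * sqrt(r) / (1 + r), tolerance = 0.005)
  }
  # the 0.9-threshold calibration: ratio 2.5 scores 0.90 to two decimals
  a <- lorentzian(x, 1, w)
  b <- lorentzian(x, 1, 2.5 * w)
  expect_equal(round(cosine_score(a, b), 2), 0.90)
})

test_that("regions of interest span multiplets with the width margin", {
  pk <- peak_list(5.0, height = 1, width_hz = 1)
  roi <- regions_of_interest(pk, 600, margin_factor = 10)
  expect_equal(nrow(roi), 1L)
  expect_equal(roi$ppm_high, 5 + 10 / 600)
  expect_equal(roi$ppm_low, 5 - 10 / 600)

  # two multiplets 5 ppm apart stay disjoint
  two <- peak_list(c(2, 7), height = 1, width_hz = 1,
                   multiplet_id = c("A", "B"))
  roi2 <- regions_of_interest(two, 600)
  expect_equal(nrow(roi2), 2L)
  expect_true(roi2$ppm_low[1] > roi2$ppm_high[2])

  # overlapping margins merge into exactly one region covering both
  near <- peak_list(c(2.000, 2.005), height = 1, width_hz = 2,
                    multiplet_id = c("A", "B"))
  roi3 <- regions_of_interest(near, 600)
  expect_equal(nrow(roi3), 1L)
  expect_equal(roi3$ppm_low, 2.000 - 20 / 600)
  expect_equal(roi3$ppm_high, 2.005 + 20 / 600)
  expect_equal(roi3$origin, "A,B")
})

test_that("snr is max signal over noise standard deviation", {
  pk <- peak_list(8.0, height = 100, width_hz = 1)
  sp <- toy_grid(pk)
  noisy <- sp
  noise <- withr::with_seed(7, rnorm(nrow(sp)))
  noisy$intensity <- noisy$intensity + noise
  roi <- list(ppm_low = 7.9, ppm_high = 8.1)
  got <- spectrum_snr(noisy, roi, c(2, 4))
  expect_equal(got, max(noisy$intensity[noisy$ppm >= 7.9 & noisy$ppm <= 8.1]) /
                 sd(noisy$intensity[sp$ppm >= 2 & sp$ppm <= 4]),
               tolerance = 1e-9)
  expect_gt(got, 50)
  # a peak-free region scores a small snr
  flat <- spectrum_snr(noisy, list(ppm_low = 5.5, ppm_high = 6), c(2, 4))
  expect_lt(flat, 10)
  # a grid with a perfectly flat noise interval has undefined snr
  flat_grid <- toy_grid(peak_list(numeric(0)))
  expect_error(spectrum_snr(flat_grid, roi, c(2, 4)),
               class = "spinmatch_error_undefined_snr")
})

test_that("overall score averages region scores and applies thresholds", {
  pk <- toy_peaks()
  sp <- toy_grid(pk)
  rois <- regions_of_interest(pk, 600)
  rep <- score_spectra(sp, sp, rois)
  expect_true(all(abs(tidy(rep)$score - 1) < 1e-12))
  expect_equal(overall_score(rep), 1, tolerance = 1e-12)
  expect_true(attr(rep, "passed"))

  # one region perfect, one orthogonal -> overall is their mean, 0.5
  ortho <- sp
  idx_b <- which(sp$ppm >= rois$ppm_low[2] & sp$ppm <= rois$ppm_high[2])
  a <- sp$intensity[idx_b]
  v <- rep(1, length(a))
  ortho$intensity[idx_b] <- v - sum(v * a) / sum(a * a) * a
  rep2 <- score_spectra(sp, ortho, rois, threshold = 0.9, snr_min = 0)
  scores <- tidy(rep2)$score
  expect_equal(max(scores), 1, tolerance = 1e-9)
  expect_equal(min(scores), 0, tolerance = 1e-9)
  expect_equal(overall_score(rep2), 0.5, tolerance = 1e-9)
  expect_equal(overall_score(rep2), mean(scores))
  expect_false(attr(rep2, "passed"))
})

test_that("intensity outside every region never changes the report", {
  pk <- toy_peaks()
  sp <- toy_grid(pk)
  exp0 <- sp
  exp0$intensity <- exp0$intensity * 0.9
  rois <- regions_of_interest(pk, 600)
  # fixed clean noise interval so the SNR rule sees the same noise in
  # both calls
  noise_iv <- c(8.5, 9.5)
  base <- score_spectra(sp, exp0, rois, noise_interval = noise_iv)
  spiked <- exp0
  outside <- rep(TRUE, nrow(spiked))
  for (k in seq_len(nrow(rois))) {
    outside[spiked$ppm >= rois$ppm_low[k] &
              spiked$ppm <= rois$ppm_high[k]] <- FALSE
  }
  band <- which(outside & spiked$ppm > 6 & spiked$ppm < 6.05)
  spiked$intensity[band] <- spiked$intensity[band] + 50
  after <- score_spectra(sp, spiked, rois, noise_interval = noise_iv)
  expect_equal(tidy(after)$score, tidy(base)$score, tolerance = 1e-12)
  expect_equal(overall_score(after), overall_score(base), tolerance = 1e-12)
})

test_that("low-snr regions are excluded from the mean", {
  pk <- peak_list(c(2, 7), height = c(100, 0.5), width_hz = 1,
                  multiplet_id = c("A", "B"))
  sim <- toy_grid(pk)
  noisy <- sim
  noisy$intensity <- noisy$intensity + withr::with_seed(3, rnorm(nrow(sim), 0, 0.3))
  rois <- regions_of_interest(pk, 600)
  rep <- score_spectra(sim, noisy, rois, snr_min = 10)
  td <- tidy(rep)
  weak <- which(td$origin == "B")
  expect_true(td$excluded[weak])
  expect_equal(overall_score(rep), mean(td$score[!td$excluded]))
  # with every region excluded the report is an error
  sparse <- peak_list(7.0, height = 0.5, width_hz = 1)
  rois_b <- regions_of_interest(sparse, 600)
  expect_error(score_spectra(toy_grid(sparse), noisy, rois_b, snr_min = 10),
               class = "spinmatch_error_empty_report")
})

test_that("similarity reports serialize as flat text", {
  pk <- toy_peaks()
  sp <- toy_grid(pk)
  rep <- score_spectra(sp, sp, regions_of_interest(pk, 600))
  path <- withr::local_tempfile(fileext = ".txt")
  write_report(rep, path)
  lines <- readLines(path)
  expect_match(lines[1], "^overall\t1\\.0")
  expect_match(lines[3], "^passed\ttrue$")
  expect_equal(sum(startsWith(lines, "roi\t")), nrow(rep) + 1L)
  g <- glance(rep)
  expect_named(g, c("overall", "threshold", "passed", "n_rois", "n_excluded"))
})
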