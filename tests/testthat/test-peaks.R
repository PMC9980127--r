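test_that("noise estimation is consistent for Gaussian noise and respects blocks", {
  # constant spectrum: noise floored at machine epsilon
  expect_true(all(estimate_noise(rep(5, 100), "mad", 4) <=
                  .Machine$double.eps))

  set.seed(81)
  x <- rnorm(5000, 0, 1.0)
  est <- estimate_noise(x, method = "mad", blocks = 10)
  expect_gt(stats::median(est), 0.9)
  expect_lt(stats::median(est), 1.1)

  # 'simple' = block mean absolute deviation, 500 control points honored
  x2 <- rnorm(2000)
  s <- estimate_noise(x2, method = "simple", blocks = 500)
  # oracle on one interior block
  edges <- floor(seq(0, 2000, length.out = 501))
  b <- 250
  v <- x2[(edges[b] + 1):edges[b + 1]]
  center <- (edges[b] + 1 + edges[b + 1]) / 2
  expect_equal(s[round(center)], mean(abs(v - mean(v))), tolerance = 0.35)
  expect_error(estimate_noise(x2, blocks = 3000), "exceeds")
})

test_that("peak detection finds planted peaks, nothing on flat spectra, monotone in snr", {
  expect_identical(nrow(detect_peaks(rep(0, 500), snr = 6)), 0L)
  expect_identical(nrow(detect_peaks(rep(2, 500), snr = 6)), 0L)

  set.seed(82)
  n <- 4000
  noise_sd <- 0.5
  x <- rnorm(n, 0, noise_sd)
  apex <- c(500, 1200, 2000, 2800, 3600)
  for (a in apex) x <- x + 20 * noise_sd * exp(-(seq_len(n) - a)^2 / (2 * 9))
  pk <- detect_peaks(x, snr = 6, window = 10, method = "mad", blocks = 8)
  hits <- vapply(apex, function(a) any(abs(pk$index - a) <= 1), logical(1))
  expect_true(all(hits))
  expect_identical(nrow(pk), 5L)

  # monotone: the peak set at higher snr is a subset of that at lower snr
  grid <- c(2.5, 4, 6, 9)
  sets <- lapply(grid, function(s)
    detect_peaks(x, snr = s, window = 10, method = "mad", blocks = 8)$index)
  for (i in seq_len(length(grid) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))

  # every reported peak is a strict local maximum (brute-force check)
  expect_true(all(pk$index %in% local_max_for_test(x, 10)))
})

test_that("reference building attaches frequency and mean-intensity statistics", {
  pk <- data.frame(mz = c(950, 1020), amplitude = c(10, 6), sd = 0.15)
  g <- profile_phantom(seed = 83, peaks = pk, axis_ppm = 20,
                       width = 5, height = 5, noise_sd = 0.05)
  ref <- build_reference(g$dataset, snr = 5, window = 10, method = "mad",
                         blocks = 10, tol_ppm = 200)
  expect_s3_class(ref, "msi_reference_peaks")
  for (m0 in pk$mz)
    expect_true(any(abs(ref$mz - m0) / m0 * 1e6 < 40))
  expect_true(all(ref$freq >= 0 & ref$freq <= 1))
  expect_true(all(ref$mean_intensity > 0))
  j <- which.min(abs(ref$mz - 950))
  expect_gt(ref$freq[j], 0.9)

  flat <- msi_dataset(matrix(1, 50, 4), mz = seq(100, 110, length.out = 50))
  expect_error(build_reference(flat, snr = 6), "lower snr")
})

test_that("frequency filtering removes rare peaks and keeps a brute-force recount", {
  ref <- data.frame(mz = c(900, 950, 1000, 1050),
                    freq = c(0.9, 0.005, 0.02, 0.5),
                    mean_intensity = c(3, 2, 0, 1))
  class(ref) <- c("msi_reference_peaks", "data.frame")
  expect_identical(filter_reference(ref, 0, -1)$mz, ref$mz)
  # planted rare peak at 0.5% frequency removed at the 1% threshold;
  # zero-mean peak removed by the mean filter
  kept <- filter_reference(ref, min_freq = 0.01, min_mean = 0)
  oracle <- ref$mz[ref$freq >= 0.01 & ref$mean_intensity > 0]
  expect_identical(kept$mz, oracle)
  expect_identical(kept$mz, c(900, 1050))
})

test_that("peak integration recovers the analytic Gaussian area", {
  # analytic peak: amplitude A, sd sigma in Da; area = A sigma sqrt(2 pi)
  A <- 12; sigma <- 0.1; m0 <- 1000
  axis <- seq(995, 1005, by = 0.005)
  y <- A * exp(-(axis - m0)^2 / (2 * sigma^2))
  d <- msi_dataset(matrix(y, ncol = 1), mz = axis)
  ref <- data.frame(mz = m0, freq = 1, mean_intensity = 1)
  out <- integrate_peak_areas(d, ref, tol_ppm = 1000)  # window >> sigma
  expect_lt(abs(msi_intensities(out)[1, 1] - A * sigma * sqrt(2 * pi)) /
            (A * sigma * sqrt(2 * pi)), 0.01)
  expect_true(out$centroided)

  # zero spectrum integrates to zero everywhere
  z <- msi_dataset(matrix(0, length(axis), 2), mz = axis)
  zz <- integrate_peak_areas(z, ref, tol_ppm = 500)
  expect_true(all(msi_intensities(zz) == 0))

  # +/-100 ppm window: half-width equals mz * 1e-4
  d2 <- msi_dataset(matrix(1, length(axis), 1), mz = axis)
  out2 <- integrate_peak_areas(d2, ref, tol_ppm = 100)
  # integrating a unit spectrum gives the window width
  expect_equal(msi_intensities(out2)[1, 1], 2 * m0 * 1e-4,
               tolerance = 0.05)
})

test_that("integration is linear and truncates overlapping windows at midpoints", {
  axis <- seq(990, 1010, by = 0.01)
  set.seed(84)
  a <- runif(length(axis)); b <- runif(length(axis))
  ref <- data.frame(mz = c(998, 1003), freq = 1, mean_intensity = 1)
  area <- function(v) msi_intensities(
    integrate_peak_areas(msi_dataset(matrix(v, ncol = 1), mz = axis),
                         ref, tol_ppm = 500))[, 1]
  expect_equal(area(a + b), area(a) + area(b), tolerance = 1e-9)

  # overlapping windows: truncated at the midpoint, no double counting
  wide <- data.frame(mz = c(999.9, 1000.1), freq = 1, mean_intensity = 1)
  flat <- msi_dataset(matrix(1, length(axis), 1), mz = axis)
  out <- integrate_peak_areas(flat, wide, tol_ppm = 5000)  # 5000 ppm ~ 5 Da
  tot <- sum(msi_intensities(out))
  # total cannot exceed the union of the two windows
  expect_lt(tot, 2 * 2 * 1000 * 5000e-6)
  prov <- out$provenance[[length(out$provenance)]]
  expect_true(prov$params$overlapping_windows_truncated)
})
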