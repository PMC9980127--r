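test_that("Gaussian smoothing matches a brute-force convolution oracle", {
  # constant signal is invariant (kernel renormalizes to 1 everywhere)
  expect_equal(smooth_gaussian(rep(3.5, 50), window = 9, sd = 2),
               rep(3.5, 50))

  # unit impulse: compare to direct renormalized truncated convolution
  n <- 41
  x <- numeric(n); x[21] <- 1
  got <- smooth_gaussian(x, window = 9, sd = 2)
  k <- exp(-(-4:4)^2 / (2 * 2^2))
  oracle <- vapply(seq_len(n), function(i) {
    j <- (i - 4):(i + 4)
    ok <- j >= 1 & j <= n
    sum(k[ok] * x[j[ok]]) / sum(k[ok])
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-14)

  expect_error(smooth_gaussian(x, window = 9, sd = 0), "sd")
})

test_that("an even smoothing window is rounded up and recorded in provenance", {
  g <- profile_phantom(seed = 51, peaks = data.frame(mz = 1000,
                                                     amplitude = 10,
                                                     sd = 0.2))
  d <- smooth_gaussian(g$dataset, window = 8, sd = 2)
  last <- d$provenance[[length(d$provenance)]]
  expect_identical(last$params$window, 9L)
  expect_identical(last$params$window_rounded_up_from, 8L)
  # vector form agrees with the odd window
  v <- msi_spectrum(g$dataset, 1)$intensity
  expect_identical(smooth_gaussian(v, 8, 2), smooth_gaussian(v, 9, 2))
})

test_that("smoothing preserves the total signal of interior peaks", {
  x <- numeric(500)
  x[240:260] <- dnorm(240:260, 250, 4) * 100
  sm <- smooth_gaussian(x, window = 9, sd = 2)
  expect_lt(abs(sum(sm) - sum(x)) / sum(x), 1e-3)
})

test_that("block-median baseline removal recovers offset and ramp baselines", {
  n <- 1000
  peaks <- numeric(n)
  apexes <- c(150, 420, 780)
  # compact-support peaks (zero outside +/-4 samples) so every 20-sample
  # block has a zero majority and the block medians vanish exactly
  for (a in apexes) {
    shape <- 10 * dnorm(seq_len(n), a, 1.3) * 3
    shape[abs(seq_len(n) - a) > 4] <- 0
    peaks <- peaks + shape
  }

  # flat zero baseline: peaks pass through
  out0 <- remove_baseline_median(peaks, blocks = 50)
  expect_equal(out0, peaks, tolerance = 1e-12)

  # constant offset: oracle recomputes the block medians of the offset signal
  c0 <- 2.5
  out1 <- remove_baseline_median(peaks + c0, blocks = 50)
  away <- abs(seq_len(n) - rep(apexes, each = n)[1:n])
  away_mask <- rep(TRUE, n)
  for (a in apexes) away_mask[abs(seq_len(n) - a) < 25] <- FALSE
  expect_lt(max(abs(out1[away_mask] - peaks[away_mask])), 1e-9)

  # linear ramp: piecewise-linear fit of a line is exact up to block-center
  # quantization; residual under 2% of the ramp range
  ramp <- seq(0, 4, length.out = n)
  out2 <- remove_baseline_median(peaks + ramp, blocks = 50)
  expect_lt(max(abs(out2[away_mask] - peaks[away_mask])), 0.02 * 4)

  expect_error(remove_baseline_median(peaks, blocks = n + 1), "exceeds")
})

test_that("TIC normalization equalizes sums to the pre-scaling mean and flags zero spectra", {
  m <- matrix(1, 4, 3)
  m[, 2] <- 2; m[, 3] <- 3   # TICs 4, 8, 12
  d <- matrix_dataset(m)
  nd <- normalize_tic(d)
  expect_equal(unname(colSums(msi_intensities(nd))), rep(8, 3))

  # already equal -> factor 1
  eq <- normalize_tic(matrix_dataset(matrix(2, 4, 5)))
  expect_equal(eq$pixels$tic_factor, rep(1, 5))

  # one all-zero spectrum among 10: flagged, unchanged
  set.seed(61)
  mm <- matrix(rexp(50), 5, 10)
  mm[, 4] <- 0
  dd <- normalize_tic(matrix_dataset(mm))
  expect_identical(which(dd$pixels$tic_zero), 4L)
  expect_equal(msi_intensities(dd)[, 4], rep(0, 5))
  expect_equal(sum(dd$pixels$tic_zero), 1)

  # idempotence: a second application is the identity within 1e-12
  dd2 <- normalize_tic(dd)
  expect_equal(msi_intensities(dd2), msi_intensities(dd),
               tolerance = 1e-12)
})

test_that("ppm binning builds the closed-form geometric axis and tiles it", {
  # axis spanning 100-102 Da at 10 ppm: closed-form bin count
  mzs <- seq(100, 102, length.out = 400)
  d <- msi_dataset(matrix(runif(800), 400, 2), mz = mzs)
  r <- resample_ppm_bins(d, ppm = 10)
  expect_identical(n_features(r),
                   as.integer(ceiling(log(102 / 100) / log(1 + 1e-5))))
  # adjacent axis points differ by exactly 10 ppm
  ratios <- diff(r$mz) / r$mz[-length(r$mz)]
  expect_lt(max(abs(ratios - 1e-5)), 1e-9 * 1e-5 + 1e-15)

  # bins tile [min, max): edges of bin i+1 start where bin i ends (exact)
  p <- 1e-5
  edges <- 100 * (1 + p)^(0:n_features(r))
  expect_identical(edges[-1][-n_features(r)],
                   edges[-c(1, length(edges))])

  # input already on the target axis: bin i holds sample i
  d2 <- msi_dataset(matrix(1:10, 10, 1), mz = 100 * (1 + p)^(0:9))
  r2 <- resample_ppm_bins(d2, ppm = 10)
  expect_equal(msi_intensities(r2)[1:9, 1], as.numeric(1:9))
})

test_that("ppm binning averages processed-mode samples onto the shared axis", {
  axes <- list(c(100.000, 100.0005, 100.002), c(100.0001, 100.003))
  ints <- list(c(1, 3, 10), c(5, 20))
  d <- msi_dataset(intensities = ints, axes = axes,
                   pixels = data.frame(run = "r", x = 0:1, y = 0L))
  r <- resample_ppm_bins(d, ppm = 10)
  expect_true(has_bin <- !is.null(r$mz))
  # first bin [100, 100.001): spectrum 1 has samples 1 and 3 -> mean 2
  expect_equal(msi_intensities(r)[1, 1], 2)
  expect_equal(msi_intensities(r)[1, 2], 5)
})
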