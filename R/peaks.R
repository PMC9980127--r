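# Noise estimation, peak detection, reference peak lists, frequency
# filtering, and peak-area integration onto a centroided dataset.

#' Per-sample noise level of a spectrum
#'
#' Estimates a slowly varying noise level by splitting the sample axis into
#' `blocks` equal-width blocks, computing a robust scale per block, and
#' linearly interpolating the block values at the block centers across the
#' full axis (constant extrapolation at the ends, floored at machine
#' epsilon).
#'
#' Methods: `"mad"` is 1.4826 * median(|x - median(x)|) per block (consistent
#' for Gaussian noise); `"simple"` is the block mean absolute deviation
#' mean(|x - mean(x)|).
#'
#' @param x numeric spectrum.
#' @param method `"mad"` or `"simple"`.
#' @param blocks number of noise-estimation blocks (<= length(x)).
#' @return numeric vector of per-sample noise levels, same length as `x`.
#' @export
estimate_noise <- function(x, method = c("mad", "simple"), blocks = 1L) {
  method <- match.arg(method)
  n <- length(x)
  blocks <- as.integer(blocks)
  if (blocks < 1L) stop("blocks must be >= 1")
  if (blocks > n) stop("blocks (", blocks, ") exceeds spectrum length (",
                       n, ")")
  edges <- floor(seq(0, n, length.out = blocks + 1L))
  centers <- numeric(blocks); lev <- numeric(blocks)
  for (b in seq_len(blocks)) {
    i0 <- edges[b] + 1L; i1 <- max(edges[b + 1L], i0)
    v <- x[i0:i1]
    centers[b] <- (i0 + i1) / 2
    lev[b] <- if (method == "mad") stats::mad(v, constant = 1.4826)
              else mean(abs(v - mean(v)))
  }
  out <- if (blocks == 1L) rep(lev, n)
         else stats::approx(centers, lev, xout = seq_len(n), rule = 2)$y
  pmax(out, .Machine$double.eps)
}

#' Detect peaks in a spectrum
#'
#' A sample is a peak when it is a strict local maximum over `+/- window`
#' samples (plateau ties resolve to the leftmost index) and its intensity is
#' at least `snr` times the local noise level.
#'
#' @param x numeric spectrum.
#' @param mz m/z axis matching `x` (optional; indices reported regardless).
#' @param snr signal-to-noise threshold (> 0).
#' @param window local-maximum half-width in samples (>= 1).
#' @param noise per-sample noise from [estimate_noise()] on the same
#'   spectrum; computed with defaults (`method`, `blocks`) when missing.
#' @param method,blocks forwarded to [estimate_noise()] when `noise` is
#'   missing.
#' @return data.frame with columns `index`, `mz`, `intensity`, `snr`.
#' @export
detect_peaks <- function(x, mz = NULL, snr = 6, window = 5L, noise = NULL,
                         method = "mad", blocks = 1L) {
  if (snr <= 0) stop("snr must be > 0")
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (is.null(noise)) noise <- estimate_noise(x, method, blocks)
  idx <- local_maxima(x, window)
  idx <- idx[x[idx] >= snr * noise[idx]]
  data.frame(index = idx,
             mz = if (is.null(mz)) rep(NA_real_, length(idx)) else mz[idx],
             intensity = x[idx],
             snr = x[idx] / noise[idx])
}

#' Build a reference peak list from the mean spectrum
#'
#' Detects peaks on the dataset mean spectrum and attaches dataset-level
#' statistics to each reference m/z: the detection frequency (fraction of
#' spectra with a local maximum within `tol_ppm` of the reference) and the
#' mean across spectra of the maximum intensity inside the window.
#'
#' @param dataset continuous-mode `msi_dataset` (profile).
#' @param snr,window,method,blocks peak-detection parameters (see
#'   [detect_peaks()]).
#' @param tol_ppm alignment tolerance used for the per-spectrum statistics.
#' @param plan a [chunk_plan()].
#' @return `msi_reference_peaks`: data.frame with columns `mz`, `freq`,
#'   `mean_intensity`.
#' @export
build_reference <- function(dataset, snr = 6, window = 5L, method = "mad",
                            blocks = 1L, tol_ppm = 15,
                            plan = chunk_plan()) {
  if (!has_shared_axis(dataset))
    stop("build_reference requires a shared m/z axis")
  mu <- mean_spectrum(dataset, plan)
  pk <- detect_peaks(mu, mz = dataset$mz, snr = snr, window = window,
                     method = method, blocks = blocks)
  if (nrow(pk) == 0L)
    stop("no peaks detected on the mean spectrum; try a lower snr")
  axis <- dataset$mz
  lo_idx <- vapply(pk$mz, function(m)
    findInterval(m * (1 - tol_ppm * 1e-6), axis) , numeric(1))
  hi_idx <- vapply(pk$mz, function(m) {
    h <- findInterval(m * (1 + tol_ppm * 1e-6), axis)
    min(h + 1, length(axis))
  }, numeric(1))
  lo_idx <- pmax(lo_idx, 1)
  stats_fn <- function(v, i) {
    lm_i <- local_maxima(v, window)
    present <- vapply(seq_len(nrow(pk)), function(j) {
      if (!length(lm_i)) return(0)
      any(abs(axis[lm_i] - pk$mz[j]) / pk$mz[j] * 1e6 <= tol_ppm)
    }, numeric(1))
    mx <- vapply(seq_len(nrow(pk)), function(j)
      max(v[lo_idx[j]:hi_idx[j]]), numeric(1))
    c(present, mx)
  }
  agg <- process_in_chunks(dataset, stats_fn, `+`, plan)
  n <- n_pixels(dataset)
  m <- nrow(pk)
  ref <- data.frame(mz = pk$mz,
                    freq = agg[seq_len(m)] / n,
                    mean_intensity = agg[m + seq_len(m)] / n)
  class(ref) <- c("msi_reference_peaks", "data.frame")
  ref
}

#' Filter a reference peak list
#'
#' Keeps references detected in at least `min_freq` of spectra AND with mean
#' intensity strictly above `min_mean`; order preserved. An empty result is
#' allowed.
#'
#' @param ref `msi_reference_peaks` from [build_reference()].
#' @param min_freq minimum detection frequency in `[0, 1]`.
#' @param min_mean mean-intensity threshold (kept if strictly greater).
#' @return filtered `msi_reference_peaks`.
#' @export
filter_reference <- function(ref, min_freq = 0.01, min_mean = 0) {
  keep <- ref$freq >= min_freq & ref$mean_intensity > min_mean
  out <- ref[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("msi_reference_peaks", "data.frame")
  out
}

#' Integrate peak areas at reference positions (peakBin)
#'
#' For every reference m/z and spectrum, integrates the profile intensity by
#' the trapezoidal rule over the samples within `+/- tol_ppm` of the
#' reference. Windows of adjacent references that would overlap are
#' truncated at the midpoint between the two reference m/z values so no
#' signal is double-counted; the truncation is recorded in provenance.
#'
#' @param dataset continuous-mode profile `msi_dataset`.
#' @param ref `msi_reference_peaks` (or numeric vector of reference m/z).
#' @param tol_ppm integration half-window in ppm.
#' @param plan a [chunk_plan()].
#' @return centroided `msi_dataset` whose features are the reference m/z.
#' @export
integrate_peak_areas <- function(dataset, ref, tol_ppm = 100,
                                 plan = chunk_plan()) {
  if (!has_shared_axis(dataset))
    stop("integration requires a shared m/z axis")
  if (dataset$centroided) stop("dataset is already centroided")
  mzs <- if (is.data.frame(ref)) ref$mz else as.numeric(ref)
  if (is.unsorted(mzs)) stop("reference m/z must be ascending")
  axis <- dataset$mz
  m <- length(mzs)
  lo <- mzs * (1 - tol_ppm * 1e-6)
  hi <- mzs * (1 + tol_ppm * 1e-6)
  merged <- FALSE
  if (m > 1L) {
    mid <- (mzs[-m] + mzs[-1]) / 2
    cut_hi <- hi[-m] > mid
    cut_lo <- lo[-1] < mid
    if (any(cut_hi | cut_lo)) merged <- TRUE
    hi[-m] <- pmin(hi[-m], mid)
    lo[-1] <- pmax(lo[-1], mid)
  }
  windows <- lapply(seq_len(m), function(j) {
    w <- which(axis >= lo[j] & axis <= hi[j])
    if (!length(w)) w <- which.min(abs(axis - mzs[j]))
    w
  })
  fn_area <- function(v, i) {
    vapply(windows, function(w) {
      if (length(w) < 2L) return(0)
      sum(diff(axis[w]) * (v[w[-length(w)]] + v[w[-1]]) / 2)
    }, numeric(1))
  }
  n <- n_pixels(dataset)
  out <- matrix(0, m, n)
  starts <- seq(1L, n, by = plan$chunk_size)
  for (s in starts) {
    idx <- s:min(s + plan$chunk_size - 1L, n)
    mat <- msi_intensities(dataset, idx)
    out[, idx] <- vapply(seq_along(idx),
                         function(j) fn_area(mat[, j], idx[j]), numeric(m))
  }
  feats <- data.frame(mz = mzs)
  if (is.data.frame(ref)) {
    if (!is.null(ref$freq)) feats$freq <- ref$freq
    if (!is.null(ref$mean_intensity)) feats$mean_intensity <- ref$mean_intensity
  }
  ds <- msi_dataset(intensities = out, mz = mzs, pixels = dataset$pixels,
                    features = feats, centroided = TRUE,
                    provenance = dataset$provenance)
  add_provenance(ds, "integrate_peak_areas",
                 list(tol_ppm = tol_ppm, n_ref = m,
                      overlapping_windows_truncated = merged))
}
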