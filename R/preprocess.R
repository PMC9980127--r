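# Per-spectrum profile conditioning: Gaussian smoothing, block-median
# baseline removal, TIC normalization, ppm binning onto a shared axis.

# Apply a vector -> vector transform to every spectrum, chunk-wise, and
# record one provenance step.
apply_spectra <- function(dataset, fn, name, params = list(),
                          plan = chunk_plan()) {
  n <- n_pixels(dataset)
  out <- NULL
  starts <- seq(1L, n, by = plan$chunk_size)
  for (s in starts) {
    idx <- s:min(s + plan$chunk_size - 1L, n)
    m <- msi_intensities(dataset, idx)
    res <- vapply(seq_along(idx), function(j) fn(m[, j], idx[j]),
                  numeric(nrow(m)))
    if (is.null(out)) out <- matrix(0, nrow(m), n)
    out[, idx] <- res
  }
  dataset <- replace_intensities(dataset, out)
  add_provenance(dataset, name, params)
}

#' Gaussian spectral smoothing
#'
#' Convolves each spectrum with a truncated, renormalized Gaussian kernel.
#' The window is a sample count and must be odd so the kernel is centered; an
#' even request is rounded up to the next odd value and the adjustment is
#' recorded in provenance. Near the spectrum edges the kernel is renormalized
#' over the available samples, so no padding values are invented and a
#' constant spectrum passes through unchanged.
#'
#' @param x numeric spectrum, or an `msi_dataset` (applied to every
#'   spectrum).
#' @param window kernel width in samples (odd, >= 3).
#' @param sd kernel standard deviation in samples (> 0).
#' @return smoothed spectrum or dataset.
#' @export
smooth_gaussian <- function(x, window = 9, sd = 2) {
  if (sd <= 0) stop("kernel sd must be > 0")
  window <- as.integer(window)
  adjusted <- FALSE
  if (window %% 2L == 0L) { window <- window + 1L; adjusted <- TRUE }
  if (window < 3L) stop("window must be >= 3 samples")
  if (inherits(x, "msi_dataset")) {
    params <- list(window = window, sd = sd)
    if (adjusted) params$window_rounded_up_from <- window - 1L
    return(apply_spectra(x, function(v, i) smooth_gaussian(v, window, sd),
                         "smooth_gaussian", params))
  }
  half <- (window - 1L) %/% 2L
  k <- exp(-(seq(-half, half))^2 / (2 * sd^2))
  n <- length(x)
  num <- numeric(n); den <- numeric(n)
  for (o in seq(-half, half)) {
    w <- k[o + half + 1L]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w * x[src[ok]]
    den[ok] <- den[ok] + w
  }
  num / den
}

#' Block-median baseline removal
#'
#' Estimates the baseline as the per-block median of the signal over
#' `blocks` equal-width blocks along the sample axis, linearly interpolated
#' at the block centers (constant extrapolation beyond the outer centers),
#' and subtracts it. The residual is clamped at zero: negative residuals
#' would poison downstream TIC normalization and displayed profile spectra
#' are nonnegative.
#'
#' @param x numeric spectrum, or an `msi_dataset`.
#' @param blocks number of blocks (1 <= blocks <= spectrum length).
#' @return baseline-subtracted spectrum or dataset.
#' @export
remove_baseline_median <- function(x, blocks = 750) {
  if (inherits(x, "msi_dataset"))
    return(apply_spectra(x, function(v, i) remove_baseline_median(v, blocks),
                         "remove_baseline_median", list(blocks = blocks)))
  n <- length(x)
  blocks <- as.integer(blocks)
  if (blocks < 1L) stop("blocks must be >= 1")
  if (blocks > n) stop("blocks (", blocks, ") exceeds spectrum length (",
                       n, ")")
  edges <- floor(seq(0, n, length.out = blocks + 1L))
  centers <- numeric(blocks); meds <- numeric(blocks)
  for (b in seq_len(blocks)) {
    i0 <- edges[b] + 1L; i1 <- max(edges[b + 1L], i0)
    centers[b] <- (i0 + i1) / 2
    meds[b] <- stats::median(x[i0:i1])
  }
  base <- if (blocks == 1L) rep(meds, n)
          else stats::approx(centers, meds, xout = seq_len(n), rule = 2)$y
  pmax(x - base, 0)
}

#' Total ion current normalization
#'
#' Rescales each spectrum so its intensity sum (TIC) equals the dataset mean
#' TIC computed before scaling, preserving the overall intensity scale.
#' All-zero spectra cannot be rescaled; they are left unchanged, flagged in
#' the pixel annotation column `tic_zero`, and excluded from the target mean
#' (so a second application is the identity).
#'
#' @param dataset an `msi_dataset` with nonnegative intensities.
#' @param plan a [chunk_plan()].
#' @return normalized dataset; per-pixel scale factors in the pixel column
#'   `tic_factor`.
#' @export
normalize_tic <- function(dataset, plan = chunk_plan()) {
  t <- tic(dataset, plan)
  zero <- t == 0
  target <- if (all(zero)) 0 else mean(t[!zero])
  fac <- ifelse(zero, 1, target / t)
  ds <- apply_spectra(dataset, function(v, i) v * fac[i], "normalize_tic",
                      list(method = "tic", target = target,
                           n_zero = sum(zero)), plan)
  ds$pixels$tic_factor <- fac
  ds$pixels$tic_zero <- zero
  ds
}

#' Resample spectra onto shared ppm-width bins
#'
#' Builds a geometric m/z axis from the global minimum to the global maximum
#' with consecutive points separated by `ppm` parts-per-million, and assigns
#' each spectrum's samples to bins `[m_i, m_{i+1})`. The bin value is the
#' mean of the samples falling in the bin (`aggregate = "mean"`, robust to
#' sampling density) or their sum (for centroided input); empty bins are 0.
#' The result is a continuous-mode dataset, the usual route from
#' processed-mode imzML to a matrix-shaped dataset.
#'
#' @param dataset an `msi_dataset` (continuous or processed mode).
#' @param ppm bin width in parts-per-million (> 0).
#' @param aggregate `"mean"` or `"sum"`.
#' @return continuous-mode `msi_dataset` on the shared binned axis.
#' @export
resample_ppm_bins <- function(dataset, ppm = 10, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (ppm <= 0) stop("ppm must be > 0")
  n <- n_pixels(dataset)
  if (n == 0L) stop("empty dataset")
  p <- ppm * 1e-6
  if (has_shared_axis(dataset)) {
    lo <- min(dataset$mz); hi <- max(dataset$mz)
  } else {
    rng <- range(unlist(lapply(seq_len(n), function(i) {
      a <- if (!is.null(dataset$axes)) dataset$axes[[i]]
           else msi_spectrum(dataset, i)$mz
      range(a)
    })))
    lo <- rng[1]; hi <- rng[2]
  }
  n_bins <- max(1L, as.integer(ceiling(log(hi / lo) / log1p(p))))
  axis <- lo * (1 + p)^(0:(n_bins))   # n_bins+1 edges; axis points = left edges
  new_mz <- axis[seq_len(n_bins)]
  bin_of <- function(mz) {
    b <- findInterval(mz, axis, rightmost.closed = FALSE)
    pmin(pmax(b, 1L), n_bins)   # clamp the global max into the last bin
  }
  out <- matrix(0, n_bins, n)
  for (i in seq_len(n)) {
    s <- msi_spectrum(dataset, i)
    b <- bin_of(s$mz)
    tot <- rowsum(s$intensity, b)
    idx <- as.integer(rownames(tot))
    if (aggregate == "mean") {
      cnt <- rowsum(rep(1, length(b)), b)
      out[idx, i] <- tot / cnt
    } else {
      out[idx, i] <- tot
    }
  }
  ds <- msi_dataset(intensities = out, mz = new_mz, pixels = dataset$pixels,
                    centroided = dataset$centroided,
                    provenance = dataset$provenance)
  add_provenance(ds, "resample_ppm_bins",
                 list(ppm = ppm, aggregate = aggregate, n_bins = n_bins))
}
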