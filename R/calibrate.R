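# Mass-axis correction: per-spectrum alignment to the mean spectrum and
# global re-calibration against internal calibrants.

# Strict local maxima of a vector over +/- halfwindow samples; on plateau
# ties the leftmost index wins.
local_maxima <- function(x, halfwindow = 5L) {
  n <- length(x)
  halfwindow <- as.integer(halfwindow)
  if (n <= 1L) return(integer(0))
  ok <- x > 0
  strict <- rep(FALSE, n)   # at least one strictly lower real neighbor,
                            # so a flat plateau spanning the window is not a peak
  for (o in seq_len(min(halfwindow, n - 1L))) {
    left <- c(rep(-Inf, o), x[seq_len(n - o)])        # x[i - o]
    right <- c(x[(o + 1L):n], rep(-Inf, o))           # x[i + o]
    ok <- ok & (x > left) & (x >= right)              # left-tie wins
    strict <- strict | (is.finite(left) & left < x) |
                       (is.finite(right) & right < x)
  }
  which(ok & strict)
}

# local maxima that clear a signal-to-noise threshold, so alignment anchors
# and calibrant matches never latch onto noise spikes
significant_maxima <- function(x, halfwindow = 5L, snr = 6, blocks = 10L) {
  blocks <- min(as.integer(blocks), length(x))
  noise <- estimate_noise(x, method = "mad", blocks = blocks)
  idx <- local_maxima(x, halfwindow)
  idx[x[idx] >= snr * noise[idx]]
}

# Piecewise-linear warp through matched (observed -> reference) m/z control
# points. The correction tapers linearly to zero over a margin of eight
# times the match tolerance beyond the outermost control points and is the
# identity outside that taper; since |correction| <= tol the tapered slope
# deviates from 1 by at most 1/8, keeping the warp strictly monotone and
# the re-interpolated peak areas near the taper essentially undistorted.
# Pairs that would break monotonicity of the corrected positions are
# dropped (largest correction first).
make_warp <- function(obs, ref, tol_ppm = 200) {
  o <- order(obs)
  obs <- obs[o]; ref <- ref[o]
  keep <- !duplicated(obs)
  obs <- obs[keep]; ref <- ref[keep]
  repeat {
    if (length(obs) < 2L || !is.unsorted(ref, strictly = TRUE)) break
    drop <- which.max(abs(ref - obs))
    obs <- obs[-drop]; ref <- ref[-drop]
  }
  if (length(obs)) {
    margin_lo <- 8 * tol_ppm * 1e-6 * obs[1]
    margin_hi <- 8 * tol_ppm * 1e-6 * obs[length(obs)]
    cp_x <- c(obs[1] - margin_lo, obs, obs[length(obs)] + margin_hi)
    cp_d <- c(0, ref - obs, 0)
  } else {
    cp_x <- numeric(0); cp_d <- numeric(0)
  }
  function(mz) {
    if (length(cp_x) == 0L) return(mz)
    delta <- stats::approx(cp_x, cp_d, xout = mz, rule = 1)$y
    delta[is.na(delta)] <- 0
    mz + delta
  }
}

#' Align spectra to the mean spectrum
#'
#' Reduces spectrum-to-spectrum mass jitter by warping each spectrum onto
#' the dataset mean spectrum. The `anchors` most intense local maxima of the
#' mean spectrum serve as reference peaks; in each spectrum, every anchor is
#' matched to its nearest local maximum within `tol_ppm`. Matched pairs
#' define a strictly monotone piecewise-linear warp of the spectrum's
#' sampling positions (tapering to the identity just beyond the outermost
#' matches), and intensities are linearly re-interpolated back onto the
#' shared axis. Spectra with fewer than two matches are left unwarped and
#' flagged.
#'
#' @param dataset continuous-mode `msi_dataset`.
#' @param tol_ppm match tolerance in ppm (> 0).
#' @param anchors number of reference peaks (>= 1).
#' @param halfwindow local-maximum half-width in samples.
#' @return list with `dataset` (aligned) and `shifts`, a per-pixel
#'   data.frame of matched anchor counts, median observed shift (ppm) and a
#'   `flagged` column for unwarped spectra.
#' @export
mz_align_to_mean <- function(dataset, tol_ppm = 200, anchors = 20,
                             halfwindow = 5L) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (anchors < 1) stop("anchors must be >= 1")
  if (!has_shared_axis(dataset)) stop("alignment requires a shared m/z axis")
  axis <- dataset$mz
  mu <- mean_spectrum(dataset)
  pk <- significant_maxima(mu, halfwindow)
  if (!length(pk)) stop("mean spectrum has no local maxima to anchor on")
  pk <- pk[order(mu[pk], decreasing = TRUE)]
  pk <- sort(pk[seq_len(min(anchors, length(pk)))])
  anchor_mz <- axis[pk]

  n <- n_pixels(dataset)
  rep_matched <- integer(n); rep_shift <- rep(NA_real_, n)
  flagged <- logical(n)
  fn <- function(v, i) {
    lm_i <- significant_maxima(v, halfwindow)
    if (!length(lm_i)) { flagged[i] <<- TRUE; return(v) }
    obs_mz <- axis[lm_i]
    matched_obs <- numeric(0); matched_ref <- numeric(0)
    for (a in anchor_mz) {
      d <- abs(obs_mz - a)
      k <- which.min(d)
      if (d[k] / a * 1e6 <= tol_ppm) {
        matched_obs <- c(matched_obs, obs_mz[k])
        matched_ref <- c(matched_ref, a)
      }
    }
    rep_matched[i] <<- length(matched_obs)
    if (length(matched_obs) < 2L) { flagged[i] <<- TRUE; return(v) }
    rep_shift[i] <<- stats::median((matched_ref - matched_obs) /
                                     matched_ref * 1e6)
    warp <- make_warp(matched_obs, matched_ref, tol_ppm)
    pos <- warp(axis)
    stats::approx(pos, v, xout = axis, rule = 2)$y
  }
  ds <- apply_spectra(dataset, fn, "mz_align_to_mean",
                      list(tol_ppm = tol_ppm, anchors = anchors))
  list(dataset = ds,
       shifts = data.frame(pixel = seq_len(n), matched = rep_matched,
                           median_shift_ppm = rep_shift, flagged = flagged))
}

#' Re-calibrate the mass axis against internal calibrants
#'
#' Corrects a systematic mass error using analytes of known m/z present in
#' the sample. Each calibrant is located as the nearest local maximum of the
#' mean spectrum within `tol_ppm`; a linear model of the observed mass error
#' versus m/z is fitted to the matched calibrants and inverted to correct
#' the shared axis globally (the per-spectrum jitter is assumed already
#' removed by [mz_align_to_mean()]).
#'
#' @param dataset continuous-mode `msi_dataset`.
#' @param calibrants ascending numeric vector of reference m/z values (Da),
#'   or a 1-column CSV path.
#' @param tol_ppm match tolerance in ppm.
#' @param halfwindow local-maximum half-width in samples.
#' @return list with `dataset` (corrected axis) and `report`, a per-calibrant
#'   data.frame of observed position and before/after residuals in ppm.
#' @export
recalibrate_internal <- function(dataset, calibrants, tol_ppm = 200,
                                 halfwindow = 5L) {
  if (is.character(calibrants))
    calibrants <- utils::read.csv(calibrants)[[1]]
  calibrants <- sort(as.numeric(calibrants))
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (!has_shared_axis(dataset))
    stop("re-calibration requires a shared m/z axis")
  axis <- dataset$mz
  mu <- mean_spectrum(dataset)
  pk <- significant_maxima(mu, halfwindow)
  if (!length(pk)) stop("mean spectrum has no local maxima")
  obs_idx <- integer(length(calibrants))
  matched <- logical(length(calibrants))
  for (k in seq_along(calibrants)) {
    d <- abs(axis[pk] - calibrants[k])
    j <- which.min(d)
    if (d[j] / calibrants[k] * 1e6 <= tol_ppm) {
      obs_idx[k] <- pk[j]; matched[k] <- TRUE
    }
  }
  if (sum(matched) < 2L)
    stop("fewer than 2 calibrants matched within ", tol_ppm, " ppm; ",
         "unmatched: ", paste(format(calibrants[!matched]), collapse = ", "))
  obs <- axis[obs_idx[matched]]
  ref <- calibrants[matched]
  before_ppm <- (obs - ref) / ref * 1e6
  fit <- stats::lm(err ~ mz, data = data.frame(err = obs - ref, mz = obs))
  correction <- stats::predict(fit, newdata = data.frame(mz = axis))
  new_axis <- axis - correction
  if (is.unsorted(new_axis, strictly = TRUE))
    stop("re-calibration produced a non-monotone axis; ",
         "check the calibrant list")
  after <- new_axis[obs_idx[matched]]
  after_ppm <- (after - ref) / ref * 1e6
  ds <- dataset
  ds$mz <- new_axis
  if (!is.null(ds$features)) ds$features$mz <- new_axis
  ds <- add_provenance(ds, "recalibrate_internal",
                       list(calibrants = calibrants, tol_ppm = tol_ppm,
                            coef = unname(stats::coef(fit))))
  report <- data.frame(calibrant = calibrants,
                       matched = matched,
                       observed = ifelse(matched, axis[obs_idx], NA_real_),
                       before_ppm = NA_real_, after_ppm = NA_real_)
  report$before_ppm[matched] <- before_ppm
  report$after_ppm[matched] <- after_ppm
  list(dataset = ds, report = report)
}
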