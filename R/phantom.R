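# Synthetic MSI phantom generator. Produces datasets with planted spatial
# segments, peaks, baseline, TIC variation, additive noise and mass drift,
# together with the planted ground truth, so every downstream method can be
# validated against known answers.

#' Declare a synthetic phantom
#'
#' A declarative recipe for [generate_phantom()]. Defaults emulate a small
#' MALDI-TOF-like acquisition: a 20 x 20 pixel grid, an m/z axis from 500 to
#' 2500 Da sampled at 100 ppm spacing, three rectangular tissue segments on
#' a background, 2-5 peaks per segment with Gaussian profiles, an
#' exponentially decaying baseline, 20% total-ion-current variation between
#' pixels and additive truncated-Gaussian noise.
#'
#' @param width,height grid size in pixels per run.
#' @param runs character vector of run identifiers.
#' @param segments list of segment recipes: each a list with `label`,
#'   `rect = c(xmin, xmax, ymin, ymax)` (inclusive, 0-based; `NULL` =
#'   background, i.e. all pixels not covered by another segment) and
#'   `peaks`, a data.frame with columns `mz` (Da), `amplitude`, `sd` (Da).
#' @param baseline list with `amplitude` and `decay` (exponential decay over
#'   the axis span; amplitude 0 disables).
#' @param noise_sd additive Gaussian noise sd (intensity units; spectra are
#'   truncated at 0 afterwards).
#' @param tic_range range of the per-pixel multiplicative TIC factor.
#' @param drift_ppm per-spectrum mass drift in ppm: a scalar (same constant
#'   drift everywhere), a vector of length `n_pixels`, or a range `c(lo, hi)`
#'   sampled uniformly per spectrum.
#' @param drift_linear if `TRUE`, the drift at m/z `m` scales linearly from
#'   0 at the axis minimum to the nominal value at the axis maximum
#'   (linear-in-m/z drift); otherwise constant in m/z.
#' @param mz_range axis range in Da.
#' @param axis_ppm axis sampling distance in ppm.
#' @param seed RNG seed (mandatory: phantoms are reproducible by contract).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(width = 20L, height = 20L, runs = "run0",
                         segments = NULL,
                         baseline = list(amplitude = 2, decay = 3),
                         noise_sd = 0.2,
                         tic_range = c(0.8, 1.2),
                         drift_ppm = 0,
                         drift_linear = FALSE,
                         mz_range = c(500, 2500),
                         axis_ppm = 100,
                         seed) {
  if (missing(seed)) stop("phantom_spec requires an explicit seed")
  if (is.null(segments)) {
    segments <- list(
      list(label = "background", rect = NULL,
           peaks = data.frame(mz = c(804.5, 1296.7), amplitude = c(4, 3),
                              sd = c(0.25, 0.4))),
      list(label = "A", rect = c(1, 8, 1, 8),
           peaks = data.frame(mz = c(804.5, 1046.5, 1570.6),
                              amplitude = c(4, 12, 8),
                              sd = c(0.25, 0.3, 0.45))),
      list(label = "B", rect = c(11, 18, 1, 8),
           peaks = data.frame(mz = c(804.5, 1296.7, 1865.0),
                              amplitude = c(4, 10, 9),
                              sd = c(0.25, 0.4, 0.55))),
      list(label = "C", rect = c(1, 18, 11, 18),
           peaks = data.frame(mz = c(804.5, 2211.1), amplitude = c(4, 11),
                              sd = c(0.25, 0.65))))
  }
  for (seg in segments) {
    if (any(seg$peaks$mz < mz_range[1] | seg$peaks$mz > mz_range[2]))
      stop("segment '", seg$label, "' has peaks outside the m/z range")
    if (any(seg$peaks$amplitude < 0)) stop("amplitudes must be >= 0")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 runs = runs, segments = segments, baseline = baseline,
                 noise_sd = noise_sd, tic_range = tic_range,
                 drift_ppm = drift_ppm, drift_linear = isTRUE(drift_linear),
                 mz_range = mz_range, axis_ppm = axis_ppm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom dataset with ground truth
#'
#' Renders the recipe into an [msi_dataset()] plus the planted truth. Each
#' pixel's profile is
#' `TIC_i * sum_peaks A exp(-(m - m0 (1 + drift_i(m) 1e-6))^2 / (2 sd^2))
#'  + baseline(m) + noise`, truncated at 0. Drift displaces the peak
#' positions (instrument-like), not the intensities. Deterministic given the
#' spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param output `"profile"` for a continuous profile dataset, or
#'   `"centroided"` for a peak-table dataset whose features are the planted
#'   peak m/z (amplitude * TIC + noise, no baseline or drift).
#' @return list with `dataset` (an `msi_dataset`) and `truth` (list with
#'   `segment` per-pixel labels, `peaks` table, `drift_ppm` per pixel,
#'   `tic_factor` per pixel).
#' @export
generate_phantom <- function(spec, output = c("profile", "centroided")) {
  output <- match.arg(output)
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    grids <- lapply(spec$runs, function(run)
      data.frame(run = run,
                 x = rep(0:(spec$width - 1L), times = spec$height),
                 y = rep(0:(spec$height - 1L), each = spec$width),
                 stringsAsFactors = FALSE))
    px <- do.call(rbind, grids)
    n <- nrow(px)

    seg_label <- rep(NA_character_, n)
    background <- NULL
    for (seg in spec$segments) {
      if (is.null(seg$rect)) { background <- seg$label; next }
      inside <- px$x >= seg$rect[1] & px$x <= seg$rect[2] &
                px$y >= seg$rect[3] & px$y <= seg$rect[4]
      seg_label[inside] <- seg$label
    }
    if (!is.null(background)) seg_label[is.na(seg_label)] <- background
    seg_peaks <- stats::setNames(
      lapply(spec$segments, `[[`, "peaks"),
      vapply(spec$segments, `[[`, character(1), "label"))

    tic_f <- stats::runif(n, spec$tic_range[1], spec$tic_range[2])
    drift <- if (length(spec$drift_ppm) == n) spec$drift_ppm
             else if (length(spec$drift_ppm) == 2L &&
                      spec$drift_ppm[1] != spec$drift_ppm[2])
               stats::runif(n, spec$drift_ppm[1], spec$drift_ppm[2])
             else rep(spec$drift_ppm[1], n)

    truth <- list(segment = seg_label,
                  peaks = do.call(rbind, lapply(names(seg_peaks), function(l)
                    cbind(segment = l, seg_peaks[[l]]))),
                  drift_ppm = drift, tic_factor = tic_f)

    if (output == "centroided") {
      all_mz <- sort(unique(unlist(lapply(seg_peaks, `[[`, "mz"))))
      amp <- matrix(0, length(all_mz), n)
      for (l in names(seg_peaks)) {
        sel <- which(seg_label == l)
        pk <- seg_peaks[[l]]
        rows <- match(pk$mz, all_mz)
        amp[rows, sel] <- pk$amplitude
      }
      intens <- sweep(amp, 2, tic_f, `*`) +
        matrix(stats::rnorm(length(all_mz) * n, 0, spec$noise_sd),
               length(all_mz), n)
      intens <- pmax(intens, 0)
      ds <- msi_dataset(intensities = intens, mz = all_mz, pixels = px,
                        centroided = TRUE)
      ds$pixels$segment <- seg_label
      ds <- add_provenance(ds, "generate_phantom",
                           list(seed = spec$seed, output = output))
      return(list(dataset = ds, truth = truth))
    }

    p <- spec$axis_ppm * 1e-6
    lo <- spec$mz_range[1]; hi <- spec$mz_range[2]
    n_axis <- as.integer(ceiling(log(hi / lo) / log1p(p)))
    axis <- lo * (1 + p)^(0:(n_axis - 1L))
    span <- hi - lo
    base <- if (spec$baseline$amplitude > 0)
      spec$baseline$amplitude *
        exp(-spec$baseline$decay * (axis - lo) / span)
    else numeric(length(axis))

    intens <- matrix(0, length(axis), n)
    for (i in seq_len(n)) {
      pk <- seg_peaks[[seg_label[i]]]
      y <- numeric(length(axis))
      for (r in seq_len(nrow(pk))) {
        m0 <- pk$mz[r]
        d_at_m0 <- if (spec$drift_linear)
          drift[i] * (m0 - lo) / span else drift[i]
        center <- m0 * (1 + d_at_m0 * 1e-6)
        y <- y + pk$amplitude[r] *
          exp(-(axis - center)^2 / (2 * pk$sd[r]^2))
      }
      y <- tic_f[i] * y + base
      if (spec$noise_sd > 0)
        y <- y + stats::rnorm(length(axis), 0, spec$noise_sd)
      intens[, i] <- pmax(y, 0)
    }
    ds <- msi_dataset(intensities = intens, mz = axis, pixels = px)
    ds$pixels$segment <- seg_label
    ds <- add_provenance(ds, "generate_phantom",
                         list(seed = spec$seed, output = output))
    list(dataset = ds, truth = truth)
  })
}

#' Write a phantom (or any dataset) as an on-disk fixture
#'
#' Writes the imzML/ibd pair plus, when a truth object is supplied, plain
#' CSV files of the planted per-pixel truth alongside.
#'
#' @param dataset an `msi_dataset`.
#' @param path output `.imzML` path.
#' @param mode `"continuous"` or `"processed"`.
#' @param precision 32 or 64.
#' @param truth optional truth list from [generate_phantom()].
#' @return invisibly, the list of files written.
#' @export
write_fixture <- function(dataset, path, mode = "continuous",
                          precision = 64, truth = NULL) {
  res <- write_imzml(dataset, path, mode = mode, precision = precision)
  files <- c(res$imzml, res$ibd)
  if (!is.null(truth)) {
    base <- sub("\\.[iI][mM][zZ][mM][lL]$", "", path)
    tp <- paste0(base, "_truth_pixels.csv")
    utils::write.csv(
      data.frame(dataset$pixels[c("run", "x", "y")],
                 segment = truth$segment,
                 drift_ppm = truth$drift_ppm,
                 tic_factor = truth$tic_factor),
      tp, row.names = FALSE)
    pp <- paste0(base, "_truth_peaks.csv")
    utils::write.csv(truth$peaks, pp, row.names = FALSE)
    files <- c(files, tp, pp)
  }
  invisible(files)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two clusterings; 1 for identical
#' partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
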