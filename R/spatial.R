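# Pixel neighborhoods and spatial weights shared by the segmentation
# methods, plus ion-image rendering with smoothing and contrast options.

#' Spatial neighborhood weights
#'
#' Builds, for every pixel, its neighbor list (pixels of the same run within
#' Chebyshev distance `r` on the grid, self included) and normalized weights.
#' The Gaussian part is `alpha = exp(-d^2 / (2 sigma^2))` with `d` the
#' Euclidean grid distance and `sigma = (2r + 1)/4`. Adaptive weights
#' additionally damp neighbors whose spectra differ:
#' `beta = exp(-delta^2 / (2 lambda^2))` with `delta` the Euclidean distance
#' between the neighbor's and the center pixel's spectra and `lambda` the
#' maximum such distance in the neighborhood (floored at machine epsilon).
#' Weights are renormalized to sum to 1 per pixel.
#'
#' @param dataset an `msi_dataset`.
#' @param r neighborhood radius in grid units (>= 0).
#' @param method `"gaussian"` or `"adaptive"`.
#' @param spectra optional feature-by-pixel matrix used for the adaptive
#'   term; defaults to the dataset intensities (required for adaptive).
#' @return `msi_spatial_weights`: list with `r`, `method`, `neighbors`
#'   (integer index lists) and `weights` (matching numeric lists).
#' @export
compute_spatial_weights <- function(dataset, r = 1,
                                    method = c("gaussian", "adaptive"),
                                    spectra = NULL) {
  method <- match.arg(method)
  if (r < 0) stop("r must be >= 0")
  px <- dataset$pixels
  n <- nrow(px)
  if (method == "adaptive" && is.null(spectra)) {
    if (is.null(dataset$intensities))
      stop("adaptive weights need spectra; none available")
    spectra <- msi_intensities(dataset)
  }
  sigma <- (2 * r + 1) / 4
  # grid hash per run for O(neighborhood) lookup
  key <- paste(px$run, px$x, px$y, sep = "\r")
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(key[i], i, envir = lookup)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  neighbors <- vector("list", n)
  weights <- vector("list", n)
  for (i in seq_len(n)) {
    kx <- px$x[i] + offs$dx; ky <- px$y[i] + offs$dy
    kk <- paste(px$run[i], kx, ky, sep = "\r")
    nb <- unlist(lapply(kk, function(k)
      if (exists(k, envir = lookup, inherits = FALSE))
        get(k, envir = lookup) else NULL))
    d2 <- (px$x[nb] - px$x[i])^2 + (px$y[nb] - px$y[i])^2
    w <- exp(-d2 / (2 * sigma^2))
    if (method == "adaptive") {
      delta2 <- colSums((spectra[, nb, drop = FALSE] - spectra[, i])^2)
      lambda2 <- max(max(delta2), .Machine$double.eps)
      w <- w * exp(-delta2 / (2 * lambda2))
    }
    neighbors[[i]] <- nb
    weights[[i]] <- w / sum(w)
  }
  structure(list(r = r, method = method, neighbors = neighbors,
                 weights = weights),
            class = "msi_spatial_weights")
}

# x_smooth[, i] = sum_{i'} w_{ii'} x[, i']
smooth_by_weights <- function(X, weights) {
  out <- matrix(0, nrow(X), ncol(X))
  for (i in seq_along(weights$neighbors)) {
    nb <- weights$neighbors[[i]]
    out[, i] <- X[, nb, drop = FALSE] %*% weights$weights[[i]]
  }
  out
}

#' Render an ion image
#'
#' Places one feature's pixel intensities on each run's (x, y) grid and
#' applies optional smoothing, contrast enhancement, and linear (min-max)
#' normalization to `[0, 1]`.
#'
#' Smoothing: `"gaussian"` convolves with a 2D kernel of scale
#' `sigma = (2r+1)/4`; `"adaptive"` is bilateral, damping neighbors with
#' dissimilar intensity exactly as in [compute_spatial_weights()]. Contrast:
#' `"suppression"` clips above the 99th percentile before scaling (hot-spot
#' suppression); `"histogram"` maps intensities to their normalized ranks
#' (histogram equalization). A constant image has no range to scale; it is
#' rendered as all zeros and flagged via the `degenerate` attribute.
#'
#' @param dataset an `msi_dataset`.
#' @param mz query m/z (Da).
#' @param tol_ppm feature-resolution tolerance (ppm).
#' @param smoothing `"none"`, `"gaussian"` or `"adaptive"`.
#' @param contrast `"none"`, `"suppression"` or `"histogram"`.
#' @param r smoothing radius in pixels.
#' @param suppression_quantile clip quantile for `"suppression"`.
#' @return named list of numeric matrices (rows = y, cols = x), one per run;
#'   pixels absent from the grid are `NA`.
#' @export
render_ion_image <- function(dataset, mz, tol_ppm = 100,
                             smoothing = c("none", "gaussian", "adaptive"),
                             contrast = c("none", "suppression", "histogram"),
                             r = 1, suppression_quantile = 0.99) {
  smoothing <- match.arg(smoothing)
  contrast <- match.arg(contrast)
  j <- resolve_feature(dataset, mz, tol_ppm)
  vals <- as.numeric(msi_intensities(dataset)[j, ])
  px <- dataset$pixels
  out <- list()
  for (run in unique(px$run)) {
    sel <- px$run == run
    xs <- px$x[sel]; ys <- px$y[sel]; v <- vals[sel]
    img <- matrix(NA_real_, nrow = max(ys) + 1L, ncol = max(xs) + 1L)
    img[cbind(ys + 1L, xs + 1L)] <- v
    if (smoothing != "none")
      img <- smooth_image(img, r = r, adaptive = smoothing == "adaptive")
    obs <- !is.na(img)
    if (contrast == "suppression") {
      q <- stats::quantile(img[obs], suppression_quantile, names = FALSE)
      img[obs] <- pmin(img[obs], q)
    } else if (contrast == "histogram") {
      img[obs] <- (rank(img[obs], ties.method = "average") - 0.5) /
        sum(obs)
    }
    rng <- range(img[obs])
    if (diff(rng) == 0) {
      img[obs] <- 0
      attr(img, "degenerate") <- TRUE
    } else {
      img[obs] <- (img[obs] - rng[1]) / diff(rng)
    }
    out[[as.character(run)]] <- img
  }
  out
}

# 2D kernel smoothing on a grid with NA holes; bilateral when adaptive.
smooth_image <- function(img, r = 1, adaptive = FALSE) {
  sigma <- (2 * r + 1) / 4
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(img[i, j])) next
    i0 <- max(1, i - r); i1 <- min(nr, i + r)
    j0 <- max(1, j - r); j1 <- min(nc, j + r)
    patch <- img[i0:i1, j0:j1]
    di <- outer((i0:i1) - i, rep(0, j1 - j0 + 1), `+`)
    dj <- outer(rep(0, i1 - i0 + 1), (j0:j1) - j, `+`)
    w <- exp(-(di^2 + dj^2) / (2 * sigma^2))
    if (adaptive) {
      delta2 <- (patch - img[i, j])^2
      lambda2 <- max(max(delta2, na.rm = TRUE), .Machine$double.eps)
      w <- w * exp(-delta2 / (2 * lambda2))
    }
    ok <- !is.na(patch)
    out[i, j] <- sum(w[ok] * patch[ok]) / sum(w[ok])
  }
  out
}

#' Write an image matrix as CSV (and optionally PNG)
#' @param img numeric matrix from [render_ion_image()].
#' @param path output path; `.png` requires the `png` package, anything else
#'   is written as a headerless CSV matrix.
#' @return invisibly, `path`.
#' @export
write_image <- function(img, path) {
  if (grepl("\\.png$", path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package")
    m <- img; m[is.na(m)] <- 0
    png::writePNG(m, path)
  } else {
    utils::write.table(img, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
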