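# Spatially-aware Dirichlet Gaussian mixture model for single-ion
# segmentation. A univariate Gaussian mixture is fitted by EM to one
# feature's pixel intensities, with the mixing proportions varying per pixel:
# each pixel's priors are the spatially smoothed responsibilities of its
# neighborhood, regularized by a Dirichlet pseudo-count, so segments are
# spatially coherent without a hard spatial model.

#' Single-ion segmentation by spatial Dirichlet Gaussian mixture
#'
#' EM on the intensities `x_i` of the feature nearest `mz`:
#' E-step `gamma_ik ~ pi_ik phi(x_i; mu_k, sigma_k^2)`; M-step updates
#' `mu_k`, `sigma_k` from responsibility-weighted moments; prior update
#' `pi_ik = (sum_{i'} w_{ii'} gamma_{i'k} + a) / (1 + k a)` with `w` the
#' spatial weights and `a` the Dirichlet pseudo-count. With annealing on,
#' responsibilities are sharpened by a temperature `T` decreasing
#' geometrically from 2 to 1 (ratio 0.9) before the M-step, which helps
#' escape poor initializations at the cost of non-monotone early iterations.
#' Components initialize at the `(2q - 1)/(2k)` intensity quantiles with
#' pooled-sd spread and a small seeded jitter for symmetry breaking.
#'
#' @param dataset an `msi_dataset`.
#' @param mz query m/z (Da).
#' @param tol_ppm feature-resolution tolerance (ppm).
#' @param r spatial radius for the prior smoothing (0 = no smoothing).
#' @param k number of mixture components (>= 1).
#' @param annealing logical; deterministic-annealing on/off.
#' @param dirichlet_a Dirichlet pseudo-count (> 0).
#' @param max_iter,tol EM controls; `tol` is the relative log-likelihood
#'   change declaring convergence.
#' @param seed RNG seed (initialization jitter).
#' @param weights optional precomputed `msi_spatial_weights`.
#' @return `msi_dgmm_fit`: list with `mu`, `sigma`, `priors` (pixels x k),
#'   `responsibilities`, `labels`, `loglik_trace`, `sigma_floored`.
#' @export
dgmm_segment <- function(dataset, mz, tol_ppm = 100, r = 1, k = 2,
                         annealing = FALSE, dirichlet_a = 1e-2,
                         max_iter = 200L, tol = 1e-8, seed = 1L,
                         weights = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (dirichlet_a <= 0) stop("dirichlet_a must be > 0")
  j <- resolve_feature(dataset, mz, tol_ppm)
  x <- as.numeric(msi_intensities(dataset)[j, ])
  n <- length(x)
  if (n < k) stop("fewer pixels (", n, ") than components (", k, ")")
  if (is.null(weights) && r > 0)
    weights <- compute_spatial_weights(dataset, r = r, method = "gaussian")
  sigma_floor <- 1e-6 * max(diff(range(x)), .Machine$double.eps)

  if (k == 1L) {
    mu <- mean(x); sig <- stats::sd(x)
    if (is.na(sig) || sig < sigma_floor) sig <- sigma_floor
    ll <- sum(stats::dnorm(x, mu, sig, log = TRUE))
    return(structure(list(
      mu = mu, sigma = sig, priors = matrix(1, n, 1),
      responsibilities = matrix(1, n, 1),
      labels = factor(rep(1L, n)), loglik_trace = ll,
      sigma_floored = sig == sigma_floor,
      params = list(mz = mz, r = r, k = k, annealing = annealing,
                    dirichlet_a = dirichlet_a, seed = seed)),
      class = "msi_dgmm_fit"))
  }

  q <- (2 * seq_len(k) - 1) / (2 * k)
  mu <- as.numeric(stats::quantile(x, q, names = FALSE))
  mu <- with_seed(seed, mu + stats::rnorm(k, 0, 1e-3 * max(stats::sd(x),
                                                           sigma_floor)))
  sig <- rep(max(stats::sd(x), sigma_floor), k)
  pi_ik <- matrix(1 / k, n, k)
  Tem <- if (annealing) 2 else 1
  ll_trace <- numeric(0)
  floored <- FALSE
  prev_ll <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(c.)
      stats::dnorm(x, mu[c.], sig[c.]), numeric(n))
    num <- pi_ik * dens
    rs <- rowSums(num)
    rs[rs == 0] <- .Machine$double.xmin
    gamma <- num / rs
    if (annealing && Tem > 1 + 1e-12) {
      g <- gamma^(1 / Tem)
      gamma <- g / rowSums(g)
      Tem <- max(1, Tem * 0.9)
    }
    w_k <- colSums(gamma)
    mu <- colSums(gamma * x) / w_k
    sig <- sqrt(colSums(gamma * (outer(x, mu, `-`))^2) / w_k)
    low <- sig < sigma_floor
    if (any(low)) { sig[low] <- sigma_floor; floored <- TRUE }
    g_sm <- if (!is.null(weights)) t(smooth_by_weights(t(gamma), weights))
            else gamma
    pi_ik <- (g_sm + dirichlet_a) / (1 + k * dirichlet_a)
    pi_ik <- pi_ik / rowSums(pi_ik)
    dens <- vapply(seq_len(k), function(c.)
      stats::dnorm(x, mu[c.], sig[c.]), numeric(n))
    ll <- sum(log(pmax(rowSums(pi_ik * dens), .Machine$double.xmin)))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(prev_ll) &&
        abs(ll - prev_ll) <= tol * (abs(prev_ll) + 1e-12) &&
        (!annealing || Tem <= 1 + 1e-12)) break
    prev_ll <- ll
  }
  dens <- vapply(seq_len(k), function(c.)
    stats::dnorm(x, mu[c.], sig[c.]), numeric(n))
  num <- pi_ik * dens
  rs <- rowSums(num); rs[rs == 0] <- .Machine$double.xmin
  gamma <- num / rs
  structure(list(
    mu = mu, sigma = sig, priors = pi_ik, responsibilities = gamma,
    labels = factor(max.col(gamma, ties.method = "first")),
    loglik_trace = ll_trace, sigma_floored = floored,
    params = list(mz = mz, r = r, k = k, annealing = annealing,
                  dirichlet_a = dirichlet_a, seed = seed)),
    class = "msi_dgmm_fit")
}
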