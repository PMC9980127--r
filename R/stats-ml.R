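# Co-localization ranking, group-then-test class comparison, PCA, and
# NIPALS PLS-DA.

#' Co-localization ranking against a query ion
#'
#' Ranks every feature by the Pearson correlation of its pixel-intensity
#' vector with the query feature's, descending. The query feature itself is
#' listed first with correlation exactly 1 (self-correlation is 1 by
#' definition; computed values are clamped to `[-1, 1]`).
#'
#' @param dataset centroided (or profile) `msi_dataset`.
#' @param mz query m/z (Da).
#' @param tol_ppm feature-resolution tolerance (ppm).
#' @param top_n maximum rows returned.
#' @return data.frame with `mz` and `correlation`, query first.
#' @export
colocalize <- function(dataset, mz, tol_ppm = Inf, top_n = 20L) {
  j <- resolve_feature(dataset, mz, tol_ppm)
  X <- msi_intensities(dataset)
  q <- X[j, ]
  if (stats::sd(q) == 0)
    stop("query feature has zero variance across pixels")
  r <- suppressWarnings(as.numeric(stats::cor(t(X), q)))
  r[is.na(r)] <- 0           # zero-variance decoys are uncorrelated
  r <- pmin(pmax(r, -1), 1)
  r[j] <- 1
  ord <- order(r, decreasing = TRUE)
  ord <- c(j, setdiff(ord, j))
  ord <- utils::head(ord, top_n)
  data.frame(mz = dataset$features$mz[ord], correlation = r[ord])
}

#' Class comparison on group means (differential abundance)
#'
#' Tests, per feature, whether the two levels of `condition` differ, with
#' the biological unit of replication being the *group* (sample, ROI or
#' tissue core), not the pixel: pixel intensities are first averaged within
#' each group, then a Welch two-sample t-test compares the group means
#' between the condition levels, and Benjamini-Hochberg adjustment is
#' applied across features. Testing pixels directly would pseudoreplicate
#' massively; this is refused by construction.
#'
#' @param dataset an `msi_dataset`.
#' @param group_unit pixel annotation column naming the replication unit.
#' @param condition pixel annotation column with exactly 2 levels, constant
#'   within each group.
#' @return data.frame, one row per feature: `mz`, per-level means, `effect`
#'   (difference of condition-level means of group means), `t`, `df`, `p`,
#'   `p_adj`.
#' @export
means_test <- function(dataset, group_unit, condition) {
  px <- dataset$pixels
  for (col in c(group_unit, condition))
    if (!col %in% names(px)) stop("unknown annotation column '", col, "'")
  grp <- as.character(px[[group_unit]])
  cond <- as.character(px[[condition]])
  keep <- !is.na(grp) & !is.na(cond)
  grp <- grp[keep]; cond <- cond[keep]
  lev <- sort(unique(cond))
  if (length(lev) != 2L)
    stop("condition must have exactly 2 levels; found ",
         length(lev))
  cond_of_group <- tapply(cond, grp, function(v) {
    u <- unique(v)
    if (length(u) > 1L)
      stop("condition is not constant within group; offending group has ",
           "levels ", paste(u, collapse = ", "))
    u
  })
  g_lev <- names(cond_of_group)
  n1 <- sum(cond_of_group == lev[1]); n2 <- sum(cond_of_group == lev[2])
  if (n1 < 2L || n2 < 2L)
    stop("each condition level needs >= 2 groups (got ", n1, " and ", n2,
         "); pixel-level testing would pseudoreplicate")
  X <- msi_intensities(dataset)[, keep, drop = FALSE]
  # features x groups matrix of within-group pixel means
  gm <- vapply(g_lev, function(g)
    rowMeans(X[, grp == g, drop = FALSE]), numeric(nrow(X)))
  a <- gm[, cond_of_group == lev[1], drop = FALSE]
  b <- gm[, cond_of_group == lev[2], drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               n1 + n2 - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df), 1)
  out <- data.frame(mz = dataset$features$mz,
                    mean_1 = m1, mean_2 = m2,
                    effect = m1 - m2, t = t_stat, df = df, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"))
  names(out)[2:3] <- paste0("mean_", lev)
  out
}

#' Principal component analysis of the intensity matrix
#'
#' @param dataset an `msi_dataset`.
#' @param ncomp number of components (<= min(features, pixels)).
#' @return list with `scores` (pixels x ncomp), `loadings` (features x
#'   ncomp, orthonormal), `explained_variance` (non-increasing fractions).
#' @export
pca <- function(dataset, ncomp = 2L) {
  X <- t(msi_intensities(dataset))   # pixels x features
  ncomp <- as.integer(ncomp)
  if (ncomp > min(dim(X)))
    stop("ncomp exceeds min(features, pixels)")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = pr$x[, seq_len(ncomp), drop = FALSE],
       loadings = pr$rotation[, seq_len(ncomp), drop = FALSE],
       explained_variance =
         (pr$sdev^2 / sum(pr$sdev^2))[seq_len(ncomp)])
}

#' PLS-DA by NIPALS
#'
#' Fits PLS2 regression of the one-hot class indicator matrix on the
#' mean-centered intensity matrix by the NIPALS algorithm, extracting
#' `ncomp` mutually orthogonal score vectors. Prediction is the argmax of
#' the regressed class scores (ties to the first class in training order).
#' Deterministic given the data.
#'
#' @param dataset centroided `msi_dataset`.
#' @param labels per-pixel class labels.
#' @param ncomp number of latent components (1 <= ncomp <= rank of the
#'   centered matrix).
#' @return `msi_pls_model`: list with `weights`, `loadings`, `y_loadings`,
#'   `scores`, `coefficients`, centering means and the class map.
#' @export
pls_fit <- function(dataset, labels, ncomp = 2L) {
  labels <- as.factor(labels)
  classes <- levels(labels)
  X <- t(msi_intensities(dataset))               # n x p
  Y <- 1 * outer(labels, classes, `==`)          # n x K one-hot
  colnames(Y) <- classes
  n <- nrow(X); p <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("ncomp must be >= 1")
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  rk <- qr(Xc)$rank
  if (ncomp > rk)
    stop("ncomp (", ncomp, ") exceeds the rank of the centered data (",
         rk, ")")
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, ncol(Y), ncomp); Tm <- matrix(0, n, ncomp)
  Xd <- Xc; Yd <- Yc
  for (h in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, n)
    for (iter in seq_len(500L)) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      t_h <- Xd %*% w
      q <- crossprod(Yd, t_h) / sum(t_h^2)
      u_new <- Yd %*% q / sum(q^2)
      if (sqrt(sum((t_h - t_old)^2)) < 1e-12 * sqrt(sum(t_h^2))) break
      t_old <- t_h; u <- u_new
    }
    p_h <- crossprod(Xd, t_h) / sum(t_h^2)
    W[, h] <- w; P[, h] <- p_h; Q[, h] <- q; Tm[, h] <- t_h
    Xd <- Xd - t_h %*% t(p_h)
    Yd <- Yd - t_h %*% t(q)
  }
  B <- W %*% solve(t(P) %*% W, t(Q))
  structure(list(classes = classes, ncomp = ncomp, weights = W,
                 loadings = P, y_loadings = Q, scores = Tm,
                 coefficients = B, x_mean = x_mean, y_mean = y_mean,
                 mz = dataset$features$mz),
            class = "msi_pls_model")
}

#' @rdname pls_fit
#' @param model `msi_pls_model`.
#' @return for `pls_predict`: list with `labels` and `scores` (regressed
#'   class scores, n x K).
#' @export
pls_predict <- function(model, dataset) {
  X <- t(msi_intensities(dataset))
  if (ncol(X) != length(model$x_mean))
    stop("dataset feature count does not match the model")
  Yhat <- sweep(X, 2, model$x_mean) %*% model$coefficients
  Yhat <- sweep(Yhat, 2, model$y_mean, `+`)
  idx <- max.col(Yhat, ties.method = "first")
  list(labels = factor(model$classes[idx], levels = model$classes),
       scores = Yhat)
}
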