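# Spatial shrunken centroids: nearest-shrunken-centroid statistics combined
# with spatial smoothing of pixel spectra, for unsupervised segmentation and
# supervised classification of MSI data.
#
# Model statistics, given per-pixel class labels on the feature-by-pixel
# matrix X (n pixels, classes k of size n_k):
#   x_bar_j       overall feature mean
#   x_bar_kj      class feature mean
#   s_j           pooled within-class standard deviation
#   s0            median_j s_j (offset guarding tiny dispersions)
#   m_k           sqrt(1/n_k - 1/n)
#   d_kj          (x_bar_kj - x_bar_j) / (m_k (s_j + s0))
#   d'_kj         sign(d) * max(|d| - s, 0)      (soft threshold at s)
#   x_bar'_kj     x_bar_j + m_k (s_j + s0) d'_kj (shrunken centroid)
# Pixels are scored against shrunken centroids on spatially smoothed
# spectra: score_ik = sum_j (x~_ij - x_bar'_kj)^2 / (s_j + s0)^2 - 2 log pi_k.

PRIOR_FLOOR_FACTOR <- 10  # priors floored at 1/(10 n)

# size convention for m_k: "minus" gives sqrt(1/n_k - 1/n), the variance of
# (class mean - overall mean); "plus" gives the sqrt(1/n_k + 1/n) variant.
compute_ssc_model <- function(X, labels, s = 0, size_convention = c("minus", "plus")) {
  size_convention <- match.arg(size_convention)
  labels <- as.factor(labels)
  classes <- levels(labels)
  K <- length(classes)
  n <- ncol(X)
  nf <- nrow(X)
  n_k <- as.numeric(table(labels))
  overall <- rowMeans(X)
  cent <- matrix(0, nf, K, dimnames = list(NULL, classes))
  ss_within <- numeric(nf)
  for (k in seq_len(K)) {
    idx <- which(labels == classes[k])
    cent[, k] <- rowMeans(X[, idx, drop = FALSE])
    ss_within <- ss_within + rowSums((X[, idx, drop = FALSE] - cent[, k])^2)
  }
  denom <- max(n - K, 1L)
  s_j <- sqrt(ss_within / denom)
  s0 <- stats::median(s_j)
  m_k <- if (size_convention == "minus") sqrt(pmax(1 / n_k - 1 / n, 0))
         else sqrt(1 / n_k + 1 / n)
  m_k <- pmax(m_k, .Machine$double.eps)
  scale_j <- s_j + s0
  d <- sweep(cent - overall, 1, scale_j, "/")
  d <- sweep(d, 2, m_k, "/")
  d_shrunk <- sign(d) * pmax(abs(d) - s, 0)
  cent_shrunk <- overall + sweep(sweep(d_shrunk, 2, m_k, "*"), 1, scale_j, "*")
  priors <- pmax(n_k / n, 1 / (PRIOR_FLOOR_FACTOR * n))
  priors <- priors / sum(priors)
  structure(
    list(classes = classes, overall = overall, centroids = cent,
         shrunken_centroids = cent_shrunk, t_statistics = d,
         shrunken_t = d_shrunk, dispersion = s_j, s0 = s0,
         size_factors = m_k, priors = priors, s = s,
         size_convention = size_convention, n = n, n_k = n_k,
         mz = NULL, r = NA_real_),
    class = "msi_ssc_model")
}

# score matrix (pixels x classes) of spatially smoothed spectra X_sm
ssc_scores <- function(model, X_sm) {
  v <- (model$dispersion + model$s0)^2
  K <- length(model$classes)
  sc <- matrix(0, ncol(X_sm), K)
  for (k in seq_len(K)) {
    sc[, k] <- colSums((X_sm - model$shrunken_centroids[, k])^2 / v) -
      2 * log(model$priors[k])
  }
  colnames(sc) <- model$classes
  sc
}

scores_to_probs <- function(sc) {
  p <- exp(-(sc - apply(sc, 1, min)) / 2)
  p / rowSums(p)
}

# argmin with ties to the lowest class index
argmin_rows <- function(sc) max.col(-sc, ties.method = "first")

#' Unsupervised spatial shrunken centroids segmentation
#'
#' Iteratively segments pixels into at most `k` classes. Labels initialize
#' from seeded k-means on a pixel subsample; each iteration recomputes the
#' shrunken-centroid model from the current labels, scores every pixel's
#' spatially smoothed spectrum against every shrunken centroid, reassigns to
#' the best-scoring class, drops emptied classes, and stops when fewer than
#' `tol` of labels change (or at `max_iter`). The shrinkage threshold `s`
#' zeroes the t-statistics of uninformative features, so each reported
#' segment comes with the features that actually drive it.
#'
#' @param dataset centroided `msi_dataset`.
#' @param r spatial radius (grid units); 0 disables spatial smoothing.
#' @param k maximum number of classes.
#' @param s shrinkage threshold, or a vector of thresholds (one fit each).
#' @param weights_method `"gaussian"` or `"adaptive"`.
#' @param max_iter,tol convergence controls (fraction of labels changed).
#' @param seed RNG seed for initialization.
#' @param init_labels optional per-pixel starting labels; when supplied the
#'   k-means initialization is skipped. A vector of `s` values is fitted as
#'   a regularization path in ascending order, each fit warm-started from
#'   the previous one's labels, which keeps the surviving-feature counts
#'   monotone along the path.
#' @return an `msi_ssc_fit` (list with `model`, `labels`, `probabilities`,
#'   `iterations`, `objective_trace`, `assignment_decrease`, `collapsed`),
#'   or a list of fits when `s` has length > 1. `assignment_decrease` is the
#'   per-iteration change of the assignment objective produced by the
#'   reassignment step under the then-current model; it is never positive.
#' @export
ssc_segment <- function(dataset, r = 1, k = 10, s = 0,
                        weights_method = c("gaussian", "adaptive"),
                        max_iter = 100L, tol = 1e-3, seed = 1L,
                        init_labels = NULL) {
  weights_method <- match.arg(weights_method)
  if (length(s) > 1L) {
    ord <- order(s)
    fits <- vector("list", length(s))
    prev <- init_labels
    for (i in ord) {
      fits[[i]] <- ssc_segment(dataset, r = r, k = k, s = s[i],
                               weights_method = weights_method,
                               max_iter = max_iter, tol = tol, seed = seed,
                               init_labels = prev)
      prev <- fits[[i]]$labels
    }
    names(fits) <- paste0("s=", s)
    return(fits)
  }
  X <- msi_intensities(dataset)
  n <- ncol(X)
  if (k > n) stop("k (", k, ") exceeds pixel count (", n, ")")
  X_sm <- if (r > 0) {
    w <- compute_spatial_weights(dataset, r = r, method = weights_method,
                                 spectra = X)
    smooth_by_weights(X, w)
  } else X

  labels <- if (!is.null(init_labels)) {
    stopifnot(length(init_labels) == n)
    as.factor(init_labels)
  } else with_seed(seed, {
    sub <- sort(sample.int(n, min(n, max(2L * k, ceiling(0.1 * n)))))
    pts <- unique(t(X[, sub, drop = FALSE]))
    centers <- tryCatch({
      km <- suppressWarnings(
        stats::kmeans(pts, centers = min(k, nrow(pts)), nstart = 3))
      t(km$centers)
    }, error = function(e)
      X[, sample.int(n, min(k, n)), drop = FALSE])
    d2 <- vapply(seq_len(ncol(centers)), function(c.)
      colSums((X - centers[, c.])^2), numeric(n))
    factor(max.col(-d2, ties.method = "first"))
  })

  objective <- numeric(0)
  assignment_decrease <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) == 1L) break
    model <- compute_ssc_model(X, labels, s = s)
    sc <- ssc_scores(model, X_sm)
    new_idx <- argmin_rows(sc)
    # reassignment can only lower the objective under the current model
    old_idx <- match(as.character(labels), model$classes)
    obj_new <- sum(sc[cbind(seq_len(n), new_idx)])
    objective <- c(objective, obj_new)
    assignment_decrease <-
      c(assignment_decrease, obj_new - sum(sc[cbind(seq_len(n), old_idx)]))
    new_labels <- factor(model$classes[new_idx], levels = model$classes)
    changed <- mean(as.character(new_labels) != as.character(labels))
    labels <- new_labels
    if (changed < tol || iter >= max_iter) break
  }
  labels <- droplevels(as.factor(labels))
  collapsed <- nlevels(labels) == 1L
  model <- if (!collapsed) compute_ssc_model(X, labels, s = s) else {
    m <- compute_ssc_model(X, factor(rep(1, n), levels = 1), s = s)
    m
  }
  model$r <- r
  model$mz <- dataset$features$mz
  sc <- ssc_scores(model, X_sm)
  probs <- scores_to_probs(sc)
  final_idx <- argmin_rows(sc)
  structure(
    list(model = model,
         labels = factor(model$classes[final_idx], levels = model$classes),
         probabilities = probs, iterations = iter,
         objective_trace = objective,
         assignment_decrease = assignment_decrease, collapsed = collapsed,
         params = list(r = r, k = k, s = s,
                       weights_method = weights_method, seed = seed)),
    class = "msi_ssc_fit")
}

#' Fit a spatial shrunken centroids classifier from known labels
#'
#' A single pass of the model equations on the supplied labels; no label
#' iteration. Spatial smoothing is applied at prediction time, not to the
#' training labels.
#'
#' @param dataset centroided `msi_dataset`.
#' @param labels per-pixel class labels (>= 2 classes, >= 2 pixels each).
#' @param r spatial radius stored for prediction.
#' @param s shrinkage threshold.
#' @param weights_method weights used at prediction time.
#' @return `msi_ssc_model`.
#' @export
ssc_fit_classifier <- function(dataset, labels, r = 0, s = 0,
                               weights_method = c("gaussian", "adaptive")) {
  weights_method <- match.arg(weights_method)
  labels <- as.factor(labels)
  if (any(is.na(labels))) stop("labels contain NA")
  if (nlevels(droplevels(labels)) < 2L)
    stop("classification needs at least 2 classes")
  sizes <- table(droplevels(labels))
  if (any(sizes < 2L))
    stop("class(es) with a single pixel (dispersion undefined): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  X <- msi_intensities(dataset)
  model <- compute_ssc_model(X, droplevels(labels), s = s)
  model$r <- r
  model$weights_method <- weights_method
  model$mz <- dataset$features$mz
  model
}

#' Predict classes with a fitted SSC model
#'
#' Scores each pixel's (spatially smoothed) spectrum against the model's
#' shrunken centroids; deterministic.
#'
#' @param model `msi_ssc_model`.
#' @param dataset centroided `msi_dataset` on the same reference features.
#' @param weights optional `msi_spatial_weights`; computed from `model$r`
#'   when `NULL` (identity when `r` is 0 or unset).
#' @return list with `labels` (factor) and `probabilities` (matrix).
#' @export
ssc_predict <- function(model, dataset, weights = NULL) {
  fmz <- dataset$features$mz
  if (!is.null(model$mz)) {
    if (length(model$mz) != length(fmz) ||
        any(abs(model$mz - fmz) > 1e-9 * pmax(model$mz, 1))) {
      missing_mz <- setdiff(signif(model$mz, 10), signif(fmz, 10))
      stop("dataset features do not match the model's reference peaks; ",
           "missing m/z: ",
           paste(utils::head(format(missing_mz), 5), collapse = ", "))
    }
  } else if (length(model$overall) != n_features(dataset)) {
    stop("dataset feature count does not match the model")
  }
  X <- msi_intensities(dataset)
  r <- model$r
  if (is.null(weights) && !is.na(r) && r > 0) {
    wm <- if (!is.null(model$weights_method)) model$weights_method
          else "gaussian"
    weights <- compute_spatial_weights(dataset, r = r, method = wm,
                                       spectra = X)
  }
  X_sm <- if (!is.null(weights)) smooth_by_weights(X, weights) else X
  sc <- ssc_scores(model, X_sm)
  idx <- argmin_rows(sc)
  list(labels = factor(model$classes[idx], levels = model$classes),
       probabilities = scores_to_probs(sc))
}

#' Top discriminating features of a class
#'
#' Features whose soft-thresholded t-statistic for the class survived
#' shrinkage (`d' != 0`), ranked by `|d'|` descending.
#'
#' @param model `msi_ssc_model`.
#' @param class class label.
#' @param n maximum rows.
#' @return data.frame with `mz`, `statistic` (d'), `centroid`.
#' @export
ssc_top_features <- function(model, class, n = 10L) {
  k <- match(as.character(class), model$classes)
  if (is.na(k)) stop("unknown class '", class, "'; classes are: ",
                     paste(model$classes, collapse = ", "))
  d <- model$shrunken_t[, k]
  nz <- which(d != 0)
  nz <- nz[order(abs(d[nz]), decreasing = TRUE)]
  nz <- utils::head(nz, n)
  data.frame(mz = if (!is.null(model$mz)) model$mz[nz] else NA_real_,
             statistic = d[nz],
             centroid = model$shrunken_centroids[nz, k])
}

#' Grouped cross-validation for SSC or PLS classifiers
#'
#' Partitions the *levels* of `fold_unit` (for example tissue cores) into
#' `folds` folds as evenly as possible, never splitting a unit across folds,
#' so spatially correlated pixels of one unit cannot leak between training
#' and test. When `rebin_hook` is given, reference peaks are recomputed from
#' each fold's training spectra only and both halves are re-integrated (the
#' per-fold rebinning contract). Accuracy is the pixel-level fraction
#' correct pooled over held-out folds. Ties on accuracy resolve to the
#' smaller model: larger `s` for SSC, fewer components for PLS.
#'
#' @param dataset centroided (or profile, with `rebin_hook`) `msi_dataset`.
#' @param labels per-pixel class labels.
#' @param fold_unit pixel annotation column naming the grouping unit.
#' @param grid for `learner = "ssc"`, a data.frame with columns `r` and `s`;
#'   for `"pls"`, an integer vector of component counts.
#' @param learner `"ssc"` or `"pls"`.
#' @param folds number of folds.
#' @param rebin_hook optional `function(train_dataset, test_dataset)`
#'   returning `list(train =, test =)` after per-fold reference rebuilding.
#' @param seed RNG seed for the fold partition.
#' @return list with `table` (per-parameter accuracy) and `best` (row of the
#'   winning parameters).
#' @export
cross_validate <- function(dataset, labels, fold_unit, grid,
                           learner = c("ssc", "pls"), folds = 5L,
                           rebin_hook = NULL, seed = 1L) {
  learner <- match.arg(learner)
  labels <- as.factor(labels)
  if (!fold_unit %in% names(dataset$pixels))
    stop("unknown fold_unit column '", fold_unit, "'")
  units <- as.character(dataset$pixels[[fold_unit]])
  lev <- unique(units)
  if (folds > length(lev))
    stop("folds (", folds, ") exceeds the number of distinct ", fold_unit,
         " levels (", length(lev), ")")
  fold_of_unit <- with_seed(seed, {
    perm <- sample(lev)
    stats::setNames(rep(seq_len(folds), length.out = length(lev)),
                    perm)
  })
  fold_of_pixel <- fold_of_unit[units]

  if (learner == "ssc") {
    grid <- as.data.frame(grid)
    stopifnot(all(c("r", "s") %in% names(grid)))
    n_par <- nrow(grid)
  } else {
    ncomps <- as.integer(grid)
    n_par <- length(ncomps)
  }
  correct <- numeric(n_par); total <- numeric(n_par)
  for (f in seq_len(folds)) {
    te <- which(fold_of_pixel == f)
    tr <- which(fold_of_pixel != f)
    d_tr <- select_pixels(dataset, tr, "cv_train")
    d_te <- select_pixels(dataset, te, "cv_test")
    if (!is.null(rebin_hook)) {
      rb <- rebin_hook(d_tr, d_te)
      d_tr <- rb$train; d_te <- rb$test
    }
    for (g in seq_len(n_par)) {
      pred <- if (learner == "ssc") {
        m <- ssc_fit_classifier(d_tr, labels[tr], r = grid$r[g],
                                s = grid$s[g])
        ssc_predict(m, d_te)$labels
      } else {
        m <- pls_fit(d_tr, labels[tr], ncomp = ncomps[g])
        pls_predict(m, d_te)$labels
      }
      correct[g] <- correct[g] +
        sum(as.character(pred) == as.character(labels[te]))
      total[g] <- total[g] + length(te)
    }
  }
  acc <- correct / total
  tab <- if (learner == "ssc") cbind(grid, accuracy = acc)
         else data.frame(ncomp = ncomps, accuracy = acc)
  best_idx <- if (learner == "ssc") {
    cand <- which(acc == max(acc))
    cand[order(-grid$s[cand], grid$r[cand])][1]   # ties -> larger s
  } else {
    cand <- which(acc == max(acc))
    cand[order(ncomps[cand])][1]                  # ties -> fewer components
  }
  list(table = tab, best = tab[best_idx, , drop = FALSE],
       folds = fold_of_unit)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
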