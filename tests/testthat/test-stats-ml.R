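test_that("co-localization ranks the query first and planted partners next", {
  set.seed(121)
  n <- 150
  q <- rexp(n) + 0.5
  partner <- 2 * q + rnorm(n, 0, 0.02 * sd(q))
  decoys <- matrix(rexp(5 * n), 5, n)
  X <- rbind(q, partner, decoys)
  d <- matrix_dataset(X, mz = c(743.5448, 750.1, 760.2, 770.3, 780.4,
                                790.5, 800.6))
  res <- colocalize(d, 743.5448, top_n = 7)
  expect_equal(res$mz[1], 743.5448)
  expect_identical(res$correlation[1], 1)
  expect_equal(res$mz[2], 750.1)
  expect_gte(res$correlation[2], 0.99)
  # direct-formula correlation oracle
  expect_equal(res$correlation[2], cor(q, partner), tolerance = 1e-12)
  # symmetry: corr(a,b) = corr(b,a) exactly
  res2 <- colocalize(d, 750.1, top_n = 7)
  expect_identical(res$correlation[res$mz == 750.1],
                   res2$correlation[res2$mz == 743.5448])

  dz <- matrix_dataset(rbind(rep(1, n), q), mz = c(100, 200))
  expect_error(colocalize(dz, 100), "zero variance")
})

test_that("class comparison tests group means, not pixels, with BH adjustment", {
  set.seed(122)
  n_groups <- 10; px_per <- 8; p <- 30L
  grp <- rep(sprintf("g%02d", 1:n_groups), each = px_per)
  cond <- rep(rep(c("ctl", "trt"), each = px_per), n_groups / 2)
  cond_of_grp <- tapply(cond, grp, unique)
  X <- matrix(rnorm(p * n_groups * px_per, 10), p, n_groups * px_per)
  # plant a 3-sd group-level shift in feature 5
  shift_groups <- names(cond_of_grp)[cond_of_grp == "trt"]
  X[5, grp %in% shift_groups] <- X[5, grp %in% shift_groups] + 3
  d <- matrix_dataset(X, mz = 100 + seq_len(p))
  d$pixels$grp <- grp; d$pixels$cond <- cond
  res <- means_test(d, "grp", "cond")
  expect_identical(nrow(res), p)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(which.min(res$p_adj), 5L)

  # identical sets of group means in both condition levels give t = 0, p = 1
  Y <- X
  Y[1, ] <- rep(rep(1:(n_groups / 2), each = 2 * px_per), length.out = ncol(Y))
  d2 <- matrix_dataset(Y, mz = 100 + seq_len(p))
  d2$pixels$grp <- grp; d2$pixels$cond <- cond
  res2 <- means_test(d2, "grp", "cond")
  expect_equal(res2$t[1], 0)
  expect_equal(res2$p[1], 1)

  # fewer than 2 groups per level is refused (pseudoreplication)
  d3 <- d
  d3$pixels$grp <- rep(c("only1", "only2"), each = n_groups * px_per / 2)
  expect_error(means_test(d3, "grp", "cond"), ">= 2 groups|not constant")
})

test_that("null class comparison keeps nominal type-I error and uniform p-values", {
  set.seed(123)
  n_groups <- 20; px_per <- 4; p <- 50
  grp <- rep(sprintf("g%02d", 1:n_groups), each = px_per)
  cond <- rep(rep(c("a", "b"), each = px_per), n_groups / 2)
  pvals <- replicate(100, {
    X <- matrix(rnorm(p * n_groups * px_per), p, n_groups * px_per)
    d <- matrix_dataset(X, mz = 100 + seq_len(p))
    d$pixels$grp <- grp; d$pixels$cond <- cond
    means_test(d, "grp", "cond")$p
  })
  expect_gt(mean(pvals < 0.05), 0.03)
  expect_lt(mean(pvals < 0.05), 0.07)
  ks <- suppressWarnings(ks.test(as.numeric(pvals), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("full-component PLS equals the least-squares oracle and separates classes", {
  set.seed(124)
  n <- 30; p <- 5
  X <- matrix(rnorm(n * p), p, n)
  labels <- rep(c("u", "v"), length.out = n)
  d <- matrix_dataset(pmax(X + 4, 0), mz = 100 + seq_len(p))
  m <- pls_fit(d, labels, ncomp = p)
  # normal-equations oracle on the centered matrices
  Xc <- scale(t(msi_intensities(d)), scale = FALSE)
  Y <- 1 * outer(factor(labels), levels(factor(labels)), `==`)
  Yc <- scale(Y, scale = FALSE)
  B_ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_lt(max(abs(m$coefficients - B_ols)), 1e-8)
  # score orthogonality
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)

  # separable phantom: perfect training accuracy
  g <- core_phantom(seed = 125, output = "centroided")
  mm <- pls_fit(g$dataset, g$dataset$pixels$class, ncomp = 2)
  pr <- pls_predict(mm, g$dataset)
  expect_equal(mean(pr$labels == g$dataset$pixels$class), 1.0)

  expect_error(pls_fit(d, labels, ncomp = 0), "ncomp")
  expect_error(pls_fit(d, labels, ncomp = p + 3), "rank")
})

test_that("PLS prediction is invariant to feature reordering", {
  g <- core_phantom(seed = 126, output = "centroided")
  d <- g$dataset
  m <- pls_fit(d, d$pixels$class, ncomp = 2)
  p1 <- pls_predict(m, d)$labels
  perm <- rev(seq_len(n_features(d)))
  d2 <- msi_dataset(msi_intensities(d)[perm, ][order(d$features$mz[perm]), ],
                    mz = sort(d$features$mz[perm]), pixels = d$pixels,
                    centroided = TRUE)
  m2 <- pls_fit(d2, d$pixels$class, ncomp = 2)
  expect_identical(pls_predict(m2, d2)$labels, p1)
})

test_that("PCA agrees with the SVD oracle and orders explained variance", {
  set.seed(127)
  m <- matrix(rnorm(30 * 100), 30, 100)
  d <- matrix_dataset(m, mz = 100 + seq_len(30))
  res <- pca(d, ncomp = 5)
  sv <- svd(scale(t(m), scale = FALSE))
  for (j in 1:5) {
    # scores agree up to sign
    s_pkg <- res$scores[, j]; s_svd <- sv$u[, j] * sv$d[j]
    expect_lt(min(max(abs(s_pkg - s_svd)), max(abs(s_pkg + s_svd))), 1e-8)
  }
  expect_true(all(diff(res$explained_variance) <= 1e-12))
  L <- res$loadings
  expect_lt(max(abs(crossprod(L) - diag(5))), 1e-8)

  # rank-1 data: first component carries all variance
  r1 <- matrix(outer(rnorm(10), rnorm(40)), 10, 40)
  dr <- matrix_dataset(r1, mz = 100 + seq_len(10))
  expect_equal(pca(dr, 2)$explained_variance[1], 1, tolerance = 1e-10)
})
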