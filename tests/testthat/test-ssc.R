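test_that("r=0, s=0 classifier equals the diagonal nearest-centroid oracle exactly", {
  td <- two_class_data(seed = 101, n_per = 100, p = 50)
  d <- matrix_dataset(pmax(td$X + 5, 0), mz = seq_len(50) + 499)
  X <- msi_intensities(d)
  model <- ssc_fit_classifier(d, td$labels, r = 0, s = 0)
  pred <- ssc_predict(model, d)
  oracle <- nsc_oracle(X, td$labels, s = 0)
  expect_identical(as.character(pred$labels), oracle$predict(X))
  # model identity: x'_kj = x_j + m_k (s_j + s0) d'_kj reconstructs the
  # class centroids at s = 0
  expect_equal(unname(model$shrunken_centroids), unname(oracle$shrunk),
               tolerance = 1e-12)
  expect_equal(unname(model$t_statistics), unname(oracle$d),
               tolerance = 1e-10)
  # probabilities sum to 1 and argmax equals the label
  expect_equal(rowSums(pred$probabilities), rep(1, ncol(X)))
  expect_identical(as.character(pred$labels),
                   model$classes[max.col(pred$probabilities,
                                         ties.method = "first")])
})

test_that("shrinkage zeroes statistics, never flips signs, and counts are monotone in s", {
  td <- two_class_data(seed = 102)
  d <- matrix_dataset(pmax(td$X + 5, 0), mz = seq_len(50) + 499)
  grid <- c(0, 6, 12, 18, 24, 30)
  counts <- integer(length(grid))
  prev_d <- NULL
  for (i in seq_along(grid)) {
    m <- ssc_fit_classifier(d, td$labels, r = 0, s = grid[i])
    expect_true(all(m$shrunken_t[abs(m$t_statistics) <= grid[i]] == 0))
    expect_true(all(sign(m$shrunken_t[m$shrunken_t != 0]) ==
                    sign(m$t_statistics[m$shrunken_t != 0])))
    counts[i] <- sum(m$shrunken_t != 0)
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation recovers planted 4-region structure and drops empty classes", {
  g <- centroided_phantom(seed = 103, width = 14, height = 14,
                          noise_sd = 0.3)
  fit <- ssc_segment(g$dataset, r = 1, k = 10, s = 0, seed = 1)
  expect_identical(length(levels(droplevels(fit$labels))), 4L)
  expect_gte(adjusted_rand_index(fit$labels, g$truth$segment), 0.95)
  expect_false(fit$collapsed)
  # each reassignment step lowers the assignment objective under the
  # then-current model
  fit0 <- ssc_segment(g$dataset, r = 0, k = 6, s = 0, seed = 2)
  expect_true(all(fit0$assignment_decrease <=
                  1e-9 * abs(fit0$objective_trace)))
})

test_that("a shrinkage threshold above every |d| collapses to one flagged class", {
  g <- centroided_phantom(seed = 104, width = 8, height = 8)
  fit <- ssc_segment(g$dataset, r = 0, k = 4, s = 1e6, seed = 1)
  expect_true(fit$collapsed)
  expect_identical(length(levels(droplevels(fit$labels))), 1L)
})

test_that("a list of s values returns one fit per value", {
  g <- centroided_phantom(seed = 105, width = 8, height = 8)
  fits <- ssc_segment(g$dataset, r = 2, k = 10, s = c(0, 6, 12, 18, 24, 30),
                      seed = 1)
  expect_identical(length(fits), 6L)
  expect_named(fits, paste0("s=", c(0, 6, 12, 18, 24, 30)))
  for (f in fits) expect_s3_class(f, "msi_ssc_fit")
})

test_that("top features rank the planted enriched feature first", {
  set.seed(106)
  n_per <- 40; p <- 12
  X <- matrix(abs(rnorm(p * 2 * n_per, 5, 0.5)), p, 2 * n_per)
  X[4, seq_len(n_per)] <- X[4, seq_len(n_per)] * 10   # enriched in class A
  labels <- rep(c("A", "B"), each = n_per)
  d <- matrix_dataset(X, mz = 100 + seq_len(p))
  m <- ssc_fit_classifier(d, labels, r = 0, s = 0)
  top <- ssc_top_features(m, "A", n = 5)
  expect_equal(top$mz[1], 104)
  expect_error(ssc_top_features(m, "Z"), "unknown class")
  # total shrinkage empties the list
  m2 <- ssc_fit_classifier(d, labels, r = 0, s = 1e9)
  expect_identical(nrow(ssc_top_features(m2, "A")), 0L)
})

test_that("classifier training rejects degenerate label sets", {
  g <- centroided_phantom(seed = 107, width = 6, height = 6)
  d <- g$dataset
  expect_error(ssc_fit_classifier(d, rep("only", n_pixels(d))),
               "at least 2 classes")
  lab <- rep(c("a", "b"), length.out = n_pixels(d))
  lab[1] <- "c"
  expect_error(ssc_fit_classifier(d, lab), "single pixel")
})

test_that("prediction requires matching reference features", {
  td <- two_class_data(seed = 108, n_per = 20, p = 10)
  d <- matrix_dataset(pmax(td$X + 5, 0), mz = 100 + seq_len(10))
  m <- ssc_fit_classifier(d, td$labels, r = 0, s = 0)
  other <- matrix_dataset(pmax(td$X + 5, 0), mz = 200 + seq_len(10))
  expect_error(ssc_predict(m, other), "reference peaks")
  # uniform-intensity dataset: every pixel gets the majority-prior class
  lab2 <- rep(c("A", "B"), times = c(30, 10))
  d2 <- matrix_dataset(pmax(td$X[, 1:40] + 5, 0), mz = 100 + seq_len(10))
  m2 <- ssc_fit_classifier(d2, lab2, r = 0, s = 1e9)  # centroids all equal
  uni <- matrix_dataset(matrix(5, 10, 7), mz = 100 + seq_len(10))
  p2 <- ssc_predict(m2, uni)
  expect_true(all(p2$labels == "A"))
})

test_that("grouped cross-validation partitions cores, rebins per fold, picks ties conservatively", {
  g <- core_phantom(seed = 109, output = "centroided")
  d <- g$dataset
  labels <- d$pixels$class
  cv <- cross_validate(d, labels, fold_unit = "core",
                       grid = data.frame(r = 0, s = c(0, 5)),
                       learner = "ssc", folds = 5, seed = 3)
  # every core appears in exactly one fold
  expect_identical(sort(names(cv$folds)), sort(unique(d$pixels$core)))
  expect_true(all(table(cv$folds) >= 1))
  # separable by construction: perfect accuracy at s = 0
  expect_equal(cv$table$accuracy[cv$table$s == 0], 1.0)
  # tie on accuracy resolves to the larger s
  if (cv$table$accuracy[1] == cv$table$accuracy[2])
    expect_equal(cv$best$s, 5)
  expect_error(cross_validate(d, labels, "core", data.frame(r = 0, s = 0),
                              folds = 99), "exceeds")
})
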