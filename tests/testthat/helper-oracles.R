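# Independent oracles and small data builders shared across test files.
# The oracles use plain dense arithmetic and share no code with the package.

# diagonal-covariance (nearest shrunken centroid) classifier oracle
nsc_oracle <- function(X, labels, s = 0) {
  labels <- as.factor(labels)
  cl <- levels(labels)
  n <- ncol(X); K <- length(cl)
  xbar <- rowMeans(X)
  cent <- sapply(cl, function(k) rowMeans(X[, labels == k, drop = FALSE]))
  nk <- sapply(cl, function(k) sum(labels == k))
  ssw <- 0
  for (k in cl) ssw <- ssw + rowSums((X[, labels == k, drop = FALSE] -
                                        cent[, k])^2)
  sj <- sqrt(ssw / (n - K))
  s0 <- median(sj)
  mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(sweep(cent - xbar, 1, sj + s0, "/"), 2, mk, "/")
  ds <- sign(d) * pmax(abs(d) - s, 0)
  shrunk <- xbar + sweep(sweep(ds, 2, mk, "*"), 1, sj + s0, "*")
  prior <- pmax(nk / n, 1 / (10 * n)); prior <- prior / sum(prior)
  predict <- function(Xnew) {
    sc <- sapply(seq_len(K), function(k)
      colSums((Xnew - shrunk[, k])^2 / (sj + s0)^2) - 2 * log(prior[k]))
    cl[apply(sc, 1, which.min)]
  }
  list(shrunk = shrunk, d = d, ds = ds, sj = sj, s0 = s0, mk = mk,
       predict = predict)
}

# two spherical Gaussian classes, first 10 features shifted in class A
two_class_data <- function(seed = 1, n_per = 100, p = 50, shift = 2) {
  set.seed(seed)
  X <- matrix(rnorm(p * 2 * n_per), p, 2 * n_per)
  X[1:10, seq_len(n_per)] <- X[1:10, seq_len(n_per)] + shift
  labels <- rep(c("A", "B"), each = n_per)
  list(X = X, labels = labels)
}

# single-feature dataset with two spatial blocks of distinct mean intensity
two_block_phantom <- function(seed = 1, side = 12, mu = c(1, 5), sd = 0.1) {
  set.seed(seed)
  n <- side * side
  px <- data.frame(run = "r",
                   x = rep(0:(side - 1), times = side),
                   y = rep(0:(side - 1), each = side))
  block <- ifelse(px$x < side / 2, 1L, 2L)
  x <- rnorm(n, mu[block], sd)
  d <- msi_dataset(matrix(pmax(x, 0), 1, n), mz = 1347.7, pixels = px,
                   centroided = TRUE)
  list(dataset = d, block = block)
}
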