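test_that("annotation join covers all pixels, leaves unmatched NA, rejects duplicates", {
  g <- centroided_phantom(seed = 3, width = 5, height = 4)
  d <- g$dataset
  full <- data.frame(d$pixels[c("run", "x", "y")],
                     cond = rep(c("a", "b"), length.out = n_pixels(d)))
  d2 <- attach_pixel_annotations(d, full)
  expect_false(anyNA(d2$pixels$cond))
  expect_identical(d2$pixels$cond, full$cond)

  part <- full[1:7, ]
  part$cond <- "tumor"
  d3 <- attach_pixel_annotations(d, part)
  expect_identical(sum(!is.na(d3$pixels$cond)), 7L)
  d4 <- subset_pixels(d3, !is.na(cond))
  expect_identical(n_pixels(d4), 7L)
  expect_true(all(d4$pixels$cond == "tumor"))

  dup <- rbind(part, part[3, ])
  expect_error(attach_pixel_annotations(d, dup), "duplicate.*\\(")
})

test_that("pixel subsetting matches ground truth counts and rejects unknown columns", {
  g <- generate_phantom(phantom_spec(
    seed = 5, width = 10, height = 10,
    segments = list(
      list(label = "bg", rect = NULL,
           peaks = data.frame(mz = 900, amplitude = 2, sd = 0.2)),
      list(label = "A", rect = c(0, 7, 0, 4),
           peaks = data.frame(mz = 1000, amplitude = 5, sd = 0.2))),
    mz_range = c(850, 1100), axis_ppm = 100, noise_sd = 0.1),
    output = "centroided")
  d <- g$dataset
  # ground truth by direct scan of the planted rectangle
  expected <- sum(g$truth$segment == "A")
  expect_identical(expected, sum(d$pixels$x <= 7 & d$pixels$y <= 4))
  sub <- subset_pixels(d, segment == "A")
  expect_identical(n_pixels(sub), expected)
  expect_identical(n_features(sub), n_features(d))

  all_d <- subset_pixels(d, rep(TRUE, n_pixels(d)))
  expect_identical(msi_intensities(all_d), msi_intensities(d))

  expect_error(subset_pixels(d, nonexistent_col == "A"), "nonexistent_col")
  empty <- subset_pixels(d, segment == "no-such-label")
  expect_identical(n_pixels(empty), 0L)
})

test_that("subset composition equals conjunctive predicate, provenance grows by one per op", {
  g <- centroided_phantom(seed = 9, width = 8, height = 8)
  d <- g$dataset
  p0 <- length(d$provenance)
  a <- subset_pixels(subset_pixels(d, x < 6), y < 3)
  b <- subset_pixels(d, x < 6 & y < 3)
  expect_identical(msi_intensities(a), msi_intensities(b))
  expect_identical(a$pixels[c("run", "x", "y")], b$pixels[c("run", "x", "y")])
  expect_identical(length(a$provenance), p0 + 2L)
  expect_identical(length(b$provenance), p0 + 1L)
})

test_that("rectangle ROIs label exactly the covered pixels and reject overlap", {
  g <- centroided_phantom(seed = 2, width = 6, height = 6)
  d <- g$dataset
  whole <- data.frame(run = "run0", xmin = 0, xmax = 5, ymin = 0, ymax = 5,
                      label = "all")
  d1 <- roi_from_rectangles(d, whole)
  expect_true(all(d1$pixels$roi == "all"))

  two <- data.frame(run = "run0",
                    xmin = c(0, 0), xmax = c(3, 3),
                    ymin = c(0, 3), ymax = c(2, 5),
                    label = c("up", "down"))
  d2 <- roi_from_rectangles(d, two)
  # brute-force point-in-rectangle scan
  in_rect <- function(px, r) px$x >= r$xmin & px$x <= r$xmax &
    px$y >= r$ymin & px$y <= r$ymax
  expect_identical(sum(d2$pixels$roi == "up", na.rm = TRUE),
                   sum(in_rect(d$pixels, two[1, ])))
  expect_identical(sum(d2$pixels$roi == "down", na.rm = TRUE),
                   sum(in_rect(d$pixels, two[2, ])))
  expect_identical(sum(is.na(d2$pixels$roi)), 36L - 12L - 12L)

  overlap <- data.frame(run = "run0",
                        xmin = c(0, 2), xmax = c(3, 4),
                        ymin = c(0, 0), ymax = c(2, 2),
                        label = c("p", "q"))
  expect_error(roi_from_rectangles(d, overlap), "overlap")
})

test_that("chunked map-reduce is invariant to chunk size and workers", {
  g <- centroided_phantom(seed = 13, width = 10, height = 10)
  d <- g$dataset
  tic_sum <- function(plan) process_in_chunks(d, function(x, i) sum(x), `+`,
                                              plan)
  all_px <- n_pixels(d)
  s1 <- tic_sum(chunk_plan(1)); s13 <- tic_sum(chunk_plan(13))
  sall <- tic_sum(chunk_plan(all_px))
  expect_identical(s1, s13)
  expect_identical(s13, sall)

  m1 <- mean_spectrum(d, chunk_plan(7, workers = 1))
  m2 <- mean_spectrum(d, chunk_plan(7, workers = 2))
  expect_lt(max(abs(m1 - m2) / pmax(abs(m1), .Machine$double.xmin)), 1e-12)
  dense <- rowMeans(msi_intensities(d))
  expect_lt(max(abs(m1 - dense) / pmax(abs(dense), .Machine$double.xmin)),
            1e-10)

  expect_error(
    process_in_chunks(d, function(x, i) if (i == 7) stop("boom") else 0,
                      `+`, chunk_plan(5)),
    "pixel 7")
})

test_that("mean spectrum equals the dense column mean", {
  two <- matrix_dataset(cbind(c(1, 3), c(3, 5)))
  expect_equal(mean_spectrum(two), c(2, 4))

  same <- matrix_dataset(matrix(rep(c(2, 0, 7), 5), nrow = 3))
  expect_equal(mean_spectrum(same), c(2, 0, 7))

  set.seed(101)
  m <- matrix(rexp(50 * 200), nrow = 50)
  d <- matrix_dataset(m)
  expect_equal(mean_spectrum(d), rowMeans(m), tolerance = 1e-12)
})

test_that("feature summaries aggregate by annotation group and resolve nearest m/z", {
  set.seed(21)
  n <- 60
  m <- matrix(0, 2, n)
  grp <- rep(c("lo", "hi"), each = n / 2)
  m[1, ] <- ifelse(grp == "lo", 1, 5) + rnorm(n, 0, 0.01)
  m[2, ] <- runif(n)
  d <- msi_dataset(m, mz = c(1347.65, 1400.0), centroided = TRUE)
  d$pixels$grp <- grp
  # paper-style query near substance P resolves to the nearest feature
  expect_identical(resolve_feature(d, 1347.7, tol_ppm = 100), 1L)
  tab <- summarize_feature(d, 1347.7, tol_ppm = 100, groups = "grp")
  expect_identical(nrow(tab), 2L)
  expect_lt(abs(tab$value[tab$grp == "lo"] - 1), 0.01)
  expect_lt(abs(tab$value[tab$grp == "hi"] - 5), 0.01)

  one <- summarize_feature(d, 1400, tol_ppm = 10, groups = "grp",
                           stat = mean)
  expect_equal(sum(one$value * table(grp)[as.character(one$grp)]) / n,
               mean(m[2, ]), tolerance = 1e-12)

  expect_error(summarize_feature(d, 2000, tol_ppm = 10, groups = "grp"),
               "nearest")
})
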