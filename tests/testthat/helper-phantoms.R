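# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so the suite is deterministic.

# small 4-segment centroided phantom (3 planted regions + background)
centroided_phantom <- function(seed = 7, width = 14, height = 14,
                               noise_sd = 0.3) {
  generate_phantom(
    phantom_spec(seed = seed, width = width, height = height,
                 noise_sd = noise_sd),
    output = "centroided")
}

# small profile phantom on a narrow axis (fast), one segment, given peaks
profile_phantom <- function(seed, peaks, width = 6, height = 6,
                            mz_range = c(900, 1100), axis_ppm = 20,
                            noise_sd = 0, baseline_amplitude = 0,
                            drift_ppm = 0, drift_linear = FALSE,
                            tic_range = c(1, 1)) {
  generate_phantom(phantom_spec(
    seed = seed, width = width, height = height,
    segments = list(list(label = "tissue", rect = NULL, peaks = peaks)),
    baseline = list(amplitude = baseline_amplitude, decay = 3),
    noise_sd = noise_sd, tic_range = tic_range,
    drift_ppm = drift_ppm, drift_linear = drift_linear,
    mz_range = mz_range, axis_ppm = axis_ppm))
}

# brute-force local-maximum oracle (independent of the package's search)
local_max_for_test <- function(x, hw) {
  n <- length(x)
  which(vapply(seq_len(n), function(i) {
    lo <- max(1, i - hw); hi <- min(n, i + hw)
    left <- if (i > lo) x[lo:(i - 1)] else numeric(0)
    right <- if (i < hi) x[(i + 1):hi] else numeric(0)
    x[i] > 0 && (!length(left) || all(x[i] > left)) &&
      (!length(right) || all(x[i] >= right))
  }, logical(1)))
}

# dense in-memory dataset straight from a matrix (features x pixels)
matrix_dataset <- function(m, mz = seq_len(nrow(m)) + 99,
                           centroided = TRUE) {
  msi_dataset(intensities = m, mz = mz, centroided = centroided)
}

# two-class core phantom for classification: n_cores 4x4-pixel cores laid
# out on one grid, alternating classes with class-specific peaks
core_phantom <- function(seed = 11, n_cores = 10, noise_sd = 0.05,
                         output = "centroided") {
  per_row <- 5
  segs <- lapply(seq_len(n_cores), function(i) {
    row <- (i - 1) %/% per_row; col <- (i - 1) %% per_row
    cls <- if (i %% 2 == 1) "tumor" else "stroma"
    pk <- if (cls == "tumor")
      data.frame(mz = c(800.4, 1000.5), amplitude = c(5, 10),
                 sd = c(0.2, 0.25))
    else
      data.frame(mz = c(800.4, 1200.6), amplitude = c(5, 10),
                 sd = c(0.2, 0.3))
    list(label = sprintf("core%02d", i),
         rect = c(col * 4, col * 4 + 3, row * 4, row * 4 + 3),
         peaks = pk)
  })
  g <- generate_phantom(phantom_spec(
    seed = seed, width = 4 * per_row, height = 4 * ceiling(n_cores / per_row),
    segments = segs, baseline = list(amplitude = 0, decay = 1),
    noise_sd = noise_sd, tic_range = c(1, 1),
    mz_range = c(700, 1300), axis_ppm = 100), output = output)
  core <- g$truth$segment
  class <- ifelse(as.integer(sub("core", "", core)) %% 2 == 1,
                  "tumor", "stroma")
  g$dataset$pixels$core <- core
  g$dataset$pixels$class <- class
  g
}
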