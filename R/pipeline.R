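# Config-driven pipelines: an ordered list of named steps is validated
# against a registry (names and parameter keys) before anything executes, so
# a faulty config never produces partial outputs. Artifacts carry the
# dataset's provenance chain; a machine-readable run manifest is written
# beside the outputs.

# registry: step name -> list(fn = function(state, params), params = allowed
# parameter names). Steps read/replace state$dataset and may add artifacts.
pipeline_registry <- function() {
  reg <- list(
    phantom = list(
      params = c("width", "height", "noise_sd", "tic_range", "drift_ppm",
                 "drift_linear", "mz_range", "axis_ppm", "seed", "output"),
      fn = function(state, p) {
        p$seed <- p$seed %||% state$seed
        output <- p$output %||% "profile"
        p$output <- NULL
        spec <- do.call(phantom_spec, p)
        g <- generate_phantom(spec, output = output)
        state$dataset <- g$dataset
        state$truth <- g$truth
        state
      }),
    read_imzml = list(
      params = c("path"),
      fn = function(state, p) {
        state$dataset <- read_imzml(p$path)
        state
      }),
    write_imzml = list(
      params = c("path", "mode", "precision"),
      fn = function(state, p) {
        write_imzml(state$dataset, p$path, mode = p$mode %||% "continuous",
                    precision = p$precision %||% 64)
        state$artifacts <- c(state$artifacts, p$path)
        state
      }),
    attach_annotations = list(
      params = c("path"),
      fn = function(state, p) {
        state$dataset <- attach_pixel_annotations(state$dataset, p$path)
        state
      }),
    subset = list(
      params = c("predicate"),
      fn = function(state, p) {
        keep <- eval(parse(text = p$predicate), state$dataset$pixels,
                     baseenv())
        state$dataset <- subset_pixels(state$dataset, keep)
        state
      }),
    smooth = list(
      params = c("window", "sd"),
      fn = function(state, p) {
        state$dataset <- smooth_gaussian(state$dataset,
                                         window = p$window %||% 9,
                                         sd = p$sd %||% 2)
        state
      }),
    baseline = list(
      params = c("blocks"),
      fn = function(state, p) {
        state$dataset <- remove_baseline_median(state$dataset,
                                                blocks = p$blocks %||% 750)
        state
      }),
    normalize = list(
      params = c("method"),
      fn = function(state, p) {
        m <- p$method %||% "tic"
        if (m != "tic") stop("unknown normalization method '", m, "'")
        state$dataset <- normalize_tic(state$dataset)
        state
      }),
    resample = list(
      params = c("ppm", "aggregate"),
      fn = function(state, p) {
        state$dataset <- resample_ppm_bins(state$dataset, ppm = p$ppm %||% 10,
                                           aggregate = p$aggregate %||% "mean")
        state
      }),
    align = list(
      params = c("tol_ppm", "anchors"),
      fn = function(state, p) {
        res <- mz_align_to_mean(state$dataset, tol_ppm = p$tol_ppm %||% 200,
                                anchors = p$anchors %||% 20)
        state$dataset <- res$dataset
        state$results$align_shifts <- res$shifts
        state
      }),
    recalibrate = list(
      params = c("calibrants", "tol_ppm"),
      fn = function(state, p) {
        res <- recalibrate_internal(state$dataset, p$calibrants,
                                    tol_ppm = p$tol_ppm %||% 200)
        state$dataset <- res$dataset
        state$results$recalibration <- res$report
        state
      }),
    peaks = list(
      params = c("method", "snr", "window", "blocks", "tol_ppm",
                 "min_freq", "min_mean"),
      fn = function(state, p) {
        ref <- build_reference(state$dataset, snr = p$snr %||% 6,
                               window = p$window %||% 5,
                               method = p$method %||% "mad",
                               blocks = p$blocks %||% 1,
                               tol_ppm = p$tol_ppm %||% 15)
        ref <- filter_reference(ref, min_freq = p$min_freq %||% 0,
                                min_mean = p$min_mean %||% 0)
        state$dataset <- integrate_peak_areas(state$dataset, ref,
                                              tol_ppm = p$tol_ppm %||% 100)
        state$results$reference_peaks <- ref
        state
      }),
    image = list(
      params = c("mz", "tol_ppm", "smoothing", "contrast", "path"),
      fn = function(state, p) {
        imgs <- render_ion_image(state$dataset, mz = p$mz,
                                 tol_ppm = p$tol_ppm %||% 100,
                                 smoothing = p$smoothing %||% "none",
                                 contrast = p$contrast %||% "none")
        state$results$image <- imgs
        if (!is.null(p$path)) {
          write_image(imgs[[1]], p$path)
          state$artifacts <- c(state$artifacts, p$path)
        }
        state
      }),
    ssc_segment = list(
      params = c("r", "k", "s", "weights_method", "seed"),
      fn = function(state, p) {
        state$results$ssc <- ssc_segment(
          state$dataset, r = p$r %||% 1, k = p$k %||% 10, s = p$s %||% 0,
          weights_method = p$weights_method %||% "gaussian",
          seed = p$seed %||% state$seed)
        state
      }),
    dgmm = list(
      params = c("mz", "tol_ppm", "r", "k", "annealing", "seed"),
      fn = function(state, p) {
        state$results$dgmm <- dgmm_segment(
          state$dataset, mz = p$mz, tol_ppm = p$tol_ppm %||% 100,
          r = p$r %||% 1, k = p$k %||% 2,
          annealing = isTRUE(p$annealing), seed = p$seed %||% state$seed)
        state
      }),
    colocalize = list(
      params = c("mz", "tol_ppm", "top_n"),
      fn = function(state, p) {
        state$results$colocalization <- colocalize(
          state$dataset, mz = p$mz, tol_ppm = p$tol_ppm %||% Inf,
          top_n = p$top_n %||% 20)
        state
      }),
    meanstest = list(
      params = c("group", "condition"),
      fn = function(state, p) {
        state$results$means_test <- means_test(state$dataset, p$group,
                                               p$condition)
        state
      })
  )
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured pipeline
#'
#' Executes an ordered list of processing steps. The whole config is
#' validated first (step names against the registry, parameter keys against
#' each step's signature); any problem aborts before execution. Identical
#' config and seed give identical outputs.
#'
#' @param config path to a YAML config, or an equivalent list. Schema:
#'   `seed:` integer; `output_dir:` optional path for the run manifest;
#'   `steps:` list of `- name: <step>` entries with parameter keys inline.
#'   Registered steps: phantom, read_imzml, write_imzml, attach_annotations,
#'   subset, smooth, baseline, normalize, resample, align, recalibrate,
#'   peaks, image, ssc_segment, dgmm, colocalize, meanstest.
#' @return list with `dataset`, `results` (per-step outputs), `artifacts`
#'   (paths written), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  reg <- pipeline_registry()
  steps <- config$steps
  if (is.null(steps) || !length(steps)) stop("config has no steps")
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (is.null(st$name)) stop("step ", i, " has no name")
    if (!st$name %in% names(reg))
      stop("unknown step '", st$name, "' (step ", i, ")")
    unknown <- setdiff(setdiff(names(st), "name"), reg[[st$name]]$params)
    if (length(unknown))
      stop("unknown parameter(s) for step '", st$name, "': ",
           paste(unknown, collapse = ", "))
  }
  state <- list(dataset = NULL, truth = NULL, results = list(),
                artifacts = character(0),
                seed = config$seed %||% 1L)
  t0 <- Sys.time()
  timings <- numeric(0)
  for (st in steps) {
    s0 <- Sys.time()
    params <- st[setdiff(names(st), "name")]
    message(sprintf("[msikit] step %s ...", st$name))
    state <- reg[[st$name]]$fn(state, params)
    timings[st$name] <- as.numeric(Sys.time() - s0, units = "secs")
  }
  manifest <- list(
    seed = state$seed,
    steps = vapply(steps, `[[`, character(1), "name"),
    timings_sec = as.list(round(timings, 3)),
    artifacts = state$artifacts,
    provenance = if (!is.null(state$dataset))
      lapply(state$dataset$provenance, function(p)
        list(name = p$name, params = p$params)) else list(),
    elapsed_sec = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  list(dataset = state$dataset, truth = state$truth,
       results = state$results, artifacts = state$artifacts,
       manifest = manifest)
}
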