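#' MSI dataset container
#'
#' An `msi_dataset` holds a feature-by-pixel intensity store together with a
#' pixel table (run, grid coordinates, annotations), a feature table (one m/z
#' per row), and an ordered provenance trail. Intensities may be an in-memory
#' matrix or a lazy handle into an `.ibd` file created by [read_imzml()], so
#' pixel chunks can be materialized without loading the whole dataset.
#'
#' Continuous-mode data share one ascending m/z axis (`mz`); processed-mode
#' data carry one axis per spectrum (`axes`) and must be resampled onto a
#' shared axis (see [resample_ppm_bins()]) before matrix-shaped operations.
#'
#' @param intensities numeric matrix (features x pixels) with nonnegative
#'   entries, or an internal lazy store handle.
#' @param mz shared ascending m/z axis (Da); `NULL` for processed mode.
#' @param pixels data.frame with columns `run`, `x`, `y` (0-based integer grid
#'   coordinates) plus arbitrary annotation columns. Defaults to a single-run
#'   row-major grid guessed from the pixel count.
#' @param features data.frame with column `mz`, ascending; defaults to `mz`.
#' @param axes list of per-spectrum m/z axes (processed mode only).
#' @param centroided logical; `TRUE` when rows are integrated peaks rather
#'   than profile samples.
#' @param provenance list of processing-step records.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(intensities, mz = NULL, pixels = NULL, features = NULL,
                        axes = NULL, centroided = FALSE, provenance = list()) {
  lazy <- inherits(intensities, "msikit_ibd_store")
  ragged <- !lazy && is.list(intensities)
  if (!lazy && !ragged && !is.null(intensities)) {
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
  }
  if (is.null(mz) && is.null(axes) && !lazy)
    stop("either a shared `mz` axis or per-spectrum `axes` is required")
  if (ragged) {
    if (is.null(axes)) stop("list intensities require per-spectrum `axes`")
    if (!identical(lengths(intensities), lengths(axes)))
      stop("per-spectrum intensity lengths do not match axis lengths")
  }
  n_pix <- if (lazy) length(intensities$intensity_offsets)
           else if (ragged) length(intensities)
           else if (!is.null(intensities)) ncol(intensities)
           else length(axes)
  if (!is.null(mz)) {
    mz <- as.numeric(mz)
    if (is.unsorted(mz, strictly = TRUE))
      stop("m/z axis must be strictly increasing")
  }
  if (!is.null(axes)) {
    bad <- which(vapply(axes, function(a) is.unsorted(a, strictly = TRUE),
                        logical(1)))
    if (length(bad))
      stop("per-spectrum m/z axes must be strictly increasing (spectrum ",
           bad[1], " is not)")
  }
  if (is.null(pixels)) {
    side <- ceiling(sqrt(n_pix))
    pixels <- data.frame(
      run = "run0",
      x = rep(seq_len(side) - 1L, length.out = n_pix),
      y = rep(seq_len(side) - 1L, each = side)[seq_len(n_pix)],
      stringsAsFactors = FALSE)
  }
  pixels <- as.data.frame(pixels, stringsAsFactors = FALSE)
  stopifnot(all(c("run", "x", "y") %in% names(pixels)))
  if (nrow(pixels) != n_pix)
    stop("pixel table has ", nrow(pixels), " rows but there are ",
         n_pix, " spectra")
  if (anyDuplicated(pixels[c("run", "x", "y")]))
    stop("duplicate (run, x, y) keys in pixel table")
  if (any(pixels$x < 0) || any(pixels$y < 0))
    stop("pixel coordinates must be >= 0 (0-based grid)")
  if (is.null(features)) {
    if (!is.null(mz)) features <- data.frame(mz = mz)
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    stopifnot("mz" %in% names(features))
    if (is.unsorted(features$mz)) stop("feature table must be sorted by mz")
  }
  if (!lazy && !is.null(intensities) && !is.null(features) &&
      nrow(features) != nrow(intensities))
    stop("feature table rows (", nrow(features),
         ") do not match intensity rows (", nrow(intensities), ")")
  structure(
    list(mz = mz, axes = axes, intensities = intensities, pixels = pixels,
         features = features, centroided = isTRUE(centroided),
         provenance = provenance),
    class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  mode <- if (!is.null(x$mz)) "continuous" else "processed"
  cat("<msi_dataset> ", n_features(x), " features x ", n_pixels(x),
      " pixels (", mode, if (x$centroided) ", centroided" else "", ")\n",
      sep = "")
  cat("  runs: ", paste(unique(x$pixels$run), collapse = ", "), "\n", sep = "")
  if (!is.null(x$mz))
    cat(sprintf("  m/z range: %.4f - %.4f\n", min(x$mz), max(x$mz)))
  ann <- setdiff(names(x$pixels), c("run", "x", "y"))
  if (length(ann))
    cat("  annotations: ", paste(ann, collapse = ", "), "\n", sep = "")
  cat("  provenance: ", length(x$provenance), " step(s)\n", sep = "")
  invisible(x)
}

#' Number of pixels / features in a dataset
#' @param x an `msi_dataset`.
#' @return integer count.
#' @export
n_pixels <- function(x) nrow(x$pixels)

#' @rdname n_pixels
#' @export
n_features <- function(x) {
  if (!is.null(x$features)) return(nrow(x$features))
  if (!is.null(x$mz)) return(length(x$mz))
  NA_integer_
}

has_shared_axis <- function(x) !is.null(x$mz)

#' Materialize intensity columns
#'
#' Returns the dense feature-by-pixel intensity matrix for the requested
#' pixels, reading lazily from the backing `.ibd` file when the dataset was
#' opened with [read_imzml()].
#'
#' @param x an `msi_dataset` with a shared m/z axis.
#' @param pixels integer pixel indices; default all.
#' @return numeric matrix (features x length(pixels)).
#' @export
msi_intensities <- function(x, pixels = NULL) {
  if (is.null(pixels)) pixels <- seq_len(n_pixels(x))
  if (inherits(x$intensities, "msikit_ibd_store"))
    return(read_ibd_columns(x$intensities, pixels))
  if (is.null(x$intensities) || is.list(x$intensities))
    stop("processed-mode dataset has no shared intensity matrix; ",
         "resample onto a shared axis first (resample_ppm_bins)")
  x$intensities[, pixels, drop = FALSE]
}

#' Extract one spectrum (works in both modes)
#' @param x an `msi_dataset`.
#' @param i pixel index.
#' @return list with `mz` and `intensity` vectors.
#' @export
msi_spectrum <- function(x, i) {
  stopifnot(i >= 1, i <= n_pixels(x))
  if (inherits(x$intensities, "msikit_ibd_store")) {
    s <- read_ibd_spectrum(x$intensities, i)
    return(s)
  }
  if (is.list(x$intensities))
    return(list(mz = x$axes[[i]], intensity = x$intensities[[i]]))
  mz <- if (!is.null(x$mz)) x$mz else x$axes[[i]]
  list(mz = mz, intensity = as.numeric(msi_intensities(x, i)))
}

add_provenance <- function(x, name, params = list()) {
  x$provenance[[length(x$provenance) + 1L]] <-
    list(name = name, params = params, timestamp = Sys.time())
  x
}

replace_intensities <- function(x, m) {
  x$intensities <- m
  x
}

#' Attach per-pixel annotations from a keyed table
#'
#' Joins an annotation table onto the pixel table by the key `(run, x, y)`.
#' Matching pixels gain the table's non-key columns; unmatched pixels receive
#' `NA`. Pixel order is unchanged. Rows of `table` that key pixels absent from
#' the dataset are ignored.
#'
#' @param dataset an `msi_dataset`.
#' @param table data.frame (or CSV/TSV path) with columns `run`, `x`, `y`
#'   plus annotation columns.
#' @return the dataset with extended pixel table.
#' @export
attach_pixel_annotations <- function(dataset, table) {
  if (is.character(table)) table <- read_annotation_table(table)
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!all(c("run", "x", "y") %in% names(table)))
    stop("annotation table must have key columns run, x, y")
  key <- function(df) paste(df$run, df$x, df$y, sep = "\r")
  tk <- key(table)
  if (anyDuplicated(tk)) {
    d <- unique(table[duplicated(tk), c("run", "x", "y")])
    stop("duplicate (run,x,y) keys in annotation table: ",
         paste(sprintf("(%s,%s,%s)", d$run, d$x, d$y), collapse = ", "))
  }
  idx <- match(key(dataset$pixels), tk)
  for (col in setdiff(names(table), c("run", "x", "y")))
    dataset$pixels[[col]] <- table[[col]][idx]
  add_provenance(dataset, "attach_pixel_annotations",
                 list(columns = setdiff(names(table), c("run", "x", "y"))))
}

#' Read/write annotation tables (CSV or TSV, header required)
#' @param path file path; `.tsv`/`.txt` is read tab-separated, else comma.
#' @return data.frame.
#' @export
read_annotation_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_annotation_table
#' @param table data.frame to write.
#' @export
write_annotation_table <- function(table, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Subset a dataset by a predicate on pixel annotations
#'
#' @param dataset an `msi_dataset`.
#' @param predicate an unquoted boolean expression over pixel-table columns
#'   (e.g. `region == "A"`), or a logical vector of length `n_pixels`.
#' @return dataset restricted to the matching pixels, original order kept;
#'   an empty selection yields an empty (0-pixel) dataset, not an error.
#' @export
subset_pixels <- function(dataset, predicate) {
  expr <- substitute(predicate)
  keep <- if (is.logical(predicate_try <- tryCatch(predicate,
                                                   error = function(e) NULL)) &&
              length(predicate_try) == n_pixels(dataset)) {
    predicate_try
  } else {
    eval(expr, dataset$pixels, baseenv())
  }
  if (!is.logical(keep))
    stop("predicate must evaluate to a logical vector")
  keep[is.na(keep)] <- FALSE
  idx <- which(keep)
  select_pixels(dataset, idx, name = "subset_pixels",
                params = list(predicate = deparse(expr)))
}

select_pixels <- function(dataset, idx, name = "select_pixels",
                          params = list()) {
  out <- dataset
  if (inherits(dataset$intensities, "msikit_ibd_store")) {
    out$intensities <- subset_ibd_store(dataset$intensities, idx)
  } else if (is.list(dataset$intensities)) {
    out$intensities <- dataset$intensities[idx]
  } else if (!is.null(dataset$intensities)) {
    out$intensities <- dataset$intensities[, idx, drop = FALSE]
  }
  if (!is.null(dataset$axes)) out$axes <- dataset$axes[idx]
  out$pixels <- dataset$pixels[idx, , drop = FALSE]
  rownames(out$pixels) <- NULL
  add_provenance(out, name, params)
}

#' Label pixels by rectangular regions of interest
#'
#' Builds an annotation vector from labeled axis-aligned rectangles given as
#' inclusive integer coordinate ranges on a run's grid, mirroring manual ROI
#' annotation of tissue positions. Any pixel covered by more than one
#' rectangle is an error: silent precedence between overlapping regions
#' invites silent mislabeling.
#'
#' @param dataset an `msi_dataset`.
#' @param regions data.frame with columns `run`, `xmin`, `xmax`, `ymin`,
#'   `ymax`, `label` (ranges inclusive, 0-based).
#' @param column name of the annotation column to create.
#' @return the dataset with a new pixel annotation column; pixels in no
#'   rectangle get `NA`.
#' @export
roi_from_rectangles <- function(dataset, regions, column = "roi") {
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  need <- c("run", "xmin", "xmax", "ymin", "ymax", "label")
  if (!all(need %in% names(regions)))
    stop("regions must have columns ", paste(need, collapse = ", "))
  px <- dataset$pixels
  lab <- rep(NA_character_, nrow(px))
  hits <- integer(nrow(px))
  for (r in seq_len(nrow(regions))) {
    inside <- px$run == regions$run[r] &
      px$x >= regions$xmin[r] & px$x <= regions$xmax[r] &
      px$y >= regions$ymin[r] & px$y <= regions$ymax[r]
    hits <- hits + inside
    lab[inside] <- regions$label[r]
  }
  if (any(hits > 1)) {
    i <- which(hits > 1)[1]
    stop("overlapping ROI rectangles: pixel (", px$run[i], ",", px$x[i], ",",
         px$y[i], ") is covered by more than one rectangle")
  }
  dataset$pixels[[column]] <- lab
  add_provenance(dataset, "roi_from_rectangles",
                 list(column = column, n_regions = nrow(regions)))
}

#' Chunked map-reduce over spectra
#'
#' Applies `map_fn` to every spectrum and combines the results with
#' `reduce_fn`, materializing at most `chunk_size` pixels at a time so peak
#' memory is O(chunk_size x features). `reduce_fn` must be associative and
#' commutative; combination follows a fixed pairwise (cascade) tree over
#' chunks, so the result is independent of `chunk_size` and `workers` up to
#' floating-point reassociation at the 1e-12 relative level.
#'
#' @param dataset an `msi_dataset` with shared axis.
#' @param map_fn function(intensity_vector, pixel_index) -> value.
#' @param reduce_fn function(a, b) -> combined value (associative and
#'   commutative; the caller's contract).
#' @param plan a [chunk_plan()].
#' @return the reduced aggregate value.
#' @export
process_in_chunks <- function(dataset, map_fn, reduce_fn,
                              plan = chunk_plan()) {
  n <- n_pixels(dataset)
  if (n == 0L) stop("empty dataset")
  starts <- seq(1L, n, by = plan$chunk_size)
  chunks <- lapply(starts, function(s) s:min(s + plan$chunk_size - 1L, n))
  do_chunk <- function(idx) {
    m <- msi_intensities(dataset, idx)
    vals <- vector("list", length(idx))
    for (j in seq_along(idx)) {
      vals[[j]] <- tryCatch(
        map_fn(m[, j], idx[j]),
        error = function(e) stop("map_fn failed at pixel ", idx[j], ": ",
                                 conditionMessage(e), call. = FALSE))
    }
    reduce_pairwise(vals, reduce_fn)
  }
  partials <- if (plan$workers > 1L &&
                  .Platform$OS.type == "unix" && length(chunks) > 1L) {
    res <- parallel::mclapply(chunks, do_chunk, mc.cores = plan$workers)
    err <- vapply(res, inherits, logical(1), "try-error")
    if (any(err)) stop(attr(res[[which(err)[1]]], "condition")$message,
                       call. = FALSE)
    res
  } else {
    lapply(chunks, do_chunk)
  }
  reduce_pairwise(partials, reduce_fn)
}

#' Chunking plan
#' @param chunk_size pixels materialized per chunk (>= 1).
#' @param workers degree of parallelism (>= 1; forked processes on unix).
#' @return a `chunk_plan` object.
#' @export
chunk_plan <- function(chunk_size = 256L, workers = 1L) {
  chunk_size <- as.integer(chunk_size); workers <- as.integer(workers)
  stopifnot(chunk_size >= 1L, workers >= 1L)
  structure(list(chunk_size = chunk_size, workers = workers),
            class = "chunk_plan")
}

# pairwise (cascade) reduction: fixed balanced tree so results do not depend
# on how work was split into chunks
reduce_pairwise <- function(vals, f) {
  while (length(vals) > 1L) {
    nxt <- vector("list", ceiling(length(vals) / 2))
    for (i in seq_along(nxt)) {
      a <- 2L * i - 1L; b <- 2L * i
      nxt[[i]] <- if (b <= length(vals)) f(vals[[a]], vals[[b]]) else vals[[a]]
    }
    vals <- nxt
  }
  vals[[1]]
}

#' Mean spectrum over all pixels
#'
#' @param dataset an `msi_dataset` with a shared m/z axis.
#' @param plan a [chunk_plan()] controlling chunked evaluation.
#' @return numeric vector: per-feature arithmetic mean intensity.
#' @export
mean_spectrum <- function(dataset, plan = chunk_plan()) {
  if (!has_shared_axis(dataset) && is.null(dataset$features))
    stop("mean spectrum requires a shared m/z axis; ",
         "resample processed-mode data first (resample_ppm_bins)")
  total <- process_in_chunks(dataset, function(x, i) x, `+`, plan)
  total / n_pixels(dataset)
}

#' Per-pixel total ion current
#' @param dataset an `msi_dataset`.
#' @param plan a [chunk_plan()].
#' @return numeric vector of spectrum intensity sums.
#' @export
tic <- function(dataset, plan = chunk_plan()) {
  n <- n_pixels(dataset)
  out <- numeric(n)
  starts <- seq(1L, n, by = plan$chunk_size)
  for (s in starts) {
    idx <- s:min(s + plan$chunk_size - 1L, n)
    out[idx] <- colSums(msi_intensities(dataset, idx))
  }
  out
}

#' Resolve a query m/z to a feature index
#'
#' Nearest feature within a ppm tolerance; a tie between two equally distant
#' features resolves to the lower m/z.
#'
#' @param dataset an `msi_dataset` with a feature table.
#' @param mz query m/z (Da).
#' @param tol_ppm tolerance in ppm; `Inf` accepts the nearest feature
#'   unconditionally.
#' @return integer feature index.
#' @export
resolve_feature <- function(dataset, mz, tol_ppm = Inf) {
  fm <- dataset$features$mz
  if (is.null(fm)) stop("dataset has no feature table")
  d <- abs(fm - mz)
  i <- which.min(d)  # which.min takes the first (= lower m/z) on ties
  if (d[i] / mz * 1e6 > tol_ppm)
    stop(sprintf(
      "no feature within %g ppm of m/z %.6g; nearest available is %.6g (%.1f ppm away)",
      tol_ppm, mz, fm[i], d[i] / mz * 1e6))
  i
}

#' Group-wise summary of one feature
#'
#' Resolves `mz` to the nearest feature within `tol_ppm` and summarizes its
#' pixel intensities by the requested annotation columns, e.g. mean tracer
#' intensity per condition and time point.
#'
#' @param dataset an `msi_dataset`.
#' @param mz query m/z (Da).
#' @param tol_ppm match tolerance (ppm).
#' @param groups character vector of pixel annotation columns.
#' @param stat summary function (default `mean`).
#' @return data.frame with one row per observed group-level combination and a
#'   `value` column.
#' @export
summarize_feature <- function(dataset, mz, tol_ppm = 100, groups,
                              stat = mean) {
  j <- resolve_feature(dataset, mz, tol_ppm)
  missing_cols <- setdiff(groups, names(dataset$pixels))
  if (length(missing_cols))
    stop("unknown annotation column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.numeric(msi_intensities(dataset)[j, ])
  g <- dataset$pixels[groups]
  keep <- stats::complete.cases(g)
  agg <- stats::aggregate(x[keep], by = as.list(g[keep, , drop = FALSE]),
                          FUN = stat)
  names(agg) <- c(groups, "value")
  agg
}
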