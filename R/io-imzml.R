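# imzML 1.1 reader/writer. A file pair is <name>.imzML (mzML-style XML with
# externalized binary arrays) + <name>.ibd (16-byte UUID followed by
# little-endian IEEE float arrays at the offsets recorded in the XML).

IMZML_OBO_VERSION <- "1.1.0"

CV_CONTINUOUS <- "IMS:1000030"
CV_PROCESSED  <- "IMS:1000031"
CV_UUID       <- "IMS:1000080"
CV_MD5        <- "IMS:1000090"
CV_EXT_OFFSET <- "IMS:1000102"
CV_EXT_LEN    <- "IMS:1000103"
CV_EXT_ENC    <- "IMS:1000104"
CV_POS_X      <- "IMS:1000050"
CV_POS_Y      <- "IMS:1000051"
CV_MZ_ARRAY   <- "MS:1000514"
CV_INT_ARRAY  <- "MS:1000515"
CV_F64        <- "MS:1000523"
CV_F32        <- "MS:1000521"
CV_I64        <- "MS:1000522"
CV_I32        <- "MS:1000519"

ibd_path_for <- function(path) {
  base <- sub("\\.[iI][mM][zZ][mM][lL]$", "", path)
  for (ext in c(".ibd", ".IBD")) {
    p <- paste0(base, ext)
    if (file.exists(p)) return(p)
  }
  paste0(base, ".ibd")
}

random_uuid_bytes <- function() {
  b <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  # RFC 4122 version-4 variant bits
  b[7] <- as.raw(bitwOr(bitwAnd(as.integer(b[7]), 0x0F), 0x40))
  b[9] <- as.raw(bitwOr(bitwAnd(as.integer(b[9]), 0x3F), 0x80))
  b
}

uuid_to_string <- function(bytes) {
  h <- paste(format(bytes), collapse = "")
  paste0("{", substr(h, 1, 8), "-", substr(h, 9, 12), "-",
         substr(h, 13, 16), "-", substr(h, 17, 20), "-",
         substr(h, 21, 32), "}")
}

uuid_normalize <- function(s) tolower(gsub("[{}-]", "", s))

precision_size <- function(precision) ifelse(precision == 64, 8L, 4L)

#' Write an imzML/ibd file pair
#'
#' Emits a standard-conformant imzML 1.1 XML document plus the binary `.ibd`
#' sibling (little-endian IEEE floats, fresh type-4 UUID, no compression).
#' Continuous mode stores the shared m/z array once; processed mode stores
#' one m/z array per spectrum. Internal 0-based grid coordinates are written
#' 1-based per the imzML convention.
#'
#' @param dataset an `msi_dataset`.
#' @param path output path for the `.imzML` file (`.ibd` written alongside).
#' @param mode `"continuous"` or `"processed"`.
#' @param precision 32 or 64 (bits per float).
#' @return invisibly, a list with the `imzml` and `ibd` paths and the UUID.
#' @export
write_imzml <- function(dataset, path, mode = c("continuous", "processed"),
                        precision = 64) {
  mode <- match.arg(mode)
  stopifnot(precision %in% c(32, 64))
  if (mode == "continuous" && !has_shared_axis(dataset))
    stop("continuous mode requires a shared m/z axis; ",
         "this dataset has per-spectrum axes (write mode = \"processed\")")
  n <- n_pixels(dataset)
  sz <- precision_size(precision)
  ibd <- ibd_path_for(path)
  uuid <- random_uuid_bytes()

  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  mz_off <- numeric(n); mz_len <- integer(n)
  int_off <- numeric(n); int_len <- integer(n)
  if (mode == "continuous") {
    axis <- dataset$mz
    writeBin(axis, con, size = sz, endian = "little")
    mz_off[] <- offset; mz_len[] <- length(axis)
    offset <- offset + length(axis) * sz
    for (i in seq_len(n)) {
      y <- as.numeric(msi_intensities(dataset, i))
      writeBin(y, con, size = sz, endian = "little")
      int_off[i] <- offset; int_len[i] <- length(y)
      offset <- offset + length(y) * sz
    }
  } else {
    for (i in seq_len(n)) {
      s <- msi_spectrum(dataset, i)
      writeBin(as.numeric(s$mz), con, size = sz, endian = "little")
      mz_off[i] <- offset; mz_len[i] <- length(s$mz)
      offset <- offset + length(s$mz) * sz
      writeBin(as.numeric(s$intensity), con, size = sz, endian = "little")
      int_off[i] <- offset; int_len[i] <- length(s$intensity)
      offset <- offset + length(s$intensity) * sz
    }
  }
  close(con); on.exit(NULL)

  md5 <- unname(tools::md5sum(ibd))
  prec_acc <- if (precision == 64) CV_F64 else CV_F32
  prec_name <- if (precision == 64) "64-bit float" else "32-bit float"
  mode_acc <- if (mode == "continuous") CV_CONTINUOUS else CV_PROCESSED

  cvp <- function(ref, acc, name, value = NULL) {
    v <- if (is.null(value)) "" else
      sprintf(' value="%s"', xml_escape(as.character(value)))
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>',
            ref, acc, name, v)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    sprintf('<cv id="IMS" fullName="Imaging MS Ontology" URI="https://ms-imaging.org/imzml/imagingMS.obo" version="%s"/>',
            IMZML_OBO_VERSION),
    '</cvList>',
    '<fileDescription>',
    '<fileContent>',
    cvp("IMS", mode_acc, mode),
    cvp("IMS", CV_UUID, "universally unique identifier",
        uuid_to_string(uuid)),
    cvp("IMS", CV_MD5, "ibd MD5", toupper(md5)),
    '</fileContent>',
    '</fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cvp("MS", CV_MZ_ARRAY, "m/z array"),
    cvp("MS", prec_acc, prec_name),
    cvp("MS", "MS:1000576", "no compression"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cvp("MS", CV_INT_ARRAY, "intensity array"),
    cvp("MS", prec_acc, prec_name),
    cvp("MS", "MS:1000576", "no compression"),
    cvp("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1">',
    '<scanSettings id="scanSettings1">',
    cvp("IMS", "IMS:1000042", "max count of pixels x",
        max(dataset$pixels$x) + 1L),
    cvp("IMS", "IMS:1000043", "max count of pixels y",
        max(dataset$pixels$y) + 1L),
    '</scanSettings>',
    '</scanSettingsList>',
    sprintf('<run id="%s">', xml_escape(as.character(dataset$pixels$run[1]))),
    sprintf('<spectrumList count="%d">', n))
  spec_lines <- vector("list", n)
  for (i in seq_len(n)) {
    spec_lines[[i]] <- c(
      sprintf('<spectrum id="spectrum=%d" index="%d" defaultArrayLength="0">',
              i, i - 1L),
      '<scanList count="1">',
      '<scan>',
      cvp("IMS", CV_POS_X, "position x", dataset$pixels$x[i] + 1L),
      cvp("IMS", CV_POS_Y, "position y", dataset$pixels$y[i] + 1L),
      '</scan>',
      '</scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cvp("IMS", CV_EXT_LEN, "external array length", mz_len[i]),
      cvp("IMS", CV_EXT_ENC, "external encoded length",
          format(mz_len[i] * sz, scientific = FALSE)),
      cvp("IMS", CV_EXT_OFFSET, "external offset",
          format(mz_off[i], scientific = FALSE)),
      '<binary/>',
      '</binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cvp("IMS", CV_EXT_LEN, "external array length", int_len[i]),
      cvp("IMS", CV_EXT_ENC, "external encoded length",
          format(int_len[i] * sz, scientific = FALSE)),
      cvp("IMS", CV_EXT_OFFSET, "external offset",
          format(int_off[i], scientific = FALSE)),
      '<binary/>',
      '</binaryDataArray>',
      '</binaryDataArrayList>',
      '</spectrum>')
  }
  lines <- c(lines, unlist(spec_lines),
             '</spectrumList>', '</run>', '</mzML>')
  writeLines(lines, path)
  invisible(list(imzml = path, ibd = ibd, uuid = uuid_to_string(uuid)))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

# Parse the XML half of the pair into a descriptor (no binary data touched
# beyond the UUID check).
parse_imzml_descriptor <- function(path) {
  doc <- xml2::read_xml(path)
  find_all <- function(node, name)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  cv_value <- function(node, acc) {
    p <- xml2::xml_find_first(
      node, sprintf(".//*[local-name()='cvParam'][@accession='%s']", acc))
    if (inherits(p, "xml_missing")) NA_character_
    else xml2::xml_attr(p, "value")
  }
  cv_has <- function(node, acc) {
    !inherits(xml2::xml_find_first(
      node, sprintf(".//*[local-name()='cvParam'][@accession='%s']", acc)),
      "xml_missing")
  }
  fc <- xml2::xml_find_first(doc, ".//*[local-name()='fileContent']")
  mode <- if (cv_has(fc, CV_CONTINUOUS)) "continuous"
          else if (cv_has(fc, CV_PROCESSED)) "processed"
          else NA_character_
  uuid <- cv_value(fc, CV_UUID)

  # referenceableParamGroup id -> (kind, precision)
  groups <- list()
  for (g in find_all(doc, "referenceableParamGroup")) {
    id <- xml2::xml_attr(g, "id")
    kind <- if (cv_has(g, CV_MZ_ARRAY)) "mz"
            else if (cv_has(g, CV_INT_ARRAY)) "intensity" else NA
    prec <- if (cv_has(g, CV_F64) || cv_has(g, CV_I64)) 64L
            else if (cv_has(g, CV_F32) || cv_has(g, CV_I32)) 32L else NA_integer_
    integer_type <- cv_has(g, CV_I64) || cv_has(g, CV_I32)
    groups[[id]] <- list(kind = kind, precision = prec,
                         integer = integer_type)
  }
  spectra <- find_all(doc, "spectrum")
  n <- length(spectra)
  rec <- data.frame(x = integer(n), y = integer(n),
                    mz_offset = numeric(n), mz_length = integer(n),
                    mz_precision = integer(n),
                    int_offset = numeric(n), int_length = integer(n),
                    int_precision = integer(n))
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    rec$x[i] <- as.integer(cv_value(sp, CV_POS_X))
    rec$y[i] <- as.integer(cv_value(sp, CV_POS_Y))
    for (bda in find_all(sp, "binaryDataArray")) {
      ref <- xml2::xml_find_first(
        bda, ".//*[local-name()='referenceableParamGroupRef']")
      kind <- NA; prec <- NA_integer_
      if (!inherits(ref, "xml_missing")) {
        gi <- groups[[xml2::xml_attr(ref, "ref")]]
        if (!is.null(gi)) { kind <- gi$kind; prec <- gi$precision }
      }
      if (is.na(kind)) {  # cvParams given inline instead of via a group ref
        kind <- if (cv_has(bda, CV_MZ_ARRAY)) "mz"
                else if (cv_has(bda, CV_INT_ARRAY)) "intensity" else NA
      }
      if (is.na(prec))
        prec <- if (cv_has(bda, CV_F64) || cv_has(bda, CV_I64)) 64L
                else if (cv_has(bda, CV_F32) || cv_has(bda, CV_I32)) 32L
                else NA_integer_
      off <- as.numeric(cv_value(bda, CV_EXT_OFFSET))
      len <- as.integer(cv_value(bda, CV_EXT_LEN))
      if (identical(kind, "mz")) {
        rec$mz_offset[i] <- off; rec$mz_length[i] <- len
        rec$mz_precision[i] <- prec
      } else if (identical(kind, "intensity")) {
        rec$int_offset[i] <- off; rec$int_length[i] <- len
        rec$int_precision[i] <- prec
      }
    }
  }
  run_node <- xml2::xml_find_first(doc, ".//*[local-name()='run']")
  run_id <- if (inherits(run_node, "xml_missing")) NA_character_
            else xml2::xml_attr(run_node, "id")
  list(mode = mode, uuid = uuid, records = rec, run = run_id)
}

new_ibd_store <- function(path, desc) {
  structure(
    list(path = path,
         mode = desc$mode,
         mz_offsets = desc$records$mz_offset,
         mz_lengths = desc$records$mz_length,
         mz_precision = desc$records$mz_precision,
         intensity_offsets = desc$records$int_offset,
         intensity_lengths = desc$records$int_length,
         intensity_precision = desc$records$int_precision),
    class = "msikit_ibd_store")
}

subset_ibd_store <- function(store, idx) {
  for (f in c("mz_offsets", "mz_lengths", "mz_precision",
              "intensity_offsets", "intensity_lengths",
              "intensity_precision"))
    store[[f]] <- store[[f]][idx]
  store
}

read_ibd_array <- function(con, offset, length, precision) {
  seek(con, where = offset, origin = "start")
  readBin(con, what = "double", n = length,
          size = precision_size(precision), endian = "little")
}

read_ibd_columns <- function(store, pixels) {
  if (length(unique(store$intensity_lengths[pixels])) > 1L)
    stop("processed-mode spectra have differing lengths; ",
         "resample onto a shared axis first (resample_ppm_bins)")
  con <- file(store$path, "rb")
  on.exit(close(con))
  nr <- store$intensity_lengths[pixels[1]]
  out <- matrix(0, nrow = nr, ncol = length(pixels))
  for (j in seq_along(pixels)) {
    i <- pixels[j]
    out[, j] <- read_ibd_array(con, store$intensity_offsets[i],
                               store$intensity_lengths[i],
                               store$intensity_precision[i])
  }
  out
}

read_ibd_spectrum <- function(store, i) {
  con <- file(store$path, "rb")
  on.exit(close(con))
  list(mz = read_ibd_array(con, store$mz_offsets[i], store$mz_lengths[i],
                           store$mz_precision[i]),
       intensity = read_ibd_array(con, store$intensity_offsets[i],
                                  store$intensity_lengths[i],
                                  store$intensity_precision[i]))
}

#' Read an imzML/ibd file pair
#'
#' Parses the XML descriptor, verifies the 16-byte UUID against the head of
#' the `.ibd` sibling and the recorded offsets against the file size, and
#' returns a lazily backed [msi_dataset()]: intensities are read from disk on
#' demand, per pixel chunk. Continuous mode yields a shared m/z axis;
#' processed mode yields per-spectrum axes.
#'
#' @param path path to the `.imzML` file (sibling `.ibd` required).
#' @param load if `TRUE`, materialize the full intensity matrix in memory
#'   (continuous mode only).
#' @return an `msi_dataset`.
#' @export
read_imzml <- function(path, load = FALSE) {
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) stop("missing .ibd sibling for ", path)
  desc <- parse_imzml_descriptor(path)
  con <- file(ibd, "rb"); head16 <- readBin(con, "raw", 16L); close(con)
  if (!is.na(desc$uuid) &&
      uuid_normalize(desc$uuid) != uuid_normalize(uuid_to_string(head16)))
    stop("UUID mismatch: imzML declares ", desc$uuid,
         " but ibd starts with ", uuid_to_string(head16))
  sizes <- file.info(ibd)$size
  rec <- desc$records
  ends <- pmax(rec$mz_offset + rec$mz_length * precision_size(rec$mz_precision),
               rec$int_offset + rec$int_length * precision_size(rec$int_precision))
  if (any(ends > sizes)) {
    bad <- which(ends > sizes)[1]
    stop("spectrum ", bad, ": binary array extends past end of ibd file (",
         format(ends[bad], scientific = FALSE), " > ", sizes, " bytes)")
  }
  store <- new_ibd_store(ibd, desc)
  run <- if (is.na(desc$run) || desc$run == "")
    sub("\\.[iI][mM][zZ][mM][lL]$", "", basename(path)) else desc$run
  pixels <- data.frame(run = run, x = rec$x - 1L, y = rec$y - 1L,
                       stringsAsFactors = FALSE)
  if (desc$mode == "continuous") {
    con <- file(ibd, "rb")
    axis <- read_ibd_array(con, rec$mz_offset[1], rec$mz_length[1],
                           rec$mz_precision[1])
    close(con)
    intens <- if (load) read_ibd_columns(store, seq_len(nrow(rec))) else store
    ds <- msi_dataset(intensities = intens, mz = axis, pixels = pixels,
                      provenance = list())
  } else {
    con <- file(ibd, "rb")
    axes <- lapply(seq_len(nrow(rec)), function(i)
      read_ibd_array(con, rec$mz_offset[i], rec$mz_length[i],
                     rec$mz_precision[i]))
    close(con)
    ds <- msi_dataset(intensities = store, mz = NULL, axes = axes,
                      pixels = pixels)
    ds$mz <- NULL  # processed mode: no shared axis
  }
  add_provenance(ds, "read_imzml", list(path = path, mode = desc$mode))
}

#' Validate an imzML/ibd file pair
#'
#' Structural conformance check: reports the declared mode and precision,
#' spectrum count, and a list of violated invariants (UUID mismatch, offsets
#' past end of file, overlapping binary regions, continuous-mode spectra not
#' sharing one m/z record). Problems are reported, not raised; only an
#' unreadable XML document is an error.
#'
#' @param path path to the `.imzML` file.
#' @return list with `mode`, `precision`, `n_spectra`, `violations`
#'   (character vector, empty when conformant).
#' @export
validate_imzml <- function(path) {
  desc <- parse_imzml_descriptor(path)
  rec <- desc$records
  violations <- character(0)
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) {
    violations <- c(violations, "missing .ibd sibling")
  } else {
    con <- file(ibd, "rb"); head16 <- readBin(con, "raw", 16L); close(con)
    if (is.na(desc$uuid)) {
      violations <- c(violations, "no UUID declared in imzML")
    } else if (uuid_normalize(desc$uuid) !=
               uuid_normalize(uuid_to_string(head16))) {
      violations <- c(violations,
                      sprintf("UUID mismatch (XML %s vs ibd %s)",
                              desc$uuid, uuid_to_string(head16)))
    }
    sz <- file.info(ibd)$size
    starts <- c(rec$mz_offset, rec$int_offset)
    bytes <- c(rec$mz_length * precision_size(rec$mz_precision),
               rec$int_length * precision_size(rec$int_precision))
    over <- which(starts + bytes > sz)
    if (length(over))
      violations <- c(violations,
                      sprintf("%d binary array(s) extend past end of ibd",
                              length(over)))
    # overlap check on distinct regions (continuous mode legitimately reuses
    # one shared m/z region across spectra)
    reg <- unique(data.frame(start = starts, end = starts + bytes))
    reg <- reg[order(reg$start), ]
    if (nrow(reg) > 1) {
      ov <- which(reg$start[-1] < reg$end[-nrow(reg)])
      if (length(ov))
        violations <- c(violations,
                        sprintf("%d overlapping binary region(s) in ibd",
                                length(ov)))
    }
  }
  if (is.na(desc$mode))
    violations <- c(violations, "mode (continuous/processed) not declared")
  if (identical(desc$mode, "continuous") && nrow(rec) > 1 &&
      (length(unique(rec$mz_offset)) != 1L))
    violations <- c(violations,
                    "continuous mode but spectra do not share one m/z array")
  list(mode = desc$mode,
       precision = if (nrow(rec)) rec$int_precision[1] else NA_integer_,
       n_spectra = nrow(rec),
       violations = violations)
}
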