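.WELL_SCHEMA <- c("plate_id", "well", "row", "col", "role", "gene_id",
                  "oligo_id")

## shared CSV reader with well-name and key validation; unknown columns are
## preserved untouched
.readScreenCsv <- function(path, required, n_rows = 16L, n_cols = 24L,
                           unique_key = NULL) {
  .checkTrue(file.exists(path), "file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(tab))
  .checkTrue(length(miss) == 0, path, ": missing column(s) ",
             paste(miss, collapse = ", "))
  if ("well" %in% names(tab)) {
    ok <- grepl(sprintf("^[A-%s](0[1-9]|1[0-9]|2[0-4])$",
                        LETTERS[n_rows]), tab$well) &
      suppressWarnings(as.integer(substring(tab$well, 2))) <= n_cols
    if (!all(ok)) {
      stop(path, ": malformed well name at row(s) ",
           paste(utils::head(which(!ok), 5), collapse = ", "), " (",
           paste(utils::head(unique(tab$well[!ok]), 5), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  if (!is.null(unique_key)) {
    key <- do.call(paste, tab[unique_key])
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop(path, ": duplicate ", paste(unique_key, collapse = "+"),
           " at row(s) ", paste(utils::head(dup, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  tab
}

#' Read / write per-well summary tables
#'
#' CSV with one row per (replicate, plate, well): layout metadata, feature
#' means, `n_nuclei`. Well names are validated against the plate format and
#' duplicate (replicate, plate, well) keys are rejected with row numbers.
#' Unknown columns are preserved, so round-trips are lossless.
#'
#' @param path CSV file path.
#' @param table a per-well data.frame (as from [aggregateWells()]).
#' @param n_rows,n_cols plate format used for well-name validation.
#' @return `readWellTable`: data.frame; `writeWellTable`: the path,
#'   invisibly.
#' @export
readWellTable <- function(path, n_rows = 16L, n_cols = 24L) {
  tab <- .readScreenCsv(path, c(.WELL_SCHEMA, "n_nuclei"), n_rows, n_cols)
  key <- c(if ("replicate" %in% names(tab)) "replicate", "plate_id", "well")
  dupk <- do.call(paste, tab[key])
  if (anyDuplicated(dupk)) {
    stop(path, ": duplicate (", paste(key, collapse = ", "), ") at row(s) ",
         paste(utils::head(which(duplicated(dupk)), 5), collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' @rdname readWellTable
#' @export
writeWellTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write per-nucleus tables
#'
#' CSV with one row per segmented nucleus (schema of [simulateCells()]).
#'
#' @param path CSV file path.
#' @param table per-nucleus data.frame.
#' @param n_rows,n_cols plate format for well-name validation.
#' @return `readCellTable`: data.frame; `writeCellTable`: the path,
#'   invisibly.
#' @export
readCellTable <- function(path, n_rows = 16L, n_cols = 24L) {
  .readScreenCsv(path, c("plate_id", "well", "area", "perimeter",
                         "circularity"), n_rows, n_cols)
}

#' @rdname readCellTable
#' @export
writeCellTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write single-channel images
#'
#' Grayscale TIFF (8- or 16-bit, lossless round-trip of integer pixel values)
#' or PNG (8-bit on write). Multi-channel (RGB) files are rejected: fields
#' are stored one file per channel.
#'
#' @param path image path (`.tif`/`.tiff`/`.png`).
#' @param img integer/numeric matrix of pixel values in `[0, 2^bits - 1]`.
#' @param bits bit depth for writing (8 or 16; PNG supports 8).
#' @return `readImageGray`: integer matrix with attribute `bits`;
#'   `writeImageGray`: the path, invisibly.
#' @export
#' @examples
#' p <- tempfile(fileext = ".tif")
#' writeImageGray(matrix(0:24 * 1000L, 5), p)
#' img <- readImageGray(p)
readImageGray <- function(path) {
  .checkTrue(file.exists(path), "file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  } else if (ext == "png") {
    x <- png::readPNG(path)
    bits <- 8L
    x <- round(x * (2^bits - 1))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(x)) != 2) {
    stop(path, ": multi-channel image; single-channel grayscale required",
         call. = FALSE)
  }
  out <- matrix(as.integer(x), nrow(x), ncol(x))
  attr(out, "bits") <- as.integer(bits)
  out
}

#' @rdname readImageGray
#' @export
writeImageGray <- function(img, path, bits = 16L) {
  .checkTrue(is.matrix(img), "img must be a 2-D matrix")
  .checkTrue(bits %in% c(8L, 16L), "unsupported bit depth: ", bits)
  maxv <- 2^bits - 1
  .checkTrue(all(img >= 0 & img <= maxv),
             "pixel values out of range for ", bits, "-bit output")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img / maxv, path, bits.per.sample = bits)
  } else if (ext == "png") {
    .checkTrue(bits == 8L, "PNG output is written at 8-bit depth")
    png::writePNG(img / maxv, path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Serialize / restore a screen layout
#'
#' @param layout a [ScreenLayout-class].
#' @param path CSV path.
#' @param seed seed recorded in the restored object.
#' @return `writeLayout`: the path, invisibly; `readLayout`: a
#'   [ScreenLayout-class].
#' @export
writeLayout <- function(layout, path) {
  w <- layoutWells(layout)
  attr <- data.frame(plate_id = "#format", well = NA, row = layout@n_rows,
                     col = layout@n_cols, role = NA, gene_id = NA,
                     oligo_id = NA)
  utils::write.csv(rbind(attr, w), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeLayout
#' @export
readLayout <- function(path, seed = 1L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  fmt <- tab[tab$plate_id == "#format", , drop = FALSE]
  w <- tab[tab$plate_id != "#format", , drop = FALSE]
  w$gene_id[w$gene_id == ""] <- NA
  w$oligo_id[w$oligo_id == ""] <- NA
  rownames(w) <- NULL
  new("ScreenLayout", plate_ids = unique(w$plate_id),
      n_rows = as.integer(fmt$row[1]), n_cols = as.integer(fmt$col[1]),
      wells = w, seed = as.integer(seed))
}

#' Serialize / restore ground truth
#'
#' JSON round-trip of a [GroundTruth-class]; together with the recorded seed
#' this regenerates a screen bit-identically.
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON path.
#' @return `writeGroundTruth`: the path, invisibly; `readGroundTruth`: a
#'   [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  obj <- list(
    genes = rownames(truth@gene_effects),
    features = colnames(truth@gene_effects),
    gene_effects = unname(truth@gene_effects),
    cytotoxic = unname(truth@cytotoxic),
    control_effects = lapply(truth@control_effects, as.list),
    plates = rownames(truth@plate_row_amp),
    effect_cols = colnames(truth@plate_row_amp),
    plate_row_amp = unname(truth@plate_row_amp),
    plate_col_amp = unname(truth@plate_col_amp),
    plate_edge = unname(truth@plate_edge),
    baseline = truth@baseline,
    cells_mean = truth@cells_mean,
    cells_dispersion = truth@cells_dispersion,
    seed = truth@seed
  )
  ## I(17) significant digits: doubles round-trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  dimn <- list(o$plates, o$effect_cols)
  mk <- function(m) matrix(as.numeric(m), length(o$plates),
                           length(o$effect_cols), dimnames = dimn)
  ce <- lapply(o$control_effects, unlist)
  new("GroundTruth",
      gene_effects = matrix(as.numeric(o$gene_effects), length(o$genes),
                            length(o$features),
                            dimnames = list(o$genes, o$features)),
      cytotoxic = stats::setNames(as.numeric(o$cytotoxic), o$genes),
      control_effects = ce,
      plate_row_amp = mk(o$plate_row_amp), plate_col_amp = mk(o$plate_col_amp),
      plate_edge = mk(o$plate_edge),
      baseline = as.data.frame(o$baseline),
      cells_mean = o$cells_mean, cells_dispersion = o$cells_dispersion,
      seed = as.integer(o$seed))
}
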