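# Readers and writers for every artifact the pipeline touches: multi-channel
# TIFF micrographs, 16-bit label masks, measurement tables, truth tables,
# exclusion lists and config echoes. All writers are deterministic: fixed
# column order and fixed 6-significant-digit float formatting, so identical
# inputs produce byte-identical files.

MAX_DN <- 65535  # 16-bit dynamic range of the stored TIFFs

#' Construct a multi-channel micrograph
#'
#' @param channels named list of numeric matrices (one per channel), all the
#'   same dimension, non-negative intensities
#' @param pixel_size pixel size in micrometres per pixel
#' @param source_path provenance string (file the image came from, or
#'   `"simulated"`)
#' @return an object of class `micrograph`
#' @export
micrograph <- function(channels, pixel_size, source_path = "") {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share one shape")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number (micrometres/pixel)")
  structure(list(channels = channels, pixel_size = pixel_size,
                 source_path = source_path),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<micrograph> %d x %d px, %d channel(s) [%s], %.4g um/px\n",
              d[1], d[2], length(x$channels),
              paste(names(x$channels), collapse = ", "), x$pixel_size))
  invisible(x)
}

channel_names <- function(m) names(m$channels)
field_shape <- function(m) dim(m$channels[[1]])

#' Read a multi-channel micrograph from a TIFF file
#'
#' Channels are stored as pages (ImageJ-style). Pixel size is taken from the
#' TIFF resolution metadata when present; otherwise `pixel_size` must be
#' supplied explicitly.
#'
#' @param path TIFF file path
#' @param channel_names character vector naming the channels; its length must
#'   equal the page count
#' @param pixel_size micrometres per pixel, used when the file carries no
#'   resolution metadata
#' @return a [micrograph()]
#' @export
read_micrograph <- function(path, channel_names, pixel_size = NULL) {
  if (!file.exists(path)) stop("micrograph file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channel_names))
    stop(sprintf("channel-count mismatch: file has %d page(s), %d name(s) given",
                 length(pages), length(channel_names)))
  ps <- pixel_size
  xres <- attr(pages[[1]], "x.resolution")
  if (is.null(ps) && !is.null(xres) && is.finite(xres) && xres > 0) {
    unit <- attr(pages[[1]], "resolution.unit") %||% "inch"
    um_per_unit <- switch(unit, cm = 1e4, inch = 25400, 1e4)
    ps <- um_per_unit / xres
  }
  if (is.null(ps))
    stop("no pixel-size metadata in ", path,
         " and no pixel_size override supplied")
  chans <- lapply(pages, function(p) {
    m <- unclass(p); attributes(m) <- list(dim = dim(p)); m + 0
  })
  names(chans) <- channel_names
  micrograph(chans, pixel_size = ps, source_path = path)
}

#' Write a micrograph as a multi-page 16-bit TIFF
#'
#' Intensities are rounded and clipped to the 16-bit range. Note the TIFF
#' carries no resolution tags; pixel size travels in the per-field config
#' echo written by [write_field()].
#'
#' @param m a [micrograph()]
#' @param path output path
#' @export
write_micrograph <- function(m, path) {
  pages <- lapply(m$channels, function(ch)
    pmin(pmax(round(ch), 0), MAX_DN) / MAX_DN)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  invisible(path)
}

#' Read or write a cell label mask (single-page 16-bit TIFF)
#'
#' @param mask integer matrix, 0 = background, k >= 1 = cell k
#' @param path file path
#' @return `read_label_mask` returns an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(all(mask >= 0), max(mask) <= MAX_DN)
  tiff::writeTIFF(mask / MAX_DN, path, bits.per.sample = 16L,
                  compression = "LZW")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop("label mask not found: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

# --- deterministic CSV serialisation ----------------------------------------

# 6 significant digits; Inf/NaN as "inf"/"nan" tokens (signed inf kept).
fmt_num <- function(x) {
  out <- character(length(x))
  out[is.na(x) & !is.nan(x)] <- "NA"
  out[is.nan(x)] <- "nan"
  out[is.infinite(x) & x > 0] <- "inf"
  out[is.infinite(x) & x < 0] <- "-inf"
  ok <- is.finite(x)
  out[ok] <- formatC(signif(x[ok], 6), format = "g", digits = 6)
  out
}

parse_num <- function(s) {
  x <- suppressWarnings(as.numeric(s))
  x[s == "inf"] <- Inf
  x[s == "-inf"] <- -Inf
  x[s == "nan"] <- NaN
  x
}

MEASUREMENT_COLS <- c(
  "field_id", "cell_label", "channel",
  "mean_whole", "integrated_whole", "n_whole",
  "mean_membrane", "integrated_membrane", "n_membrane",
  "mean_interior", "integrated_interior", "n_interior",
  "area_um2", "pm_cytosol_ratio", "ratio_undefined", "degenerate",
  "condition", "replicate")

empty_measurements <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), length(MEASUREMENT_COLS)),
                               MEASUREMENT_COLS), stringsAsFactors = FALSE)
  num <- setdiff(MEASUREMENT_COLS,
                 c("field_id", "channel", "condition", "replicate",
                   "ratio_undefined", "degenerate"))
  for (cn in num) df[[cn]] <- numeric(0)
  df$ratio_undefined <- logical(0); df$degenerate <- logical(0)
  df$cell_label <- integer(0)
  df
}

#' Write / read a per-cell measurement table
#'
#' One row per (field, cell, channel). Column order is fixed, floats are
#' serialised with 6 significant digits, and infinity/NaN ratio sentinels are
#' written as the literal tokens `inf` / `nan`, so that files round-trip and
#' identical tables produce byte-identical CSVs.
#'
#' @param tbl measurement data.frame as produced by [quantify_field()]
#' @param path output CSV path
#' @export
write_measurements <- function(tbl, path) {
  miss <- setdiff(MEASUREMENT_COLS, names(tbl))
  for (cn in miss) tbl[[cn]] <- if (cn %in% c("condition", "replicate")) "" else NA
  tbl <- tbl[, MEASUREMENT_COLS, drop = FALSE]
  out <- tbl
  for (cn in names(out))
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) out[[cn]] <- fmt_num(out[[cn]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0) {
    out <- empty_measurements()
    return(out)
  }
  num <- c("mean_whole", "integrated_whole", "n_whole", "mean_membrane",
           "integrated_membrane", "n_membrane", "mean_interior",
           "integrated_interior", "n_interior", "area_um2", "pm_cytosol_ratio")
  for (cn in num) df[[cn]] <- parse_num(df[[cn]])
  df$cell_label <- as.integer(df$cell_label)
  df$ratio_undefined <- df$ratio_undefined %in% c("TRUE", "true", "1")
  df$degenerate <- df$degenerate %in% c("TRUE", "true", "1")
  df
}

#' Read an exclusion list of manually curated cells
#'
#' Plain text, one `field_id,cell_label` per line; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path
#' @return data.frame with columns `field_id`, `cell_label`
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("exclusion list not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(field_id = character(0), cell_label = integer(0)))
  parts <- strsplit(lines, ",")
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) stop("malformed exclusion-list line(s): ",
                     paste(lines[bad], collapse = "; "))
  data.frame(field_id = trimws(vapply(parts, `[`, "", 1L)),
             cell_label = as.integer(vapply(parts, `[`, "", 2L)))
}

# Truth-table CSV (one row per simulated cell; see simulate_field docs).
write_truth <- function(truth, path) {
  df <- truth$cells
  out <- df
  for (cn in names(out))
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) out[[cn]] <- fmt_num(out[[cn]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
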