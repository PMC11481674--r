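# Per-cell compartmentalization and intensity measurement. The membrane band
# is the set of pixels within a half-width of the segmentation-mask boundary
# on both sides of it (the mask edge stands in for the plasma-membrane
# mid-line); the interior ("cytosol") is the mask eroded by the same
# half-width, so bright cortical signal cannot contaminate it.

# Core geometry: pixel index sets for one labelled cell. Distances are
# Euclidean distance-transform values on the binary mask, with the
# half-open convention that a pixel at distance exactly `band_px` belongs
# to the band. Outer-band pixels are background pixels owned by the nearest
# cell boundary; ties go to the lower label; pixels of other cells are never
# claimed.
compartment_indices <- function(mask, label, band_px,
                                band_mode = c("symmetric", "inner")) {
  band_mode <- match.arg(band_mode)
  stopifnot(band_px >= 1)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask == label, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("label ", label, " absent from mask")
  marg <- ceiling(band_px) + 2L
  i0 <- max(1L, min(idx[, 1]) - marg); i1 <- min(nr, max(idx[, 1]) + marg)
  j0 <- max(1L, min(idx[, 2]) - marg); j1 <- min(nc, max(idx[, 2]) + marg)
  w <- mask[i0:i1, j0:j1]
  cellw <- w == label

  din <- as.matrix(EBImage::distmap(cellw * 1))
  inner_band <- cellw & din <= band_px
  interior <- cellw & din > band_px

  if (band_mode == "symmetric") {
    dself <- as.matrix(EBImage::distmap(1 - cellw))  # bg distance to this cell
    cand <- (w == 0L) & dself <= band_px
    if (any(cand)) {
      others <- setdiff(sort(unique(w[w > 0L])), label)
      for (lab2 in others) {
        d2 <- as.matrix(EBImage::distmap(1 - (w == lab2)))
        # keep pixels strictly nearer to us, or tied with lower label winning
        cand <- cand & (dself < d2 | (dself == d2 & label < lab2))
      }
    }
    outer_band <- cand
  } else {
    outer_band <- matrix(FALSE, nrow(w), ncol(w))
  }

  to_full <- function(m) {
    ij <- which(m, arr.ind = TRUE)
    (ij[, 2] + j0 - 2L) * nr + (ij[, 1] + i0 - 1L)  # linear index in full mask
  }
  membrane <- to_full(inner_band | outer_band)
  list(label = label,
       whole = to_full(cellw),
       membrane = membrane,
       membrane_in_mask = to_full(inner_band),
       interior = to_full(interior),
       degenerate = !any(interior))
}

#' Partition a cell into whole / membrane-band / interior pixel sets
#'
#' @param roi a `cell_roi` from [mask_to_rois()] (only its label is used)
#' @param mask integer label mask the ROI came from
#' @param band_halfwidth band half-width in micrometres
#' @param pixel_size micrometres per pixel
#' @param band_mode `"symmetric"` (band on both sides of the mask edge,
#'   default) or `"inner"` (intra-mask band pixels only)
#' @return list with linear pixel-index vectors `whole`, `membrane`,
#'   `membrane_in_mask`, `interior`, and a `degenerate` flag (empty
#'   interior). For every non-degenerate cell
#'   `length(whole) == length(interior) + length(membrane_in_mask)`.
#' @export
compartmentalize <- function(roi, mask, band_halfwidth, pixel_size,
                             band_mode = c("symmetric", "inner")) {
  band_px <- band_halfwidth / pixel_size
  if (band_px < 1)
    stop("band_halfwidth must convert to at least one pixel")
  compartment_indices(mask, roi$label, band_px, match.arg(band_mode))
}

# Ratio with the division contract: +Inf sentinel when the interior mean is
# zero and the membrane mean positive; NaN (undefined) when both are zero.
ratio_value <- function(mem_mean, int_mean) {
  if (int_mean == 0) {
    if (mem_mean > 0) Inf else NaN
  } else mem_mean / int_mean
}

#' Measure one cell's compartment intensities and PM/cytosol ratio
#'
#' @param m a [micrograph()]
#' @param comp compartment index sets from [compartmentalize()]
#' @param field_id field identifier recorded in the output rows
#' @return data.frame, one row per channel, with mean/integrated intensity
#'   and pixel count for the whole-cell, membrane-band and interior
#'   compartments, the cell cross-sectional area (um^2) and the
#'   PM/cytosol mean-intensity ratio (`Inf` sentinel / `NaN` + flag per the
#'   division contract)
#' @export
measure_cell <- function(m, comp, field_id = "field1") {
  ps <- m$pixel_size
  rows <- lapply(names(m$channels), function(chn) {
    img <- m$channels[[chn]]
    stat <- function(idx) {
      n <- length(idx)
      tot <- if (n) sum(img[idx]) else 0
      c(mean = if (n) tot / n else NaN, integrated = tot, n = n)
    }
    sw <- stat(comp$whole); sm <- stat(comp$membrane); si <- stat(comp$interior)
    ratio <- if (comp$degenerate) NA_real_ else ratio_value(sm["mean"], si["mean"])
    data.frame(field_id = field_id, cell_label = comp$label, channel = chn,
               mean_whole = sw["mean"], integrated_whole = sw["integrated"],
               n_whole = sw["n"],
               mean_membrane = sm["mean"], integrated_membrane = sm["integrated"],
               n_membrane = sm["n"],
               mean_interior = si["mean"], integrated_interior = si["integrated"],
               n_interior = si["n"],
               area_um2 = sw["n"] * ps^2,
               pm_cytosol_ratio = ratio,
               ratio_undefined = !comp$degenerate && is.nan(ratio),
               degenerate = comp$degenerate,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Extract the PM/cytosol ratio for one channel from a measurement table
#'
#' The ratio is scale-equivariant: multiplying all pixel intensities by a
#' positive constant leaves it unchanged.
#'
#' @param meas data.frame from [measure_cell()] or [quantify_field()]
#' @param channel channel name
#' @return numeric vector of ratios (may contain the `Inf` sentinel or `NaN`)
#' @export
pm_cytosol_ratio <- function(meas, channel) {
  rows <- meas[meas$channel == channel, , drop = FALSE]
  if (nrow(rows) == 0) stop("channel not present: ", channel)
  rows$pm_cytosol_ratio
}

#' Quantify every retained cell of a field
#'
#' @param m a [micrograph()]
#' @param mask integer label mask
#' @param rois list of `cell_roi` (typically after [filter_edge_cells()] and
#'   [filter_dead_cells()]); only ROIs with all curation flags clear are
#'   measured
#' @param band_halfwidth membrane-band half-width, micrometres
#' @param band_mode see [compartmentalize()]
#' @param field_id field identifier for the output rows
#' @return measurement data.frame, one row per (cell, channel); degenerate
#'   cells (interior emptied by the band) are flagged and carry no ratio
#' @export
quantify_field <- function(m, mask, rois, band_halfwidth = 0.25,
                           band_mode = c("symmetric", "inner"),
                           field_id = "field1") {
  band_mode <- match.arg(band_mode)
  keep <- Filter(roi_retained, rois)
  cq_log("quantify %s: %d retained of %d ROIs", field_id, length(keep),
         length(rois))
  out <- lapply(keep, function(roi) {
    comp <- compartmentalize(roi, mask, band_halfwidth, m$pixel_size,
                             band_mode)
    if (comp$degenerate)
      cq_log("cell %d: interior empty at band %.3g um, flagged degenerate",
             roi$label, band_halfwidth)
    measure_cell(m, comp, field_id)
  })
  if (length(out) == 0) return(empty_measurements())
  res <- do.call(rbind, out)
  res$condition <- ""; res$replicate <- ""
  res
}
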