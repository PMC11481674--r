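# Label-mask curation: connected labels -> cell ROIs with moment-equivalent
# ellipses, removal of incompletely imaged (border-touching) cells, and
# rule-based dead-cell / manual exclusion with an audit trail. A simple
# threshold + watershed segmenter is provided for synthetic data in place of
# an external Cellpose mask.

roi_retained <- function(roi) {
  !roi$flags$edge_touching && !roi$flags$excluded_dead &&
    !roi$flags$excluded_manual
}

#' ROIs retained after curation
#' @param rois list of `cell_roi`
#' @return the sub-list with all curation flags clear
#' @export
retained_rois <- function(rois) Filter(roi_retained, rois)

# Moment-equivalent ellipse of a pixel set: semi-axes are 2*sqrt of the
# eigenvalues of the coordinate covariance (exact for a filled ellipse);
# orientation is the major-axis eigenvector angle folded into [0, pi).
moment_ellipse <- function(xy) {
  mu <- colMeans(xy)
  n <- nrow(xy)
  dx <- xy[, 1] - mu[1]; dy <- xy[, 2] - mu[2]
  # 1/12 term: variance of the unit-square pixel footprint
  sxx <- sum(dx * dx) / n + 1 / 12
  syy <- sum(dy * dy) / n + 1 / 12
  sxy <- sum(dx * dy) / n
  e <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  a <- 2 * sqrt(e$values[1]); b <- 2 * sqrt(e$values[2])
  v <- e$vectors[, 1]
  ellipse(mu[1], mu[2], a, b, atan2(v[2], v[1]) %% pi)
}

new_cell_roi <- function(label, contour, ell, pixel_count,
                         degenerate_orientation) {
  structure(list(label = label, contour = contour, ellipse = ell,
                 pixel_count = pixel_count,
                 degenerate_orientation = degenerate_orientation,
                 flags = list(edge_touching = FALSE, excluded_dead = FALSE,
                              excluded_manual = FALSE)),
            class = "cell_roi")
}

#' @export
print.cell_roi <- function(x, ...) {
  fl <- names(Filter(isTRUE, x$flags))
  cat(sprintf("<cell_roi> label %d: %d px, ellipse a=%.1f b=%.1f theta=%.2f%s\n",
              x$label, x$pixel_count, x$ellipse$a, x$ellipse$b,
              x$ellipse$theta,
              if (length(fl)) paste0(" [", paste(fl, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Convert a label mask into cell ROIs
#'
#' Each positive label becomes one ROI with its boundary contour (traced on
#' the label region) and a moment-equivalent fitted ellipse, mirroring the
#' "fit ellipse" of a Fiji ROI workflow. Labels smaller than `min_size`
#' pixels are dropped with a warning.
#'
#' @param mask integer label mask (0 background)
#' @param min_size minimum cell size in pixels
#' @return list of `cell_roi`; each has fields `label`, `contour` (n x 2
#'   matrix of 0-based x,y boundary-pixel coordinates), `ellipse`,
#'   `pixel_count`, `degenerate_orientation` (near-circular: a/b < 1.02,
#'   orientation arbitrary) and curation `flags`
#' @export
mask_to_rois <- function(mask, min_size = 200L) {
  labs <- sort(unique(mask[mask > 0L]))
  rois <- list()
  for (lab in labs) {
    idx <- which(mask == lab, arr.ind = TRUE)
    if (nrow(idx) < min_size) {
      warning(sprintf("label %d dropped: %d px < min_size %d", lab,
                      nrow(idx), min_size))
      next
    }
    xy <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    ell <- moment_ellipse(xy)
    # contour traced on a cropped window, then shifted back to field coords
    i0 <- min(idx[, 1]); j0 <- min(idx[, 2])
    wbin <- matrix(0L, max(idx[, 1]) - i0 + 3L, max(idx[, 2]) - j0 + 3L)
    wbin[cbind(idx[, 1] - i0 + 2L, idx[, 2] - j0 + 2L)] <- 1L
    oc <- EBImage::ocontour(wbin)[[1]]
    contour <- cbind(x = oc[, 2] + j0 - 2L, y = oc[, 1] + i0 - 2L)
    rois[[length(rois) + 1L]] <-
      new_cell_roi(as.integer(lab), contour, ell, nrow(idx),
                   degenerate_orientation = ell$a / ell$b < 1.02)
  }
  cq_log("mask_to_rois: %d label(s) -> %d ROI(s)", length(labs), length(rois))
  rois
}

#' Flag incompletely imaged cells at the field border
#'
#' A cell whose mask pixels come within `margin` pixels of the field border
#' (inclusive: a cell exactly tangent to the margin is flagged) is marked
#' `edge_touching` and excluded downstream.
#'
#' @param rois list of `cell_roi`
#' @param field_shape image size `(rows, cols)`
#' @param margin border margin in pixels
#' @return the ROI list with `edge_touching` flags set
#' @export
filter_edge_cells <- function(rois, field_shape, margin = 1L) {
  nr <- field_shape[1]; nc <- field_shape[2]
  n_flag <- 0L
  rois <- lapply(rois, function(roi) {
    cc <- roi$contour
    touch <- any(cc[, "x"] <= margin - 1L) || any(cc[, "y"] <= margin - 1L) ||
      any(cc[, "x"] >= nc - margin) || any(cc[, "y"] >= nr - margin)
    if (touch) { roi$flags$edge_touching <- TRUE; n_flag <<- n_flag + 1L }
    roi
  })
  cq_log("filter_edge_cells: %d of %d flagged edge-touching", n_flag,
         length(rois))
  rois
}

#' Flag dead or manually excluded cells
#'
#' Reproducible stand-in for manual ROI curation: cells named in an
#' exclusion list are flagged `excluded_manual`; under the
#' `"intensity-outlier"` criterion, cells whose whole-cell mean intensity
#' deviates from the field median by more than `k` scaled median absolute
#' deviations are flagged `excluded_dead`.
#'
#' @param rois list of `cell_roi`
#' @param m a [micrograph()] (first channel is used for the outlier rule)
#' @param mask label mask pairing the ROIs with their pixels
#' @param exclusion_list data.frame from [read_exclusion_list()], or `NULL`
#' @param criterion `"list-only"` or `"intensity-outlier"`
#' @param field_id this field's identifier (matched against the list)
#' @param k MAD multiplier for the outlier rule
#' @return the ROI list with exclusion flags set
#' @export
filter_dead_cells <- function(rois, m, mask, exclusion_list = NULL,
                              criterion = c("list-only", "intensity-outlier"),
                              field_id = "field1", k = 5) {
  criterion <- match.arg(criterion)
  labs <- vapply(rois, function(r) r$label, 0L)
  if (!is.null(exclusion_list) && nrow(exclusion_list) > 0) {
    here <- exclusion_list[exclusion_list$field_id == field_id, , drop = FALSE]
    missing <- setdiff(here$cell_label, labs)
    if (length(missing))
      warning("exclusion list names absent label(s): ",
              paste(missing, collapse = ", "))
    rois <- lapply(rois, function(roi) {
      if (roi$label %in% here$cell_label) roi$flags$excluded_manual <- TRUE
      roi
    })
  }
  if (criterion == "intensity-outlier" && length(rois) > 0) {
    img <- m$channels[[1]]
    means <- vapply(rois, function(roi)
      mean(img[mask == roi$label]), numeric(1))
    med <- median(means); s <- mad(means)
    if (s > 0) {
      out <- abs(means - med) > k * s
      rois <- Map(function(roi, o) {
        if (o) roi$flags$excluded_dead <- TRUE
        roi
      }, rois, out)
    }
  }
  n_dead <- sum(vapply(rois, function(r) r$flags$excluded_dead, logical(1)))
  n_man <- sum(vapply(rois, function(r) r$flags$excluded_manual, logical(1)))
  cq_log("filter_dead_cells (%s): %d outlier, %d manual of %d", criterion,
         n_dead, n_man, length(rois))
  rois
}

# --- built-in segmenter -----------------------------------------------------

# Refine per-label ellipse semi-axes to the radial intensity ridge (the
# membrane ring), so the mask edge intersects the ring in its middle. Falls
# back to the threshold-derived region when no ridge is prominent.
refine_to_ridge <- function(img, ell, n_rays = 72L) {
  tt <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  scales <- seq(0.7, 1.35, by = 0.01)
  prof <- sapply(tt, function(t) {
    p0 <- ellipse_point(ell, t)
    dx <- p0[1] - ell$cx; dy <- p0[2] - ell$cy
    bilinear(img, ell$cx + scales * dx, ell$cy + scales * dy)
  })
  mean_prof <- rowMeans(prof)
  pk <- which.max(mean_prof)
  interior_lvl <- median(bilinear(img, ell$cx + 0.3 * (ellipse_point(ell, tt)[, 1] - ell$cx),
                                  ell$cy + 0.3 * (ellipse_point(ell, tt)[, 2] - ell$cy)))
  ridge_contrast <- mean_prof[pk] / max(interior_lvl, .Machine$double.eps)
  if (ridge_contrast < 1.3 || pk %in% c(1L, length(scales)))
    return(NULL)  # no prominent ring -> keep threshold boundary
  # per-ray ridge radii -> least-squares ellipse radius fit (2 parameters)
  ridge_scale <- apply(prof, 2, function(v) scales[which.max(v)])
  p0 <- ellipse_point(ell, tt)
  rx <- ell$cx + ridge_scale * (p0[, 1] - ell$cx) - ell$cx
  ry <- ell$cy + ridge_scale * (p0[, 2] - ell$cy) - ell$cy
  co <- cos(ell$theta); so <- sin(ell$theta)
  u <- rx * co + ry * so; v <- -rx * so + ry * co
  phi <- atan2(v, u)            # ellipse-frame polar angle of each ridge point
  r_obs <- sqrt(u^2 + v^2)
  fit <- optim(c(ell$a, ell$b), function(ab) {
    r_mod <- ab[1] * ab[2] /
      sqrt((ab[2] * cos(phi))^2 + (ab[1] * sin(phi))^2)
    sum((r_obs - r_mod)^2)
  }, method = "Nelder-Mead")
  ellipse(ell$cx, ell$cy, fit$par[1], fit$par[2], ell$theta)
}

#' Built-in threshold/watershed segmenter for synthetic fields
#'
#' Foreground threshold from a robust background model (field median plus
#' `k_bg` scaled MADs -- fluorescence fields are background-dominated, which
#' defeats histogram-split thresholds), hole filling, a small opening to
#' drop noise specks, distance-transform watershed to split touching cells,
#' then per-cell refinement of the ellipse boundary to the membrane-ring
#' intensity ridge (when one is prominent), so that mask edges intersect the
#' ring in its middle. Intended for simulated data in place of an external
#' Cellpose mask; deterministic.
#'
#' @param m a [micrograph()]
#' @param channel channel name or index to segment on
#' @param min_size minimum object size in pixels
#' @param k_bg MAD multiplier of the background threshold
#' @return integer label mask
#' @export
segment_builtin <- function(m, channel = 1L, min_size = 200L, k_bg = 5) {
  img <- m$channels[[channel]]
  rng <- range(img)
  if (diff(rng) <= 0) stop("unusable contrast: image is constant")
  # mad = 0 means the majority of pixels sit exactly at the background
  # level (noise-free render): anything above the median is then signal
  med <- median(img); s <- mad(img)
  th <- med + k_bg * s
  bw <- img > th
  if (!any(bw)) stop("unusable contrast: threshold removes everything")
  bw <- EBImage::fillHull(bw * 1)
  bw <- EBImage::opening(bw, EBImage::makeBrush(5, "disc"))
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  labs <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labs <- as.matrix(EBImage::imageData(labs))
  storage.mode(labs) <- "integer"

  # drop specks, then snap each object's boundary to the ring ridge
  out <- matrix(0L, nrow(labs), ncol(labs))
  next_lab <- 0L
  for (lab in sort(unique(labs[labs > 0L]))) {
    idx <- which(labs == lab, arr.ind = TRUE)
    if (nrow(idx) < min_size) next
    next_lab <- next_lab + 1L
    xy <- cbind(idx[, 2] - 1, idx[, 1] - 1)
    ell0 <- moment_ellipse(xy)
    ell1 <- refine_to_ridge(img, ell0)
    if (is.null(ell1)) {
      # no ring: re-threshold locally at half-max between background and
      # interior so the boundary sits on the true (blurred) cell edge
      interior <- img[labs == lab]
      th2 <- (median(img[labs == 0L]) + median(interior)) / 2
      keep <- labs == lab & img >= th2
      out[keep] <- next_lab
    } else {
      region <- rasterize_ellipse(ell1, dim(img))
      out[region & (labs == lab | labs == 0L) & out == 0L] <- next_lab
    }
  }
  if (next_lab == 0L) stop("unusable contrast: no object of min_size found")
  cq_log("segment_builtin: %d cell(s)", next_lab)
  out
}
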