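# Synthetic transversal-section micrographs with per-cell ground truth.
#
# A simulated cell is an ellipse (the mid-plane cross-section) carrying three
# signal pools that split one configured per-cell total:
#   membrane_fraction  -> a Gaussian-profile ring on the contour, part of it
#                         concentrated into discrete cortical punctae
#                         (eisosomes / eisosome remnants),
#   foci_fraction      -> bright cytosolic foci (P-body-like),
#   remainder          -> a uniform cytosolic pool over the whole section.
# The field is blurred with a Gaussian PSF, then Poisson shot noise acts on
# the blurred photon flux and Gaussian read noise is added (blur -> Poisson
# -> Gaussian, in that order). Two expected PM/cytosol ratios are recorded
# per cell: a geometric one measured on the placed (unblurred, background-
# free) signal and a blur-aware one measured on the noise-free blurred image
# including background -- the latter is what a perfect pipeline would
# recover, PSF bias included.

#' Configuration for the synthetic-micrograph generator
#'
#' Defaults emulate post-diauxic yeast imaged as a single transversal
#' confocal section with a 100x/1.46 NA objective: 0.08 um pixels, cells
#' 4--6 um across, a diffraction-limited membrane ring (0.25 um full width)
#' carrying discrete cortical punctae.
#'
#' @param field_shape image size in pixels `(rows, cols)`
#' @param pixel_size micrometres per pixel
#' @param n_cells number of cells placed fully inside the field
#' @param n_edge_cells additional cells deliberately clipped by the field
#'   border (for edge-filter testing); flagged in the truth table
#' @param cell_semiaxis_range micrometres, `(min, max)` for each ellipse
#'   semi-axis
#' @param cell_total_intensity total signal (intensity units) per cell and
#'   channel, before noise
#' @param membrane_fraction fraction of a cell's signal placed in the
#'   membrane ring (punctae included), in `[0, 1]`
#' @param puncta_per_cell number of cortical punctae on the ring
#' @param puncta_sigma punctum Gaussian sigma, micrometres
#' @param puncta_enrichment fraction of the membrane signal concentrated in
#'   punctae (the rest is a uniform-density ring), in `[0, 1]`
#' @param min_arc_sep minimum arc separation between punctae, micrometres;
#'   default `2 * puncta_sigma` (violating draws are redrawn)
#' @param n_foci cytosolic foci per cell
#' @param foci_fraction fraction of the cell signal in foci, in `[0, 1]`
#' @param foci_sigma focus Gaussian sigma, micrometres
#' @param ring_fwhm full width of the membrane-ring Gaussian profile,
#'   micrometres
#' @param background_level constant background intensity added everywhere
#' @param psf_sigma Gaussian PSF sigma, micrometres (0 disables blur)
#' @param photon_gain photons per intensity unit (Poisson noise scale)
#' @param read_noise_sd Gaussian read noise standard deviation, intensity
#'   units
#' @param noise logical; apply the Poisson + Gaussian noise stage
#' @param channel2_mode `"absent"`, `"colocalized"` (channel-2 punctae share
#'   channel-1 arc positions up to `colocalization_jitter`) or
#'   `"independent"` (fresh positions)
#' @param colocalization_jitter arc-position jitter of colocalized channel-2
#'   punctae, micrometres
#' @param cell_gap minimum clearance between placed cell outlines,
#'   micrometres (keeps membrane bands of neighbours disjoint)
#' @param band_halfwidth membrane-band half-width (micrometres) used when
#'   computing the truth ratios; matches the quantification default
#' @param max_place_attempts rejection-sampling budget for cell placement
#' @param seed integer seed; a fixed config + seed reproduces the field
#'   bit-identically
#' @return validated list of class `simulation_config`
#' @export
simulation_config <- function(field_shape = c(1024L, 1024L),
                              pixel_size = 0.08,
                              n_cells = 12L,
                              n_edge_cells = 0L,
                              cell_semiaxis_range = c(2.0, 3.0),
                              cell_total_intensity = 3e5,
                              membrane_fraction = 0.6,
                              puncta_per_cell = 6L,
                              puncta_sigma = 0.1,
                              puncta_enrichment = 0.5,
                              min_arc_sep = NULL,
                              n_foci = 0L,
                              foci_fraction = 0,
                              foci_sigma = 0.25,
                              ring_fwhm = 0.25,
                              background_level = 10,
                              psf_sigma = 0.1,
                              photon_gain = 1,
                              read_noise_sd = 2,
                              noise = TRUE,
                              channel2_mode = c("absent", "colocalized",
                                                "independent"),
                              colocalization_jitter = 0.1,
                              cell_gap = 0.6,
                              band_halfwidth = 0.25,
                              max_place_attempts = 20000L,
                              seed = 1L) {
  channel2_mode <- match.arg(channel2_mode)
  cfg <- list(field_shape = as.integer(field_shape), pixel_size = pixel_size,
              n_cells = as.integer(n_cells),
              n_edge_cells = as.integer(n_edge_cells),
              cell_semiaxis_range = cell_semiaxis_range,
              cell_total_intensity = cell_total_intensity,
              membrane_fraction = membrane_fraction,
              puncta_per_cell = as.integer(puncta_per_cell),
              puncta_sigma = puncta_sigma,
              puncta_enrichment = puncta_enrichment,
              min_arc_sep = min_arc_sep %||% (2 * puncta_sigma),
              n_foci = as.integer(n_foci), foci_fraction = foci_fraction,
              foci_sigma = foci_sigma, ring_fwhm = ring_fwhm,
              background_level = background_level, psf_sigma = psf_sigma,
              photon_gain = photon_gain, read_noise_sd = read_noise_sd,
              noise = isTRUE(noise), channel2_mode = channel2_mode,
              colocalization_jitter = colocalization_jitter,
              cell_gap = cell_gap, band_halfwidth = band_halfwidth,
              max_place_attempts = as.integer(max_place_attempts),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (length(field_shape) != 2 || any(field_shape <= 0))
      stop("field_shape must be two positive integers")
    if (pixel_size <= 0) stop("pixel_size must be positive")
    if (n_cells < 0 || n_edge_cells < 0 || puncta_per_cell < 0 || n_foci < 0)
      stop("counts must be non-negative")
    if (length(cell_semiaxis_range) != 2 || any(cell_semiaxis_range <= 0) ||
        diff(cell_semiaxis_range) < 0)
      stop("cell_semiaxis_range must be positive (min, max)")
    if (membrane_fraction < 0 || membrane_fraction > 1 ||
        foci_fraction < 0 || foci_fraction > 1)
      stop("fractions must lie in [0, 1]")
    if (membrane_fraction + foci_fraction > 1)
      stop("membrane_fraction + foci_fraction must not exceed 1")
    if (puncta_enrichment < 0 || puncta_enrichment > 1)
      stop("puncta_enrichment must lie in [0, 1]")
    if (any(c(puncta_sigma, foci_sigma, ring_fwhm, band_halfwidth,
              cell_gap) <= 0))
      stop("length parameters must be positive")
    if (psf_sigma < 0 || read_noise_sd < 0 || background_level < 0 ||
        photon_gain <= 0)
      stop("noise/background parameters out of range")
    a_max_px <- cell_semiaxis_range[2] / pixel_size
    if (2 * a_max_px + 4 >= min(field_shape))
      stop("field too small to hold one cell of maximum size")
  })
  invisible(cfg)
}

# --- cell placement ---------------------------------------------------------

# Rejection-sample non-overlapping ellipses; clearance is checked on the
# bounding circles (semi-major axes), which is conservative. Edge cells are
# centred so the ellipse crosses a randomly chosen border.
place_cells <- function(cfg) {
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  ax_px <- cfg$cell_semiaxis_range / cfg$pixel_size
  gap_px <- cfg$cell_gap / cfg$pixel_size
  n_total <- cfg$n_cells + cfg$n_edge_cells
  cells <- vector("list", n_total)
  placed <- 0L; attempts <- 0L
  while (placed < n_total) {
    attempts <- attempts + 1L
    if (attempts > cfg$max_place_attempts)
      stop("cell placement failed: configuration too dense for the field")
    ab <- sort(runif(2, ax_px[1], ax_px[2]), decreasing = TRUE)
    th <- runif(1, 0, pi)
    edge <- placed >= cfg$n_cells
    if (!edge) {
      m <- ab[1] + 2
      if (nc - 1 - 2 * m <= 0 || nr - 1 - 2 * m <= 0)
        stop("field too small for interior placement")
      cx <- runif(1, m, nc - 1 - m); cy <- runif(1, m, nr - 1 - m)
    } else {
      side <- sample(4, 1)
      off <- runif(1, -0.5, 0.5) * ab[2]  # centre near the border
      cx <- switch(side, off, nc - 1 - off, runif(1, ab[1], nc - 1 - ab[1]),
                   runif(1, ab[1], nc - 1 - ab[1]))
      cy <- switch(side, runif(1, ab[1], nr - 1 - ab[1]),
                   runif(1, ab[1], nr - 1 - ab[1]), off, nr - 1 - off)
    }
    ok <- TRUE
    for (c2 in cells[seq_len(placed)]) {
      d <- sqrt((cx - c2$ell$cx)^2 + (cy - c2$ell$cy)^2)
      if (d < ab[1] + c2$ell$a + gap_px) { ok <- FALSE; break }
    }
    if (!ok) next
    placed <- placed + 1L
    cells[[placed]] <- list(label = placed,
                            ell = ellipse(cx, cy, ab[1], ab[2], th),
                            edge_clipped = edge)
  }
  cells
}

# --- per-cell signal rendering ----------------------------------------------

# Draw puncta arc positions (micrometres) uniformly on the contour with a
# minimum circular separation; violating draws are redrawn as a set.
draw_puncta_arcs <- function(n, perimeter_um, min_sep_um, max_tries = 200L) {
  if (n == 0L) return(numeric(0))
  if (n * min_sep_um >= perimeter_um)
    stop("puncta do not fit on the contour at the requested separation")
  for (i in seq_len(max_tries)) {
    s <- sort(runif(n, 0, perimeter_um))
    gaps <- c(diff(s), perimeter_um - s[n] + s[1])
    if (n == 1L || all(gaps >= min_sep_um)) return(s)
  }
  s  # give up on separation after the redraw budget; still valid positions
}

# Render 2D Gaussians (sum of `totals`) centred at 0-based points onto the
# field, each truncated at 4 sigma and normalised so its rendered sum equals
# its total exactly.
render_gaussians <- function(field, pts, sigma_px, totals) {
  nr <- nrow(field); nc <- ncol(field)
  r <- ceiling(4 * sigma_px)
  for (k in seq_len(nrow(pts))) {
    x0 <- pts[k, 1]; y0 <- pts[k, 2]
    i0 <- max(1L, floor(y0 - r) + 1L); i1 <- min(nr, ceiling(y0 + r) + 1L)
    j0 <- max(1L, floor(x0 - r) + 1L); j1 <- min(nc, ceiling(x0 + r) + 1L)
    if (i0 > i1 || j0 > j1) next
    yy <- (i0:i1) - 1; xx <- (j0:j1) - 1
    w <- exp(-(outer((yy - y0)^2, (xx - x0)^2, "+")) / (2 * sigma_px^2))
    w[w < exp(-8)] <- 0  # truncate at 4 sigma
    sw <- sum(w)
    if (sw > 0)
      field[i0:i1, j0:j1] <- field[i0:i1, j0:j1] + w * (totals[k] / sw)
  }
  field
}

# Render one cell's signal for one channel into `field`; returns the field
# plus the punctum arc positions used.
render_cell_channel <- function(field, cell, cellmask_win, win, cfg,
                                arcs_um = NULL, arc_tab = NULL) {
  T_total <- cfg$cell_total_intensity
  m <- cfg$membrane_fraction; f <- cfg$foci_fraction
  T_ring <- T_total * m * (1 - cfg$puncta_enrichment)
  T_punc <- T_total * m * cfg$puncta_enrichment
  T_foci <- T_total * f
  T_cyto <- T_total * (1 - m - f)
  i0 <- win[1]; i1 <- win[2]; j0 <- win[3]; j1 <- win[4]
  sub <- field[i0:i1, j0:j1]

  npix <- sum(cellmask_win)
  if (npix == 0) return(list(field = field, arcs = numeric(0)))

  # uniform cytosolic pool over the whole section
  if (T_cyto > 0) sub[cellmask_win] <- sub[cellmask_win] + T_cyto / npix

  # Gaussian-profile ring on the (rasterised) contour: signed distance from
  # the mask boundary via two distance transforms, boundary at 0.
  sig_r <- (cfg$ring_fwhm / 2.3548) / cfg$pixel_size
  if (T_ring > 0) {
    din <- as.matrix(EBImage::distmap(cellmask_win * 1))
    dout <- as.matrix(EBImage::distmap(1 - cellmask_win))
    d <- ifelse(cellmask_win, din - 0.5, -(dout - 0.5))
    w <- exp(-d^2 / (2 * sig_r^2))
    w[abs(d) > 4 * sig_r] <- 0
    sw <- sum(w)
    if (sw > 0) sub <- sub + w * (T_ring / sw)
  }
  field[i0:i1, j0:j1] <- sub

  # cortical punctae at arc positions on the true contour
  arcs <- numeric(0)
  if (cfg$puncta_per_cell > 0 && T_punc > 0) {
    arc_tab <- arc_tab %||% ellipse_arc_table(cell$ell)
    per_px <- ellipse_perimeter(cell$ell, arc_tab)
    per_um <- per_px * cfg$pixel_size
    arcs <- arcs_um %||% draw_puncta_arcs(cfg$puncta_per_cell, per_um,
                                          cfg$min_arc_sep)
    tt <- ellipse_arc_to_t(cell$ell, arcs / cfg$pixel_size, arc_tab)
    pts <- ellipse_point(cell$ell, tt)
    field <- render_gaussians(field, pts, cfg$puncta_sigma / cfg$pixel_size,
                              rep(T_punc / length(arcs), length(arcs)))
  }

  # cytosolic foci, kept in the deep interior
  if (cfg$n_foci > 0 && T_foci > 0) {
    shrink <- 0.55
    tf <- runif(cfg$n_foci, 0, 2 * pi)
    rf <- shrink * sqrt(runif(cfg$n_foci))
    co <- cos(cell$ell$theta); so <- sin(cell$ell$theta)
    u <- cell$ell$a * rf * cos(tf); v <- cell$ell$b * rf * sin(tf)
    pts <- cbind(cell$ell$cx + u * co - v * so,
                 cell$ell$cy + u * so + v * co)
    field <- render_gaussians(field, pts, cfg$foci_sigma / cfg$pixel_size,
                              rep(T_foci / cfg$n_foci, cfg$n_foci))
  }
  list(field = field, arcs = arcs)
}

# --- field simulation -------------------------------------------------------

#' Simulate one synthetic micrograph field with ground truth
#'
#' Places non-overlapping elliptical cells, renders membrane ring, cortical
#' punctae, cytosolic pool and optional foci per cell, blurs with the PSF and
#' applies Poisson-then-Gaussian noise. Deterministic for a fixed config
#' (the config seed is set on entry).
#'
#' @param cfg a [simulation_config()]
#' @param field_id identifier recorded in outputs
#' @param keep_images keep the noise-free clean and blurred channel images in
#'   the truth object (memory-heavy; used by tests)
#' @return list with elements `micrograph` (a [micrograph()], integer-valued
#'   pixels), `mask` (integer label matrix, 0 background), and `truth`: a
#'   list with `cells` (one row per cell: label, ellipse, pixel count,
#'   `edge_clipped`, `degenerate`, the configured fractions and the two
#'   expected PM/cytosol ratios `ratio_geometric` / `ratio_blur_aware`),
#'   `puncta` (cell, channel, arc position in micrometres) and `config`.
#' @export
simulate_field <- function(cfg, field_id = "field1", keep_images = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  cells <- place_cells(cfg)
  mask <- matrix(0L, nr, nc)
  for (cell in cells) {
    inside <- rasterize_ellipse(cell$ell, c(nr, nc))
    mask[inside & mask == 0L] <- cell$label
  }

  two_ch <- cfg$channel2_mode != "absent"
  clean1 <- matrix(0, nr, nc)
  clean2 <- if (two_ch) matrix(0, nr, nc) else NULL
  pad <- ceiling(4 * max(cfg$ring_fwhm / 2.3548, cfg$puncta_sigma,
                         cfg$foci_sigma) / cfg$pixel_size) + 2L

  puncta_rows <- list()
  for (cell in cells) {
    idx <- which(mask == cell$label, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    i0 <- max(1L, min(idx[, 1]) - pad); i1 <- min(nr, max(idx[, 1]) + pad)
    j0 <- max(1L, min(idx[, 2]) - pad); j1 <- min(nc, max(idx[, 2]) + pad)
    win <- c(i0, i1, j0, j1)
    cellmask_win <- mask[i0:i1, j0:j1] == cell$label
    arc_tab <- ellipse_arc_table(cell$ell)
    r1 <- render_cell_channel(clean1, cell, cellmask_win, win, cfg,
                              arc_tab = arc_tab)
    clean1 <- r1$field
    if (length(r1$arcs))
      puncta_rows[[length(puncta_rows) + 1L]] <-
        data.frame(cell_label = cell$label, channel = 1L, arc_um = r1$arcs)
    if (two_ch) {
      per_um <- ellipse_perimeter(cell$ell, arc_tab) * cfg$pixel_size
      arcs2 <- if (cfg$channel2_mode == "colocalized") {
        if (length(r1$arcs)) {
          (r1$arcs + rnorm(length(r1$arcs), 0, cfg$colocalization_jitter)) %%
            per_um
        } else numeric(0)
      } else NULL  # independent: drawn fresh inside render_cell_channel
      r2 <- render_cell_channel(clean2, cell, cellmask_win, win, cfg,
                                arcs_um = arcs2, arc_tab = arc_tab)
      clean2 <- r2$field
      if (length(r2$arcs))
        puncta_rows[[length(puncta_rows) + 1L]] <-
          data.frame(cell_label = cell$label, channel = 2L, arc_um = r2$arcs)
    }
  }

  psf_px <- cfg$psf_sigma / cfg$pixel_size
  blur <- function(img) {
    if (psf_px > 0) as.matrix(EBImage::gblur(img, sigma = psf_px)) else img
  }
  blurred1 <- blur(clean1) + cfg$background_level
  blurred2 <- if (two_ch) blur(clean2) + cfg$background_level else NULL

  noisify <- function(img) {
    if (!cfg$noise) return(pmax(round(img), 0))
    lam <- pmax(img, 0) * cfg$photon_gain
    shot <- rpois(length(lam), lam) / cfg$photon_gain
    out <- shot + rnorm(length(lam), 0, cfg$read_noise_sd)
    matrix(pmax(round(out), 0), nrow(img), ncol(img))
  }
  ch <- list(GFP = noisify(blurred1))
  if (two_ch) ch$mRFP <- noisify(blurred2)
  mg <- micrograph(ch, pixel_size = cfg$pixel_size, source_path = "simulated")

  # truth ratios per cell, measured with the pipeline's band geometry
  band_px <- cfg$band_halfwidth / cfg$pixel_size
  rows <- lapply(cells, function(cell) {
    comp <- compartment_indices(mask, cell$label, band_px)
    geo <- blur_aware <- NA_real_
    degen <- comp$degenerate
    if (!degen) {
      # geometric truth: density contrast of the placed signal itself, so
      # only intra-mask band pixels count (outside the cell there is no
      # placed signal); blur-aware truth uses the full measurement geometry
      # (symmetric band, background included) -- what a perfect pipeline
      # reading the blurred image would report
      geo <- ratio_value(mean(clean1[comp$membrane_in_mask]),
                         mean(clean1[comp$interior]))
      blur_aware <- ratio_value(mean(blurred1[comp$membrane]),
                                mean(blurred1[comp$interior]))
    }
    data.frame(field_id = field_id, cell_label = cell$label,
               cx = cell$ell$cx, cy = cell$ell$cy, a = cell$ell$a,
               b = cell$ell$b, theta = cell$ell$theta,
               pixel_count = sum(mask == cell$label),
               edge_clipped = cell$edge_clipped, degenerate = degen,
               membrane_fraction = cfg$membrane_fraction,
               foci_fraction = cfg$foci_fraction,
               ratio_geometric = geo, ratio_blur_aware = blur_aware)
  })
  truth <- list(cells = do.call(rbind, rows),
                puncta = if (length(puncta_rows)) do.call(rbind, puncta_rows)
                         else data.frame(cell_label = integer(0),
                                         channel = integer(0),
                                         arc_um = numeric(0)),
                config = cfg)
  if (keep_images) {
    truth$clean <- list(GFP = clean1)
    truth$blurred <- list(GFP = blurred1)
    if (two_ch) { truth$clean$mRFP <- clean2; truth$blurred$mRFP <- blurred2 }
  }
  list(micrograph = mg, mask = mask, truth = truth, field_id = field_id)
}

#' Write a simulated field to disk
#'
#' Writes the multi-channel image TIFF, the label-mask TIFF, the truth CSV
#' and a config echo (YAML) carrying the pixel size and every generator
#' parameter.
#'
#' @param sim result of [simulate_field()]
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths
#' @export
write_field <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sim$field_id
  paths <- c(image = file.path(dir, paste0(id, "_image.tif")),
             mask = file.path(dir, paste0(id, "_mask.tif")),
             truth = file.path(dir, paste0(id, "_truth.csv")),
             config = file.path(dir, paste0(id, "_config.yaml")))
  write_micrograph(sim$micrograph, paths["image"])
  write_label_mask(sim$mask, paths["mask"])
  write_truth(sim$truth, paths["truth"])
  yaml::write_yaml(unclass(sim$truth$config), paths["config"])
  paths
}
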