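# Shared fixtures: a downsized simulation config for fast unit tests, and
# binary-shape builders used by the geometry-level tests.

# Small field, few mid-sized cells: keeps per-test runtime low while
# preserving the default optics (pixel size, ring width, PSF, noise).
small_config <- function(...) {
  args <- modifyList(list(field_shape = c(512L, 512L), n_cells = 5L,
                          seed = 11L), list(...))
  do.call(simulation_config, args)
}

# Rasterized disc mask (single label) at 0-based center (cx, cy).
disc_mask <- function(shape, cx, cy, r, label = 1L) {
  m <- matrix(0L, shape[1], shape[2])
  d2 <- outer(((seq_len(shape[1]) - 1) - cy)^2,
              ((seq_len(shape[2]) - 1) - cx)^2, "+")
  m[d2 <= r^2] <- label
  m
}

# Rasterized axis-aligned ellipse mask.
ellipse_mask <- function(shape, cx, cy, a, b, label = 1L) {
  m <- matrix(0L, shape[1], shape[2])
  u2 <- outer(rep(1, shape[1]), ((seq_len(shape[2]) - 1) - cx)^2 / a^2)
  v2 <- outer(((seq_len(shape[1]) - 1) - cy)^2 / b^2, rep(1, shape[2]))
  m[u2 + v2 <= 1] <- label
  m
}

uniform_micrograph <- function(mask, value = 100, pixel_size = 0.08) {
  micrograph(list(GFP = matrix(value, nrow(mask), ncol(mask))),
             pixel_size = pixel_size)
}

# Per-cell best IoU of a segmentation against a truth mask.
best_iou <- function(truth_mask, seg_mask, label) {
  tm <- truth_mask == label
  labs <- setdiff(unique(seg_mask[tm]), 0L)
  if (length(labs) == 0) return(0)
  max(vapply(labs, function(sl) {
    sm <- seg_mask == sl
    sum(tm & sm) / sum(tm | sm)
  }, numeric(1)))
}
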