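# ROI extraction and curation: moment ellipses, edge and dead-cell filters,
# and the built-in threshold/watershed segmenter.

test_that("moment ellipses recover rasterized disc and ellipse parameters", {
  m <- disc_mask(c(80, 80), 40, 40, 25)
  roi <- mask_to_rois(m)[[1]]
  expect_lt(abs(roi$ellipse$a - 25) / 25, 0.02)
  expect_lt(abs(roi$ellipse$b - 25) / 25, 0.02)
  expect_true(roi$degenerate_orientation)

  m2 <- ellipse_mask(c(120, 120), 60, 60, a = 40, b = 20)
  roi2 <- mask_to_rois(m2)[[1]]
  expect_lt(abs(roi2$ellipse$a - 40) / 40, 0.02)
  expect_lt(abs(roi2$ellipse$b - 20) / 20, 0.02)
  th <- min(roi2$ellipse$theta, pi - roi2$ellipse$theta)
  expect_lt(th, 2 * pi / 180)
  expect_false(roi2$degenerate_orientation)
})

test_that("a rotated rasterized ellipse is recovered with its orientation", {
  ell <- ellipse(60, 60, 35, 18, pi / 6)
  m <- matrix(0L, 120, 120)
  m[cortiquant:::rasterize_ellipse(ell, c(120, 120))] <- 1L
  roi <- mask_to_rois(m)[[1]]
  expect_lt(abs(roi$ellipse$a - 35) / 35, 0.02)
  expect_lt(abs(roi$ellipse$b - 18) / 18, 0.02)
  expect_lt(abs(roi$ellipse$theta - pi / 6), 2 * pi / 180)
})

test_that("labels are preserved, gaps allowed, and small labels dropped", {
  m <- disc_mask(c(100, 200), 45, 50, 20, label = 1L)
  m[disc_mask(c(100, 200), 145, 50, 20, label = 3L) == 3L] <- 3L
  m[2, 2] <- 5L  # one-pixel speck
  expect_warning(rois <- mask_to_rois(m), "label 5 dropped")
  expect_equal(vapply(rois, function(r) r$label, 0L), c(1L, 3L))
})

test_that("ellipse area pi*a*b agrees with the pixel count for convex masks", {
  for (r in c(18, 25, 32)) {
    m <- disc_mask(c(90, 90), 44, 44, r)
    roi <- mask_to_rois(m)[[1]]
    expect_lt(abs(pi * roi$ellipse$a * roi$ellipse$b - roi$pixel_count) /
                roi$pixel_count, 0.05)
  }
})

test_that("edge filter flags exactly the deliberately clipped cells", {
  cfg <- small_config(n_cells = 5L, n_edge_cells = 2L, seed = 9L)
  sim <- simulate_field(cfg)
  rois <- filter_edge_cells(mask_to_rois(sim$mask), dim(sim$mask))
  flagged <- vapply(rois, function(r) r$flags$edge_touching, logical(1))
  labs <- vapply(rois, function(r) r$label, 0L)
  truth_clipped <- sim$truth$cells$cell_label[sim$truth$cells$edge_clipped]
  expect_setequal(labs[flagged], truth_clipped)
})

test_that("a cell exactly tangent to the border margin is flagged (inclusive)", {
  m <- disc_mask(c(80, 80), 40, 19, 19)  # topmost pixel exactly on row 0
  rois <- filter_edge_cells(mask_to_rois(m), c(80, 80))
  expect_true(rois[[1]]$flags$edge_touching)
  m2 <- disc_mask(c(80, 80), 40, 40, 19)  # fully interior
  rois2 <- filter_edge_cells(mask_to_rois(m2), c(80, 80))
  expect_false(rois2[[1]]$flags$edge_touching)
})

test_that("MAD-outlier rule flags exactly an injected 10x-bright cell", {
  cfg <- small_config(n_cells = 5L, seed = 21L)
  sim <- simulate_field(cfg)
  img <- sim$micrograph$channels$GFP
  img[sim$mask == 2L] <- img[sim$mask == 2L] * 10
  mg <- micrograph(list(GFP = img), cfg$pixel_size)
  rois <- filter_dead_cells(mask_to_rois(sim$mask), mg, sim$mask,
                            criterion = "intensity-outlier", k = 5)
  dead <- vapply(rois, function(r) r$flags$excluded_dead, logical(1))
  expect_equal(vapply(rois, function(r) r$label, 0L)[dead], 2L)
  # cross-check by direct MAD computation
  means <- vapply(seq_len(5), function(l) mean(img[sim$mask == l]), 0)
  expect_true(abs(means[2] - median(means)) > 5 * mad(means))
})

test_that("exclusion lists flag the named cell; unknown labels warn", {
  m <- disc_mask(c(100, 200), 45, 50, 20, 1L)
  m[disc_mask(c(100, 200), 145, 50, 20, 7L) == 7L] <- 7L
  mg <- uniform_micrograph(m)
  ex <- data.frame(field_id = "field1", cell_label = 7L)
  rois <- filter_dead_cells(mask_to_rois(m), mg, m, exclusion_list = ex,
                            field_id = "field1")
  expect_false(rois[[1]]$flags$excluded_manual)
  expect_true(rois[[2]]$flags$excluded_manual)
  ex2 <- data.frame(field_id = "field1", cell_label = 99L)
  expect_warning(filter_dead_cells(mask_to_rois(m), mg, m,
                                   exclusion_list = ex2,
                                   field_id = "field1"), "absent label")
  # empty list under list-only criterion is the identity
  rois3 <- filter_dead_cells(mask_to_rois(m), mg, m)
  expect_true(all(!vapply(rois3, function(r) r$flags$excluded_manual,
                          logical(1))))
})

test_that("curation filters are idempotent and order-independent", {
  cfg <- small_config(n_cells = 4L, n_edge_cells = 1L, seed = 13L)
  sim <- simulate_field(cfg)
  rois0 <- mask_to_rois(sim$mask)
  f_edge <- function(r) filter_edge_cells(r, dim(sim$mask))
  f_dead <- function(r) filter_dead_cells(r, sim$micrograph, sim$mask,
                                          criterion = "intensity-outlier")
  once <- f_dead(f_edge(rois0))
  twice <- f_dead(f_edge(f_dead(f_edge(rois0))))
  swapped <- f_edge(f_dead(rois0))
  flags <- function(rs) lapply(rs, function(r) r$flags)
  expect_identical(flags(once), flags(twice))
  expect_identical(flags(once), flags(swapped))
  expect_true(all(!vapply(retained_rois(once),
                          function(r) r$flags$edge_touching, logical(1))))
})

test_that("builtin segmenter matches the truth mask on noise-free fields", {
  cfg <- small_config(n_cells = 4L, seed = 3L, noise = FALSE)
  sim <- simulate_field(cfg)
  seg <- segment_builtin(sim$micrograph)
  for (lab in sim$truth$cells$cell_label)
    expect_gte(best_iou(sim$mask, seg, lab), 0.95)
})

test_that("builtin segmenter splits touching cells and rejects blank images", {
  m <- matrix(0, 100, 100)
  m[disc_mask(c(100, 100), 34, 50, 16) == 1L] <- 100
  m[disc_mask(c(100, 100), 65, 50, 16) == 1L] <- 100
  seg <- segment_builtin(micrograph(list(GFP = m), 0.08))
  expect_equal(length(setdiff(unique(as.vector(seg)), 0L)), 2L)
  expect_error(segment_builtin(uniform_micrograph(matrix(0L, 50, 50), 5)),
               "unusable contrast")
})
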