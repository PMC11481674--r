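# Membrane-contour profiles: normalization contracts, correlation and its
# permutation null, circular peak detection and puncta overlap.

sim_coloc <- function(jitter, seed = 3L, n_cells = 3L, mode = "colocalized") {
  simulate_field(small_config(n_cells = n_cells, seed = seed,
                              channel2_mode = mode,
                              colocalization_jitter = jitter))
}

first_retained <- function(sim) {
  retained_rois(filter_edge_cells(mask_to_rois(sim$mask), dim(sim$mask)))[[1]]
}

test_that("min-max normalization follows its affine contract", {
  p <- structure(list(n_samples = 3L, arc_um = c(0, 1, 2), perimeter_um = 3,
                      intensity = matrix(c(2, 4, 6), 3, 1,
                                         dimnames = list(NULL, "GFP")),
                      normalized = NULL, constant = c(GFP = FALSE)),
                 class = "membrane_profile")
  n1 <- normalize_profile(p)
  expect_equal(unname(n1$normalized[, 1]), c(0, 0.5, 1))
  # idempotent on an already-[0,1] profile
  p2 <- p; p2$intensity <- n1$normalized
  expect_equal(normalize_profile(p2)$normalized, n1$normalized)
  # constant channel -> 0.5 with flag
  p3 <- p; p3$intensity[] <- 5
  p3$constant <- c(GFP = TRUE)
  expect_equal(unname(normalize_profile(p3)$normalized[, 1]), rep(0.5, 3))
})

test_that("a uniform image gives a constant-flagged profile", {
  mask <- disc_mask(c(96, 96), 48, 48, 30)
  mg <- uniform_micrograph(mask, value = 100)
  roi <- mask_to_rois(mask)[[1]]
  p <- extract_membrane_profile(mg, roi, n_samples = 90L)
  expect_true(p$constant[["GFP"]])
  expect_equal(diff(range(p$intensity)), 0)
  expect_identical(detect_cortical_puncta(normalize_profile(p)), numeric(0))
})

test_that("profile correlation is affinely invariant and bounded", {
  v <- sin(seq(0, 2 * pi, length.out = 72)) + rnorm(72, 0, 0.01)
  expect_equal(profile_correlation(v, 3 * v + 7)$r, 1.0, tolerance = 1e-12)
  expect_equal(profile_correlation(v, -v)$r, -1.0, tolerance = 1e-12)
  expect_true(profile_correlation(v, rev(v))$r >= -1)
  expect_true(isTRUE(profile_correlation(v, rep(1, 72))$undefined))
})

test_that("simulated punctae appear as profile peaks at the true arc positions", {
  sim <- simulate_field(small_config(n_cells = 3L, seed = 3L, noise = FALSE))
  rois <- retained_rois(filter_edge_cells(mask_to_rois(sim$mask),
                                          dim(sim$mask)))
  ps <- sim$micrograph$pixel_size
  for (roi in rois) {
    p <- normalize_profile(extract_membrane_profile(sim$micrograph, roi,
                                                    n_samples = 144L))
    peaks <- detect_cortical_puncta(p, "GFP")
    tr <- sim$truth$puncta
    truth <- sort(tr$arc_um[tr$cell_label == roi$label & tr$channel == 1])
    expect_length(peaks, length(truth))
    # compare in image space: the arc origin of a near-circular fitted
    # ellipse is arbitrary, but the peak locations are not
    tc <- sim$truth$cells[sim$truth$cells$cell_label == roi$label, ]
    true_ell <- ellipse(tc$cx, tc$cy, tc$a, tc$b, tc$theta)
    pk_xy <- ellipse_point(roi$ellipse,
                           ellipse_arc_to_t(roi$ellipse, peaks / ps))
    tr_xy <- ellipse_point(true_ell,
                           ellipse_arc_to_t(true_ell, truth / ps))
    tol_px <- 2 * (p$perimeter_um / ps) / p$n_samples  # two samples
    for (k in seq_len(nrow(tr_xy))) {
      d <- sqrt((pk_xy[, 1] - tr_xy[k, 1])^2 + (pk_xy[, 2] - tr_xy[k, 2])^2)
      expect_lt(min(d), tol_px)
    }
  }
})

test_that("rotating the field by 90 degrees circularly shifts the profile", {
  sim <- simulate_field(small_config(n_cells = 1L, seed = 17L, noise = FALSE))
  roi <- first_retained(sim)
  p0 <- extract_membrane_profile(sim$micrograph, roi, n_samples = 144L)
  img90 <- t(sim$micrograph$channels$GFP)[, nrow(sim$micrograph$channels$GFP):1]
  mask90 <- t(sim$mask)[, nrow(sim$mask):1]
  mg90 <- micrograph(list(GFP = img90), sim$micrograph$pixel_size)
  roi90 <- retained_rois(filter_edge_cells(mask_to_rois(mask90),
                                           dim(mask90)))[[1]]
  p90 <- extract_membrane_profile(mg90, roi90, n_samples = 144L)
  v0 <- p0$intensity[, 1]; v90 <- p90$intensity[, 1]
  align <- sapply(seq_along(v90) - 1L, function(k) {
    vs <- if (k == 0) v90 else c(v90[-seq_len(k)], v90[seq_len(k)])
    cor(v0, vs)
  })
  expect_gt(max(align), 0.95)
})

test_that("colocalized channels correlate; independent channels sit in the null", {
  sim <- sim_coloc(jitter = 0, seed = 3L)
  roi <- first_retained(sim)
  p <- extract_membrane_profile(sim$micrograph, roi)
  r <- profile_correlation(p, p, "GFP", "mRFP")$r
  expect_gte(r, 0.9)

  sim_i <- sim_coloc(jitter = 0, seed = 4L, mode = "independent")
  roi_i <- first_retained(sim_i)
  p_i <- extract_membrane_profile(sim_i$micrograph, roi_i)
  set.seed(1)
  nl <- profile_correlation_null(p_i$intensity[, "GFP"],
                                 p_i$intensity[, "mRFP"], n_perm = 500L)
  expect_lt(abs(nl$r), nl$null_q + 0.15)  # generous single-cell check
})

test_that("correlation and overlap are invariant to a shared circular shift", {
  sim <- sim_coloc(jitter = 0.05, seed = 8L)
  roi <- first_retained(sim)
  p <- normalize_profile(extract_membrane_profile(sim$micrograph, roi))
  v1 <- p$intensity[, "GFP"]; v2 <- p$intensity[, "mRFP"]
  k <- 31L
  sh <- function(v) c(v[-seq_len(k)], v[seq_len(k)])
  expect_equal(profile_correlation(sh(v1), sh(v2))$r,
               profile_correlation(v1, v2)$r, tolerance = 1e-12)
  pk1 <- detect_cortical_puncta(p, "GFP")
  pk2 <- detect_cortical_puncta(p, "mRFP")
  ov <- puncta_overlap(pk1, pk2, p$perimeter_um)
  shift_arc <- k * p$perimeter_um / p$n_samples
  ov_sh <- puncta_overlap((pk1 + shift_arc) %% p$perimeter_um,
                          (pk2 + shift_arc) %% p$perimeter_um,
                          p$perimeter_um)
  expect_equal(ov_sh$fraction, ov$fraction)
})

test_that("puncta overlap follows its matching contract", {
  per <- 15
  expect_equal(puncta_overlap(c(1, 5, 9), c(1, 5, 9), per)$fraction, 1)
  expect_equal(puncta_overlap(c(1, 5, 9), c(3, 7, 11), per,
                              tolerance_arc = 0.3)$fraction, 0)
  expect_true(puncta_overlap(numeric(0), c(1, 2), per)$undefined)
  # circular wrap: 14.9 and 0.1 are 0.2 apart on a 15-um contour
  expect_equal(puncta_overlap(14.9, 0.1, per, tolerance_arc = 0.3)$fraction, 1)
  # each channel-2 peak is used at most once
  expect_equal(puncta_overlap(c(1.0, 1.2), 1.1, per,
                              tolerance_arc = 0.3)$n_matched, 1L)
})

test_that("permutation p-values are uniform for independent channels", {
  # 200 small cells across 10 fields; KS against U(0,1) at a stochastic
  # tolerance. A miscalibrated null would concentrate p near 0 or 1.
  pvals <- c()
  for (seed in 301:310) {
    cfg <- simulation_config(field_shape = c(512L, 512L), n_cells = 20L,
                             cell_semiaxis_range = c(1.2, 1.6),
                             channel2_mode = "independent", seed = seed)
    sim <- simulate_field(cfg)
    rois <- retained_rois(filter_edge_cells(mask_to_rois(sim$mask),
                                            dim(sim$mask)))
    set.seed(seed)
    for (roi in rois) {
      p <- extract_membrane_profile(sim$micrograph, roi, n_samples = 96L)
      nl <- profile_correlation_null(p$intensity[, "GFP"],
                                     p$intensity[, "mRFP"], n_perm = 300L)
      pvals <- c(pvals, nl$p_value)
    }
  }
  expect_gte(length(pvals), 200L)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a single Gaussian bump yields exactly one peak at its center", {
  x <- seq_len(120)
  v <- 0.1 + exp(-(x - 60)^2 / (2 * 3^2))
  p <- structure(list(n_samples = 120L, arc_um = (x - 1) * 0.1,
                      perimeter_um = 12,
                      intensity = matrix(v, 120, 1,
                                         dimnames = list(NULL, "GFP")),
                      normalized = NULL, constant = c(GFP = FALSE)),
                 class = "membrane_profile")
  peaks <- detect_cortical_puncta(normalize_profile(p), "GFP")
  expect_length(peaks, 1L)
  expect_lt(abs(peaks - 5.9), 0.1 + 1e-9)  # within one sample of the center
})
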