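#!/usr/bin/env Rscript
# Stage 3: membrane-contour colocalization. Simulates two-channel fields in
# which the second channel (an eisosome marker, mRFP) either shares the
# reporter's cortical punctae or carries independent ones, then compares
# profile correlations and puncta overlap between the two situations.
# Writes results/coloc_summary.csv and one example profile trace.

library(cortiquant)
dir.create("results", showWarnings = FALSE)

analyse_mode <- function(mode, jitter, seeds) {
  rows <- list()
  for (s in seeds) {
    cfg <- simulation_config(n_cells = 12L, channel2_mode = mode,
                             colocalization_jitter = jitter, seed = s)
    sim <- simulate_field(cfg)
    rois <- retained_rois(filter_edge_cells(mask_to_rois(sim$mask),
                                            dim(sim$mask)))
    set.seed(s)
    for (roi in rois) {
      p <- normalize_profile(extract_membrane_profile(sim$micrograph, roi))
      nl <- profile_correlation_null(p$intensity[, "GFP"],
                                     p$intensity[, "mRFP"], n_perm = 500L)
      ov <- puncta_overlap(detect_cortical_puncta(p, "GFP"),
                           detect_cortical_puncta(p, "mRFP"),
                           p$perimeter_um)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, seed = s, cell = roi$label, r = nl$r,
        null_q95 = nl$null_q, perm_p = nl$p_value,
        overlap = ov$fraction)
    }
  }
  do.call(rbind, rows)
}

coloc <- analyse_mode("colocalized", jitter = 0.05, seeds = 501:502)
indep <- analyse_mode("independent", jitter = 0, seeds = 503:504)
out <- rbind(coloc, indep)
write.csv(out, "results/coloc_summary.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("colocalized: mean r = %.3f, mean overlap = %.2f (n = %d)\n",
            mean(coloc$r), mean(coloc$overlap, na.rm = TRUE), nrow(coloc)))
cat(sprintf("independent: mean |r| = %.3f, below null q95 in %.0f%% of cells (n = %d)\n",
            mean(abs(indep$r)), 100 * mean(abs(indep$r) < indep$null_q95),
            nrow(indep)))

# one example trace for plotting/inspection
cfg <- simulation_config(n_cells = 4L, channel2_mode = "colocalized",
                         colocalization_jitter = 0.05, seed = 505L)
sim <- simulate_field(cfg)
roi <- retained_rois(filter_edge_cells(mask_to_rois(sim$mask),
                                       dim(sim$mask)))[[1]]
p <- normalize_profile(extract_membrane_profile(sim$micrograph, roi))
write_profile(p, "results/example_profile.csv")
cat("example two-channel trace -> results/example_profile.csv\n")
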