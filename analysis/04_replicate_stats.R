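#!/usr/bin/env Rscript
# Stage 4: hierarchical statistics. Cells are averaged within biological
# replicates; replicate means enter Shapiro-Wilk / Levene assumption gates,
# one-way ANOVA and Tukey HSD. Writes replicate/condition summaries and the
# pairwise comparison table with significance stars.

library(cortiquant)

measurements <- read_measurements("results/measurements.csv")
gfp <- measurements[measurements$channel == "GFP", ]

repsum <- aggregate_replicates(gfp)
condsum <- condition_summary(repsum)
write.csv(repsum, "results/replicate_summary.csv", row.names = FALSE,
          quote = FALSE)
write.csv(condsum, "results/condition_summary.csv", row.names = FALSE,
          quote = FALSE)

cat("condition means over replicate means (PM/cytosol ratio):\n")
for (r in seq_len(nrow(condsum)))
  cat(sprintf("  %-12s %.3f +/- %.3f  (%d replicates, %d cells)\n",
              condsum$condition[r], condsum$mean[r], condsum$sd[r],
              condsum$n_replicates[r], condsum$n_cells[r]))

battery <- ratio_test_battery(repsum)
cat(sprintf("\nassumption gate %s (Levene p = %.3f)\n",
            if (battery$gate_passed) "passed" else "FAILED",
            battery$levene$p_value))
cat(sprintf("one-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
            battery$anova$df[1], battery$anova$df[2],
            battery$anova$statistic, battery$anova$p_value))
cat("Tukey HSD pairwise comparisons:\n")
print(battery$tukey$pairs, row.names = FALSE)
write.csv(battery$tukey$pairs, "results/stats_pairwise.csv",
          row.names = FALSE, quote = FALSE)
cat("\ntables -> results/replicate_summary.csv, condition_summary.csv, stats_pairwise.csv\n")
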