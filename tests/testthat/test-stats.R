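# Replicate aggregation and the test battery. Reference values for the
# Shapiro-Wilk, Levene and Tukey oracles were computed with an independent
# implementation (scipy 1.17 / statsmodels 0.14) and frozen here; the
# ANOVA fixture has an exact hand computation.

test_that("replicate aggregation averages cells, then replicates", {
  mk <- function(cond, rep, ratios) data.frame(
    field_id = "f", cell_label = seq_along(ratios), channel = "GFP",
    pm_cytosol_ratio = ratios, area_um2 = 10, degenerate = FALSE,
    condition = cond, replicate = rep)
  tbl <- rbind(mk("wt", "r1", c(1, 2, 3)),
               mk("wt", "r2", c(1, 1)), mk("wt", "r3", 3))
  rs <- aggregate_replicates(tbl)
  expect_equal(rs$mean_value[rs$replicate == "r1"], 2.0)
  cs <- condition_summary(rs)
  # hierarchy: mean over replicate means (2, 1, 3) -> 2, not the cell mean
  expect_equal(cs$mean, 2.0)
  expect_equal(cs$n_cells, 6L)
})

test_that("non-finite ratio sentinels are excluded from replicate means", {
  tbl <- data.frame(field_id = "f", cell_label = 1:10, channel = "GFP",
                    pm_cytosol_ratio = c(rep(2, 9), Inf), area_um2 = 10,
                    degenerate = FALSE, condition = "wt", replicate = "r1")
  rs <- aggregate_replicates(tbl)
  expect_equal(rs$n_cells, 9L)
  expect_equal(rs$n_excluded_nonfinite, 1L)
  expect_equal(rs$mean_value, 2)
})

test_that("Shapiro-Wilk matches the frozen reference values", {
  r <- shapiro_wilk(c(0.1, 0.5, 0.9, 1.3, 1.7))
  expect_lt(abs(r$statistic - 0.9867621552), 1e-3)
  expect_lt(abs(r$p_value - 0.9671739350), 2e-3)
  r2 <- shapiro_wilk(c(1.1, 2.0, 2.9, 3.5, 4.1, 5.2, 5.0, 6.3, 7.1, 2.2, 4.4))
  expect_lt(abs(r2$statistic - 0.9809738242), 1e-3)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n <= 50")
  expect_error(shapiro_wilk(rnorm(60)), "3 <= n <= 50")
})

test_that("Shapiro-Wilk accepts normal draws in at least 90% of seeds", {
  p <- vapply(1:100, function(s) {
    set.seed(s)
    shapiro_wilk(rnorm(30))$p_value
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.90)
})

test_that("Levene equals a hand-computed ANOVA on absolute deviations", {
  g <- list(c(1, 2, 3), c(10, 20, 30))
  r <- levene_test(g, center = "mean")
  # brute force: one-way ANOVA on |x - group mean|
  z <- lapply(g, function(x) abs(x - mean(x)))
  zb <- vapply(z, mean, 0); zg <- mean(unlist(z))
  ssb <- sum(lengths(z) * (zb - zg)^2)
  ssw <- sum(unlist(lapply(z, function(v) (v - mean(v))^2)))
  f_hand <- (ssb / 1) / (ssw / 4)
  expect_lt(abs(r$statistic - f_hand), 1e-6)
  expect_lt(abs(r$statistic - 3.2079207921), 1e-6)  # frozen reference
  expect_lt(abs(r$p_value - 0.1477669258), 1e-6)
  # identical groups -> no variance heterogeneity signal
  r0 <- levene_test(list(c(1, 2, 3), c(1, 2, 3)))
  expect_lt(r0$statistic, 1e-12)
  expect_equal(r0$p_value, 1)
  expect_error(levene_test(list(1, c(1, 2))), "at least 2 observations")
})

test_that("one-way ANOVA reproduces the hand-computed fixture", {
  r <- one_way_anova(list(c(1, 2), c(3, 4), c(5, 6)))
  # SSB = 16 (df 2), SSW = 1.5 (df 3) -> F = 8 / 0.5 = 16
  expect_equal(r$statistic, 16.0, tolerance = 1e-10)
  expect_equal(r$df, c(2, 3))
  expect_lt(abs(r$p_value - 0.0250945733), 1e-6)
  r0 <- one_way_anova(list(c(5, 5), c(5, 5)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(one_way_anova(list(c(1, 2))), "at least 2 groups")
})

test_that("ANOVA F is invariant under affine transforms of the data", {
  set.seed(42)
  g <- lapply(1:4, function(i) rnorm(5, mean = i))
  f0 <- one_way_anova(g)$statistic
  expect_equal(one_way_anova(lapply(g, function(x) x + 100))$statistic, f0,
               tolerance = 1e-9)
  expect_equal(one_way_anova(lapply(g, function(x) 3.5 * x))$statistic, f0,
               tolerance = 1e-9)
})

test_that("two-group Tukey reduces to the pooled-variance t-test", {
  set.seed(7)
  for (i in 1:50) {
    g <- list(rnorm(sample(3:8, 1)), rnorm(sample(3:8, 1), mean = runif(1)))
    tk <- tukey_hsd(g)$pairs$p_adj
    tt <- t.test(g[[1]], g[[2]], var.equal = TRUE)$p.value
    expect_lt(abs(tk - tt), 1e-6)
  }
})

test_that("three-group Tukey matches the frozen reference implementation", {
  g <- list(a = c(1.1, 2.0, 2.9), b = c(3.5, 4.1, 5.2), c = c(5.0, 6.3, 7.1))
  tk <- tukey_hsd(g)$pairs
  ref <- c("b-a" = 0.05867801, "c-a" = 0.00416317, "c-b" = 0.11299234)
  expect_setequal(tk$pair, names(ref))
  for (p in tk$pair)
    expect_lt(abs(tk$p_adj[tk$pair == p] - ref[[p]]), 1e-3)
  # identical groups -> all adjusted p = 1
  same <- tukey_hsd(list(c(1, 2), c(1, 2), c(1, 2)))$pairs
  expect_true(all(same$p_adj == 1))
})

test_that("significance stars use the inclusive legend thresholds", {
  expect_identical(significance_stars(c(0.0005, 0.01, 0.2, 5e-5, 0.05, 0.002)),
                   c("***", "**", "ns", "****", "*", "**"))
  expect_identical(significance_stars(1e-4), "****")
  expect_identical(significance_stars(1e-3), "***")
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
})

test_that("the battery reports the gate outcome and still runs the ANOVA", {
  set.seed(3)
  repsum <- data.frame(
    condition = rep(c("a", "b", "c"), each = 5),
    replicate = rep(paste0("r", 1:5), 3), n_cells = 30,
    mean_value = c(rnorm(5, 2), rnorm(5, 2.2), rnorm(5, 3)),
    sd_value = 0.5, mean_area = 12, n_excluded_nonfinite = 0)
  out <- ratio_test_battery(repsum)
  expect_length(out$shapiro, 3L)
  expect_s3_class(out$anova, "cq_test_report")
  expect_equal(nrow(out$tukey$pairs), 3L)
  expect_true(is.logical(out$gate_passed))
  # heteroscedastic data must fail the gate yet still yield an ANOVA report
  repsum$mean_value[repsum$condition == "c"] <- c(0, 2, 4, 6, 8)
  out2 <- ratio_test_battery(repsum)
  expect_false(out2$gate_passed)
  expect_true(length(out2$warnings) > 0)
  expect_s3_class(out2$anova, "cq_test_report")
})
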