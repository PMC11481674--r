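# Hierarchical replicate statistics. Cells are averaged within each
# biological replicate; replicate means (not cells) are the observations for
# the test battery -- Shapiro-Wilk normality, Levene variance homogeneity,
# one-way ANOVA and Tukey HSD -- which avoids pseudoreplication from
# hundreds of correlated cells per replicate.

new_test_report <- function(test, statistic, df, p_value, pairs = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, pairs = pairs),
            class = "cq_test_report")
}

#' @export
print.cq_test_report <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, df = (%s), p = %.4g\n", x$test,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  if (!is.null(x$pairs)) print(x$pairs)
  invisible(x)
}

#' Aggregate per-cell measurements into replicate summaries
#'
#' Computes the unweighted mean of `value_col` over retained, non-degenerate
#' cells within each (condition, replicate). Cells carrying a non-finite
#' ratio sentinel (infinite or undefined) are excluded and counted in the
#' log. Replicates with no usable cell are reported and dropped.
#'
#' @param measurements measurement data.frame with `condition` and
#'   `replicate` annotations (one channel's rows)
#' @param value_col measurement column to summarise
#' @return data.frame with one row per (condition, replicate): `n_cells`,
#'   `mean_value`, `sd_value`, `mean_area`, `n_excluded_nonfinite`
#' @export
aggregate_replicates <- function(measurements,
                                 value_col = "pm_cytosol_ratio") {
  req <- c("condition", "replicate", value_col)
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- measurements[!measurements$degenerate, , drop = FALSE]
  key <- interaction(df$condition, df$replicate, drop = TRUE, sep = "\r")
  out <- lapply(levels(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    v <- rows[[value_col]]
    bad <- !is.finite(v)
    if (any(bad))
      cq_log("replicate %s/%s: %d cell(s) with non-finite %s excluded",
             rows$condition[1], rows$replicate[1], sum(bad), value_col)
    v <- v[!bad]
    if (length(v) == 0) {
      warning(sprintf("replicate %s/%s has no usable cells; dropped",
                      rows$condition[1], rows$replicate[1]))
      return(NULL)
    }
    data.frame(condition = rows$condition[1], replicate = rows$replicate[1],
               n_cells = length(v), mean_value = mean(v),
               sd_value = if (length(v) > 1) sd(v) else NA_real_,
               mean_area = mean(rows$area_um2[!bad]),
               n_excluded_nonfinite = sum(bad))
  })
  res <- do.call(rbind, out)
  res[order(res$condition, res$replicate), , drop = FALSE]
}

#' Condition-level summary over replicate means
#'
#' @param repsum data.frame from [aggregate_replicates()]
#' @return one row per condition with the mean and SD of the replicate
#'   means (replicates, not cells, are the units) and total cell count
#' @export
condition_summary <- function(repsum) {
  out <- lapply(split(repsum, repsum$condition), function(d)
    data.frame(condition = d$condition[1], n_replicates = nrow(d),
               n_cells = sum(d$n_cells), mean = mean(d$mean_value),
               sd = if (nrow(d) > 1) sd(d$mean_value) else NA_real_))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation, valid for 3 <= n <= 50 here (the replicate-mean
#' samples this pipeline feeds it are always small).
#'
#' @param x numeric sample
#' @return a `cq_test_report` with the W statistic and p-value
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 50) stop("shapiro_wilk requires 3 <= n <= 50, got ", n)
  r <- shapiro.test(x)
  new_test_report("Shapiro-Wilk", unname(r$statistic), n, r$p.value)
}

#' Levene test of variance homogeneity
#'
#' Classic Levene test: a one-way ANOVA on absolute deviations from the
#' group center. `center = "mean"` is the classic form; `"median"` is the
#' Brown-Forsythe variant.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2)
#' @param center `"mean"` or `"median"`
#' @return a `cq_test_report` with the F statistic, df and p-value
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  check_groups(groups, "levene_test")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  cfun <- if (center == "mean") mean else median
  r <- car::leveneTest(y, g, center = cfun)
  new_test_report(paste0("Levene(", center, ")"), r[1, "F value"],
                  c(r[1, "Df"], r[2, "Df"]), r[1, "Pr(>F)"])
}

check_groups <- function(groups, who) {
  if (!is.list(groups) || length(groups) < 2)
    stop(who, " requires at least 2 groups")
  if (any(lengths(groups) < 2))
    stop(who, " requires at least 2 observations per group")
  invisible(groups)
}

groups_to_df <- function(groups) {
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  nm[!nzchar(nm)] <- paste0("g", which(!nzchar(nm)))
  data.frame(y = unlist(groups, use.names = FALSE),
             g = factor(rep(nm, lengths(groups)), levels = nm))
}

#' One-way ANOVA
#'
#' @param groups list of numeric samples; in this pipeline the observations
#'   are biological-replicate means
#' @return a `cq_test_report` with F, df `(k - 1, N - k)` and the p-value
#' @export
one_way_anova <- function(groups) {
  check_groups(groups, "one_way_anova")
  df <- groups_to_df(groups)
  tab <- summary(aov(y ~ g, data = df))[[1]]
  f <- tab["g", "F value"]; p <- tab["g", "Pr(>F)"]
  if (!is.finite(f) && tab["g", "Sum Sq"] <= 1e-12 * max(1, abs(mean(df$y)))) {
    f <- 0; p <- 1  # no between-group variation at all
  }
  new_test_report("one-way ANOVA", f,
                  c(tab["g", "Df"], tab["Residuals", "Df"]), p)
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise mean differences with family-wise adjusted p-values from the
#' studentized-range distribution; unequal group sizes use the Tukey-Kramer
#' form. With two groups the adjusted p equals the pooled-variance two-sample
#' t-test p (q = sqrt(2)|t|).
#'
#' @param groups list of numeric samples (named names label the pairs)
#' @return a `cq_test_report` whose `pairs` table carries `diff`, `lwr`,
#'   `upr`, `p_adj` and significance `stars` per pair; the report-level
#'   statistic/p are those of the underlying ANOVA
#' @export
tukey_hsd <- function(groups) {
  check_groups(groups, "tukey_hsd")
  df <- groups_to_df(groups)
  fit <- aov(y ~ g, data = df)
  tk <- TukeyHSD(fit)$g
  # zero residual variance with zero differences: no evidence at all
  degen <- !is.finite(tk[, "p adj"]) & abs(tk[, "diff"]) <= 1e-12
  tk[degen, c("lwr", "upr")] <- 0
  tk[degen, "p adj"] <- 1
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      stars = significance_stars(tk[, "p adj"]),
                      row.names = NULL)
  tab <- summary(fit)[[1]]
  new_test_report("Tukey HSD", tab["g", "F value"],
                  c(tab["g", "Df"], tab["Residuals", "Df"]),
                  tab["g", "Pr(>F)"], pairs = pairs)
}

#' Map p-values to significance stars
#'
#' Inclusive thresholds: `****` p <= 1e-4, `***` p <= 1e-3, `**` p <= 0.01,
#' `*` p <= 0.05, otherwise `"ns"`.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return character vector of labels
#' @export
significance_stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' Full test battery on replicate means
#'
#' Runs Shapiro-Wilk per condition and Levene across conditions as
#' assumption gates, then one-way ANOVA with Tukey HSD on the replicate
#' means. When a gate fails at `alpha_gate` the battery still reports the
#' ANOVA (with a warning recorded in the output) rather than silently
#' switching tests; the gate outcome is part of the report.
#'
#' @param repsum data.frame from [aggregate_replicates()]
#' @param alpha_gate significance level for the assumption gates
#' @return list with `shapiro` (per condition), `levene`, `anova`, `tukey`,
#'   `gate_passed`, `warnings`
#' @export
ratio_test_battery <- function(repsum, alpha_gate = 0.05) {
  groups <- lapply(split(repsum, repsum$condition), `[[`, "mean_value")
  shap <- lapply(groups, function(g)
    if (length(g) >= 3) shapiro_wilk(g) else NULL)
  lev <- levene_test(groups)
  shap_p <- vapply(Filter(Negate(is.null), shap),
                   function(r) r$p_value, numeric(1))
  gate <- all(shap_p > alpha_gate) && lev$p_value > alpha_gate
  warn <- character(0)
  if (!gate)
    warn <- paste("assumption gate failed (Shapiro-Wilk or Levene at alpha =",
                  alpha_gate, "); ANOVA reported with caution")
  list(shapiro = shap, levene = lev, anova = one_way_anova(groups),
       tukey = tukey_hsd(groups), gate_passed = gate, warnings = warn)
}
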