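# End-to-end orchestration: simulate (or load) fields, segment, curate,
# quantify, aggregate and test, with a machine-readable run manifest. One
# config seed fans out deterministically to per-field seeds, so a single
# integer reproduces a whole run byte-identically.

#' Build a pipeline run configuration
#'
#' Two input modes. `conditions` mode simulates fields: each condition is a
#' named list of [simulation_config()] overrides, replicated
#' `n_replicates` x `fields_per_replicate` times with distinct derived
#' seeds. `inputs` mode analyses existing files: a data.frame with columns
#' `image`, `mask`, `condition`, `replicate`, `pixel_size` (and optionally
#' `channels`, a comma-separated name list).
#'
#' @param out_dir output directory
#' @param seed master seed; per-field seeds are derived from it
#' @param conditions named list of override lists (simulate mode)
#' @param n_replicates biological replicates per condition
#' @param fields_per_replicate imaged fields per replicate
#' @param base common [simulation_config()] overrides applied to every
#'   condition
#' @param inputs data.frame of existing image/mask paths (file mode)
#' @param band_halfwidth membrane-band half-width, micrometres
#' @param band_mode see [compartmentalize()]
#' @param segmentation `"truth"` (use the simulator's mask) or `"builtin"`
#'   ([segment_builtin()]); ignored in file mode (masks are given)
#' @param dead_criterion passed to [filter_dead_cells()]
#' @param exclusion_list path to an exclusion-list file, or `NULL`
#' @param channel channel analysed in the ratio statistics
#' @param min_size minimum cell size (pixels) for [mask_to_rois()]
#' @param write_images also write per-field TIFFs (slow; off by default)
#' @return validated list of class `run_config`
#' @export
run_config <- function(out_dir, seed = 1L, conditions = NULL,
                       n_replicates = 3L, fields_per_replicate = 1L,
                       base = list(), inputs = NULL, band_halfwidth = 0.25,
                       band_mode = "symmetric",
                       segmentation = c("truth", "builtin"),
                       dead_criterion = "list-only", exclusion_list = NULL,
                       channel = "GFP", min_size = 200L,
                       write_images = FALSE) {
  segmentation <- match.arg(segmentation)
  if (is.null(conditions) == is.null(inputs))
    stop("exactly one of `conditions` or `inputs` must be given")
  cfg <- structure(list(out_dir = out_dir, seed = as.integer(seed),
                        conditions = conditions,
                        n_replicates = as.integer(n_replicates),
                        fields_per_replicate = as.integer(fields_per_replicate),
                        base = base, inputs = inputs,
                        band_halfwidth = band_halfwidth,
                        band_mode = band_mode, segmentation = segmentation,
                        dead_criterion = dead_criterion,
                        exclusion_list = exclusion_list, channel = channel,
                        min_size = as.integer(min_size),
                        write_images = isTRUE(write_images)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    req <- c("image", "mask", "condition", "replicate", "pixel_size")
    miss <- setdiff(req, names(cfg$inputs))
    if (length(miss))
      stop("inputs is missing column(s): ", paste(miss, collapse = ", "))
    for (p in c(cfg$inputs$image, cfg$inputs$mask))
      if (!file.exists(p)) stop("input file not found: ", p)
  } else {
    if (length(cfg$conditions) < 1 || is.null(names(cfg$conditions)))
      stop("conditions must be a non-empty named list")
    for (nm in names(cfg$conditions))  # validate every derived sim config
      do.call(simulation_config,
              modifyList(cfg$base, cfg$conditions[[nm]]))
  }
  if (!is.null(cfg$exclusion_list) && !file.exists(cfg$exclusion_list))
    stop("exclusion list not found: ", cfg$exclusion_list)
  invisible(cfg)
}

# Deterministic per-field seed derived from the master seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 7919) %% 2147483647)
}

#' Run the full pipeline
#'
#' simulate/load -> ROIs -> edge filter -> dead-cell filter -> quantify ->
#' replicate aggregation -> test battery, writing every stage table and a
#' YAML manifest (config echo, per-field cell bookkeeping, output hashes).
#' Re-running with an identical config reproduces byte-identical CSVs.
#'
#' @param cfg a [run_config()]
#' @return invisibly, a list with `measurements`, `replicate_summary`,
#'   `condition_summary`, `battery`, `manifest`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  excl <- if (!is.null(cfg$exclusion_list))
    read_exclusion_list(cfg$exclusion_list) else NULL

  fields <- list()
  if (!is.null(cfg$conditions)) {
    idx <- 0L
    for (cond in names(cfg$conditions)) {
      for (rep_i in seq_len(cfg$n_replicates)) {
        for (f in seq_len(cfg$fields_per_replicate)) {
          idx <- idx + 1L
          sim_cfg <- do.call(simulation_config,
                             modifyList(modifyList(cfg$base,
                                                   cfg$conditions[[cond]]),
                                        list(seed = derive_seed(cfg$seed, idx))))
          fid <- sprintf("%s_rep%d_f%d", cond, rep_i, f)
          sim <- simulate_field(sim_cfg, field_id = fid)
          if (cfg$write_images)
            write_field(sim, file.path(cfg$out_dir, "fields"))
          mask <- if (cfg$segmentation == "builtin")
            segment_builtin(sim$micrograph, min_size = cfg$min_size)
          else sim$mask
          fields[[fid]] <- list(m = sim$micrograph, mask = mask,
                                condition = cond,
                                replicate = paste0("rep", rep_i))
        }
      }
    }
  } else {
    for (r in seq_len(nrow(cfg$inputs))) {
      row <- cfg$inputs[r, ]
      chn <- if ("channels" %in% names(row) && nzchar(row$channels))
        strsplit(row$channels, ",")[[1]] else cfg$channel
      fid <- sprintf("%s_%s_f%d", row$condition, row$replicate, r)
      fields[[fid]] <- list(
        m = read_micrograph(row$image, chn, pixel_size = row$pixel_size),
        mask = read_label_mask(row$mask),
        condition = row$condition, replicate = row$replicate)
    }
  }

  meas_all <- list(); bookkeeping <- list()
  for (fid in names(fields)) {
    fl <- fields[[fid]]
    rois <- mask_to_rois(fl$mask, min_size = cfg$min_size)
    rois <- filter_edge_cells(rois, field_shape(fl$m))
    rois <- filter_dead_cells(rois, fl$m, fl$mask, exclusion_list = excl,
                              criterion = cfg$dead_criterion, field_id = fid)
    meas <- quantify_field(fl$m, fl$mask, rois,
                           band_halfwidth = cfg$band_halfwidth,
                           band_mode = cfg$band_mode, field_id = fid)
    meas$condition <- fl$condition
    meas$replicate <- fl$replicate
    # bookkeeping with priority edge > excluded > degenerate > retained
    edge <- vapply(rois, function(r) r$flags$edge_touching, logical(1))
    dead <- vapply(rois, function(r) r$flags$excluded_dead ||
                     r$flags$excluded_manual, logical(1)) & !edge
    degen_labels <- unique(meas$cell_label[meas$degenerate])
    labs <- vapply(rois, function(r) r$label, 0L)
    degen <- labs %in% degen_labels & !edge & !dead
    bk <- list(field_id = fid, cells_in = length(rois),
               edge_removed = sum(edge), dead_removed = sum(dead),
               degenerate = sum(degen),
               retained = sum(!edge & !dead & !degen))
    stopifnot(bk$cells_in ==
                bk$retained + bk$edge_removed + bk$dead_removed + bk$degenerate)
    bookkeeping[[fid]] <- bk
    meas_all[[fid]] <- meas
  }
  measurements <- do.call(rbind, meas_all)
  rownames(measurements) <- NULL

  paths <- c(measurements = file.path(cfg$out_dir, "measurements.csv"))
  write_measurements(measurements, paths["measurements"])

  ch_rows <- measurements[measurements$channel == cfg$channel, , drop = FALSE]
  repsum <- aggregate_replicates(ch_rows)
  condsum <- condition_summary(repsum)
  paths["replicate_summary"] <- file.path(cfg$out_dir, "replicate_summary.csv")
  paths["condition_summary"] <- file.path(cfg$out_dir, "condition_summary.csv")
  write_summary_csv(repsum, paths["replicate_summary"])
  write_summary_csv(condsum, paths["condition_summary"])

  battery <- NULL
  if (length(unique(repsum$condition)) >= 2 &&
      all(table(repsum$condition) >= 2)) {
    battery <- ratio_test_battery(repsum)
    tests <- data.frame(
      test = c(paste0("shapiro_", names(battery$shapiro)),
               battery$levene$test, "anova"),
      statistic = c(vapply(battery$shapiro, function(r)
        if (is.null(r)) NA_real_ else r$statistic, numeric(1)),
        battery$levene$statistic, battery$anova$statistic),
      p_value = c(vapply(battery$shapiro, function(r)
        if (is.null(r)) NA_real_ else r$p_value, numeric(1)),
        battery$levene$p_value, battery$anova$p_value))
    paths["stats_tests"] <- file.path(cfg$out_dir, "stats_tests.csv")
    paths["stats_pairwise"] <- file.path(cfg$out_dir, "stats_pairwise.csv")
    write_summary_csv(tests, paths["stats_tests"])
    write_summary_csv(battery$tukey$pairs, paths["stats_pairwise"])
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cortiquant")),
    config = manifest_config(cfg),
    fields = bookkeeping,
    gate_passed = if (!is.null(battery)) battery$gate_passed else NA,
    outputs = as.list(setNames(unname(tools::md5sum(paths)), names(paths))))
  manifest_path <- file.path(cfg$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  cq_log("run complete: %d field(s), outputs in %s", length(fields),
         cfg$out_dir)
  invisible(list(measurements = measurements, replicate_summary = repsum,
                 condition_summary = condsum, battery = battery,
                 manifest = manifest, manifest_path = manifest_path))
}

# Config echo for the manifest: plain lists only.
manifest_config <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$inputs)) out$inputs <- as.list(out$inputs)
  out
}

# Deterministic CSV writer for summary tables (6 significant digits).
write_summary_csv <- function(df, path) {
  out <- df
  for (cn in names(out))
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]]))
      out[[cn]] <- fmt_num(out[[cn]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
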