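default_or <- function(x, default) if (is.null(x)) default else x

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_contract("no such config file: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_contract("config must be a list or a YAML path")
  if (is.null(config$seed))
    stop_contract("config schema error: missing key 'seed'")
  check_number(config$seed, "seed", integerish = TRUE)
  if (is.null(config$calcium) && is.null(config$counts))
    stop_contract(
      "config schema error: need at least one of 'calcium' or 'counts'")
  if (!is.null(config$calcium)) {
    cal <- config$calcium
    if (is.null(cal$frame_interval_s))
      stop_contract("config schema error: missing key 'calcium.frame_interval_s'")
    if (is.null(cal$conditions) || !length(cal$conditions))
      stop_contract("config schema error: missing key 'calcium.conditions'")
    for (i in seq_along(cal$conditions)) {
      if (is.null(cal$conditions[[i]]$label))
        stop_contract("config schema error: missing key 'calcium.conditions[%d].label'",
                      i)
    }
  }
  if (!is.null(config$counts)) {
    if (is.null(config$counts$contrasts) || !length(config$counts$contrasts))
      stop_contract("config schema error: missing key 'counts.contrasts'")
  }
  config
}

sim_config_from <- function(base, overrides) {
  args <- formals(sim_config)
  merged <- base
  for (nm in names(overrides)) {
    if (!nm %in% names(args))
      stop_contract("config schema error: unknown sim key '%s'", nm)
    merged[[nm]] <- overrides[[nm]]
  }
  do.call(sim_config, merged)
}

#' Run the full analysis pipeline from a config file
#'
#' Orchestrates end-to-end runs: for each condition in the calcium
#' section, simulates fields of view, renders traces, background-subtracts,
#' median-filters, detects spikes, computes the cross-correlation
#' eigenvalue synchrony, and compares conditions (per-cell spike rates and
#' per-field synchrony indices) with Kruskal-Wallis + Dunn; for the counts
#' section, simulates a count matrix and runs the per-cell-type Wilcoxon
#' DEG screen on the requested contrasts.  All outputs are plain CSV/JSON
#' files; a manifest records the config snapshot, seed, and an MD5 digest
#' of every output so a rerun can be verified byte for byte.
#'
#' @param config path to a YAML config file, or an equivalent nested list.
#'   Top level: `seed` (required) plus `calcium` and/or `counts` sections;
#'   see the package vignette for the schema.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character(0)
  report <- list()
  log_stage <- function(stage, detail) {
    message(sprintf("[%s] %s", stage, detail))
  }

  if (!is.null(config$calcium)) {
    cal <- config$calcium
    k_sd <- default_or(cal$detect$k_sd, 2)
    max_rise_s <- default_or(cal$detect$max_rise_s, 0.4)
    window_frames <- default_or(cal$background_window_frames, 150L)
    median_window <- default_or(cal$median_window, 3L)
    bin_frames <- default_or(cal$bin_frames, 1L)
    rates <- numeric(0); rate_labels <- character(0)
    syncs <- numeric(0); sync_labels <- character(0)
    cond_summaries <- list()
    for (cond in cal$conditions) {
      n_fields <- default_or(cond$n_fields, 3L)
      field_sync <- numeric(n_fields)
      field_active <- numeric(n_fields)
      cond_rates <- numeric(0)
      for (f in seq_len(n_fields)) {
        base <- list(frame_interval_s = cal$frame_interval_s,
                     duration_s = default_or(cal$duration_s, 200),
                     seed = child_seed(config$seed,
                                       sprintf("%s_field%d", cond$label, f)))
        cfg <- sim_config_from(base, default_or(cond$sim, list()))
        res <- pipeline_sync_index(cfg, k_sd = k_sd, max_rise_s = max_rise_s,
                                   window_frames = window_frames,
                                   median_window = median_window,
                                   bin_frames = bin_frames)
        st <- spike_stats(res$spikes)
        field_sync[f] <- res$sync$sync_index
        field_active[f] <- st$active_fraction
        cond_rates <- c(cond_rates, st$per_roi_rate)
        tag <- sprintf("%s_field%d", cond$label, f)
        sp_path <- file.path(out_dir, paste0("spikes_", tag, ".csv"))
        write_spikes(res$spikes, sp_path)
        sy_path <- file.path(out_dir, paste0("sync_", tag, ".json"))
        jsonlite::write_json(
          list(eigenvalues = res$sync$eigenvalues,
               lambda_max = res$sync$lambda_max,
               sync_index = res$sync$sync_index,
               n_rois = res$sync$n_rois),
          sy_path, auto_unbox = TRUE, digits = NA)
        outputs <- c(outputs, sp_path, sidecar_path(sp_path), sy_path)
        log_stage("calcium",
                  sprintf("%s: %d ROIs, sync index %.3f", tag,
                          res$sync$n_rois, res$sync$sync_index))
      }
      rates <- c(rates, cond_rates)
      rate_labels <- c(rate_labels, rep(cond$label, length(cond_rates)))
      syncs <- c(syncs, field_sync)
      sync_labels <- c(sync_labels, rep(cond$label, n_fields))
      cond_summaries[[cond$label]] <- list(
        n_fields = n_fields,
        mean_rate_per_min = mean(cond_rates),
        mean_active_fraction = mean(field_active),
        mean_sync_index = mean(field_sync))
    }
    report$calcium <- list(conditions = cond_summaries)
    if (length(unique(rate_labels)) >= 2L) {
      cmp <- compare_groups(rates, rate_labels,
                            adjust = default_or(cal$adjust, "holm"))
      report$calcium$rate_comparison <- list(
        method = cmp$method, H = cmp$statistic, p = cmp$p,
        pairwise = cmp$pairwise)
    }
    if (length(unique(sync_labels)) >= 2L &&
        min(table(sync_labels)) >= 2L) {
      cmp <- compare_groups(syncs, sync_labels,
                            adjust = default_or(cal$adjust, "holm"))
      report$calcium$sync_comparison <- list(
        method = cmp$method, H = cmp$statistic, p = cmp$p,
        pairwise = cmp$pairwise)
    }
  }

  if (!is.null(config$counts)) {
    cs <- config$counts
    ccfg_args <- default_or(cs$sim, list())
    ccfg_args$seed <- child_seed(config$seed, "counts_stage")
    ccfg <- do.call(count_sim_config, ccfg_args)
    sim <- simulate_counts(ccfg)
    mtx_dir <- file.path(out_dir, "counts")
    write_counts_mtx(sim$counts, mtx_dir)
    meta_path <- file.path(out_dir, "cell_metadata.csv")
    write_cell_meta(sim$meta, meta_path)
    outputs <- c(outputs,
                 file.path(mtx_dir, c("matrix.mtx", "genes.tsv",
                                      "barcodes.tsv")),
                 meta_path)
    norm <- normalize_counts(filter_zero_cells(sim$counts))
    meta_use <- sim$meta[sim$meta$cell_id %in% colnames(norm), ]
    cell_types <- default_or(cs$cell_types, unique(meta_use$cell_type))
    deg_summary <- list()
    for (ct in cell_types) {
      for (ctr in cs$contrasts) {
        ctr <- unlist(ctr)
        deg <- wilcoxon_deg(norm, meta_use, cell_type = ct, contrast = ctr)
        tag <- sprintf("%s_%s_vs_%s", ct, ctr[1], ctr[2])
        deg_path <- file.path(out_dir, paste0("deg_", tag, ".csv"))
        write.csv(as.data.frame(deg), deg_path, row.names = FALSE)
        outputs <- c(outputs, deg_path)
        deg_summary[[tag]] <- sum(deg$significant)
        log_stage("deg", sprintf("%s: %d significant genes", tag,
                                 sum(deg$significant)))
      }
    }
    prop <- cluster_proportion_test(meta_use)
    prop_path <- file.path(out_dir, "cluster_proportions.csv")
    write.csv(prop, prop_path, row.names = FALSE)
    outputs <- c(outputs, prop_path)
    report$counts <- list(n_cells = ncol(sim$counts),
                          n_genes = nrow(sim$counts),
                          n_planted = nrow(sim$truth),
                          significant_genes = deg_summary)
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  outputs <- c(outputs, report_path)
  manifest <- list(
    package = "neuroflux",
    version = as.character(utils::packageVersion("neuroflux")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[setdiff(names(config), "seed")],
    outputs = lapply(setNames(nm = basename(outputs)), function(b) {
      p <- outputs[basename(outputs) == b][1]
      list(path = b, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
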