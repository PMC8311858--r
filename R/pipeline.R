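# End-to-end orchestration: simulate/load -> connectivity -> graphs ->
# reference partition -> node metrics -> statistics -> report.

#' Pipeline configuration
#'
#' Collects every run-level choice in one validated list. Either give
#' `input_dir` (a directory of scan files plus `nodes.tsv` and
#' `covariates.tsv`) or a `design` to simulate. The reference partition is
#' taken from `partition_path` if given, otherwise derived from the
#' healthy-control scans by Ward clustering with `k` modules.
#'
#' @param input_dir Directory of time-series input, or `NULL` to simulate.
#' @param design A [cohort_design()] used when simulating.
#' @param partition_path Optional two-column partition file to load instead
#'   of clustering.
#' @param k Number of modules when deriving the partition from controls.
#' @param thresholds Edge-retention proportions.
#' @param target Stimulation-target node label.
#' @param controls Control ROI labels.
#' @param welch Use Welch instead of pooled t tests in group comparisons.
#' @param hemisphere Also compute per-hemisphere counts for the target.
#' @param seed Integer seed for the simulated cohort.
#' @param out_dir Optional output directory; when set, all artifacts are
#'   written there.
#' @return A `conn_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            design = NULL,
                            partition_path = NULL,
                            k = 7,
                            thresholds = default_thresholds(),
                            target = "LIFG_tri",
                            controls = c("RIFG_tri", "R_precuneus",
                                         "LIFG_orb", "LIFG_oper"),
                            welch = FALSE,
                            hemisphere = TRUE,
                            seed = 1L,
                            out_dir = NULL) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("thresholds must lie in (0, 1]")
  }
  structure(list(
    input_dir = input_dir, design = design, partition_path = partition_path,
    k = as.integer(k), thresholds = thresholds, target = target,
    controls = controls, welch = isTRUE(welch),
    hemisphere = isTRUE(hemisphere), seed = as.integer(seed),
    out_dir = out_dir
  ), class = "conn_config")
}

# Serializable view of a config (drops the non-scalar design internals down
# to its parameters) used for hashing and the run report.
config_fingerprint <- function(config) {
  d <- config$design
  list(
    input_dir = config$input_dir,
    design = if (is.null(d)) NULL else list(
      within_r = d$within_r, between_r = d$between_r,
      target_node = d$target_node, severity_slope = d$severity_slope,
      treatment_effect = d$treatment_effect, effect_sd = d$effect_sd,
      n_hc = d$n_hc, n_per_group = d$n_per_group, t_len = d$t_len,
      seed = d$seed),
    partition_path = config$partition_path, k = config$k,
    thresholds = config$thresholds, target = config$target,
    controls = config$controls, welch = config$welch,
    hemisphere = config$hemisphere, seed = config$seed
  )
}

#' Run the full segregation pipeline
#'
#' Executes every stage in order and returns a run report: the frozen
#' reference partition, the per-scan node metrics, per-module counts for
#' the target, and the statistical battery (pre-treatment models, change
#' model, paired/independent tests, brain-behavior model, per-module FDR
#' table) for the target and each control ROI. Reruns with the same config
#' and seed are byte-identical in their written tables.
#'
#' @param config A [pipeline_config()].
#' @return A `conn_report` list; see Details.
#' @details Report elements: `config_hash`, `seed`, `partition`, `metrics`,
#'   `module_counts`, `stats` (per-node list), `per_module`, `timings`,
#'   `nodes_analyzed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "conn_config"))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  # stage: input
  if (!is.null(config$input_dir)) {
    ts <- clock("load", read_timeseries_dir(config$input_dir))
    node_table <- validate_node_table(
      readr::read_tsv(file.path(config$input_dir, "nodes.tsv"),
                      show_col_types = FALSE, progress = FALSE))
    covariates <- read_covariates(file.path(config$input_dir, "covariates.tsv"))
  } else {
    design <- config$design %||% cohort_design(seed = config$seed)
    cohort <- clock("simulate", simulate_cohort(design))
    ts <- cohort$timeseries
    node_table <- design$node_table
    covariates <- cohort$covariates
  }

  analysis_nodes <- c(config$target, config$controls)
  missing_nodes <- setdiff(analysis_nodes, node_table$label)
  if (length(missing_nodes) > 0) {
    abort(paste0("stage config: node(s) not in node table: ",
                 paste(missing_nodes, collapse = ", ")))
  }

  # stage: reference partition (frozen for all subjects/timepoints)
  partition <- clock("partition", {
    if (!is.null(config$partition_path)) {
      load_reference_partition(config$partition_path, node_table)
    } else {
      hc_ids <- unique(covariates$subject_id[covariates$cohort == "HC"])
      hc_keys <- names(ts)[sub("_[^_]+$", "", names(ts)) %in% hc_ids]
      if (length(hc_keys) == 0) {
        abort("stage partition: no healthy-control scans to derive the reference organization from")
      }
      hc_mats <- lapply(ts[hc_keys], fisher_z_connectivity)
      ward_partition(group_mean_matrix(hc_mats), k = config$k,
                     node_table = node_table)
    }
  })

  # stage: metrics
  metrics <- clock("metrics", compute_node_metrics(
    ts, partition, nodes = analysis_nodes, thresholds = config$thresholds,
    node_table = node_table))
  module_counts <- clock("module_counts", compute_module_counts(
    ts, partition, node = config$target, thresholds = config$thresholds))

  # stage: stats
  has_patients <- any(covariates$cohort == "PPA")
  stats_list <- clock("stats", {
    if (!has_patients) list() else
    lapply(setNames(analysis_nodes, analysis_nodes), function(nd) {
      out <- list(pretreatment = pretreatment_model(metrics, covariates, nd))
      if (has_patients) {
        out$change <- change_model(metrics, covariates, nd)
        df <- out$change$extra$data
        for (a in c("active", "sham")) {
          sub <- df[df$arm == a, ]
          out[[paste0("paired_", a)]] <- paired_change_test(sub$pre, sub$post)
        }
        if (!all(is.na(df$behavior_gain))) {
          out$brain_behavior <- brain_behavior_model(metrics, covariates, nd)
        }
      }
      out
    })
  })
  per_module <- if (has_patients) {
    clock("per_module", per_module_tests(module_counts, covariates,
                                         welch = config$welch))
  } else NULL

  hemi <- NULL
  if (config$hemisphere) {
    hemi <- clock("hemisphere", {
      purrr::imap_dfr(ts, function(x, key) {
        parts <- strsplit(key, "_(?=[^_]+$)", perl = TRUE)[[1]]
        graphs <- multi_threshold_graphs(fisher_z_connectivity(x),
                                         config$thresholds)
        hemisphere_connection_counts(graphs, partition, config$target,
                                     node_table) |>
          mutate(subject_id = parts[1], timepoint = parts[2], .before = 1)
      })
    })
  }

  report <- structure(list(
    config_hash = rlang::hash(config_fingerprint(config)),
    seed = config$seed,
    nodes_analyzed = analysis_nodes,
    partition = partition,
    metrics = metrics,
    module_counts = module_counts,
    hemisphere_counts = hemi,
    stats = stats_list,
    per_module = per_module,
    timings = timings
  ), class = "conn_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.conn_report <- function(x, ...) {
  cat("<conn_report>\n")
  cat(sprintf("  %d ROIs analyzed: %s\n", length(x$nodes_analyzed),
              paste(x$nodes_analyzed, collapse = ", ")))
  cat(sprintf("  %d scans, %d reference modules, config %s, seed %d\n",
              dplyr::n_distinct(paste(x$metrics$subject_id,
                                      x$metrics$timepoint)),
              n_modules(x$partition), x$config_hash, x$seed))
  tg <- x$nodes_analyzed[1]
  st <- x$stats[[tg]]
  if (is.null(st)) return(invisible(x))
  sev <- tidy(st$pretreatment) |>
    filter(.data$model == "severity", .data$term == "severity")
  cat(sprintf("  %s severity association: t = %.2f, p = %.4g\n",
              tg, sev$statistic, sev$p.value))
  if (!is.null(st$change)) {
    arm <- tidy(st$change) |> filter(.data$term == "armactive")
    cat(sprintf("  %s arm difference in \u0394PC: t = %.2f, p = %.4g\n",
                tg, arm$statistic, arm$p.value))
  }
  invisible(x)
}

#' Write all report artifacts to a directory
#'
#' Writes the metrics, module-count, hemisphere and statistics tables as
#' TSV, the partition as a two-column file, and `report.json` with the
#' config hash, seed, analyzed ROIs and stage timings.
#'
#' @param report A `conn_report` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_metrics(report$metrics, file.path(dir, "metrics.tsv"))
  readr::write_tsv(report$module_counts, file.path(dir, "module_counts.tsv"),
                   progress = FALSE)
  if (!is.null(report$hemisphere_counts)) {
    readr::write_tsv(report$hemisphere_counts,
                     file.path(dir, "hemisphere_counts.tsv"), progress = FALSE)
  }
  write_partition(report$partition, file.path(dir, "partition.tsv"))
  stat_rows <- purrr::imap_dfr(report$stats, function(models, nd) {
    purrr::imap_dfr(models, function(st, nm) {
      tidy(st) |> mutate(node = nd, model_id = st$model_id, analysis = nm,
                         .before = 1)
    })
  })
  readr::write_tsv(stat_rows, file.path(dir, "stats.tsv"), progress = FALSE)
  if (!is.null(report$per_module)) {
    readr::write_tsv(report$per_module, file.path(dir, "per_module.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(config_hash = report$config_hash, seed = report$seed,
         nodes_analyzed = report$nodes_analyzed, timings = report$timings),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
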