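# Delimited-text I/O for every pipeline artifact. Tab-separated, UTF-8,
# header rows, full numeric precision; lossless round trips are covered by
# tests.

#' Write / read an ROI-by-time series matrix
#'
#' One file per scan: rows are ROIs (first column `label`), columns are
#' time points `t1..tT`. `read_timeseries(transpose = TRUE)` accepts the
#' transposed layout (rows = time points, columns = ROIs).
#'
#' @param ts ROI-by-time numeric matrix with ROI row names.
#' @param path File path (`.tsv`).
#' @return `write_timeseries()`: `path`, invisibly. `read_timeseries()`:
#'   the matrix, ROI labels as row names.
#' @export
write_timeseries <- function(ts, path) {
  df <- as_tibble(ts, .name_repair = ~ paste0("t", seq_along(.x)))
  df <- dplyr::bind_cols(tibble(label = rownames(ts) %||%
                                  paste0("node", seq_len(nrow(ts)) - 1L)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param transpose Input file has time points as rows.
#' @export
read_timeseries <- function(path, transpose = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (transpose) {
    m <- t(as.matrix(df))
    rownames(m) <- colnames(df)
    return(m)
  }
  labels <- df[[1]]
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) abort(sprintf("non-numeric entries in %s", path))
  rownames(m) <- labels
  dimnames(m)[2] <- list(NULL)
  m
}

#' Write / read a square connectivity matrix
#'
#' Square tab-separated layout with node labels as header and first column.
#'
#' @param z Symmetric numeric matrix with dimnames.
#' @param path File path.
#' @export
write_matrix <- function(z, path) {
  labels <- rownames(z) %||% paste0("node", seq_len(nrow(z)) - 1L)
  df <- as_tibble(z, .name_repair = ~labels)
  df <- dplyr::bind_cols(tibble(label = labels), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) abort(sprintf("non-numeric entries in %s", path))
  if (nrow(m) != ncol(m)) {
    abort(sprintf("%s is not a square matrix (%d x %d)", path, nrow(m), ncol(m)))
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' Write / read the covariate table
#'
#' @param covariates Covariate tibble (see [simulate_cohort()]).
#' @param path File path.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "cohort", "arm", "timepoint", "age", "gender",
                "education", "motion_rms")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("covariate file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"severity" %in% names(df) && any(df$cohort == "PPA")) {
    abort("covariate file has PPA rows but no 'severity' column")
  }
  bad <- df$subject_id[df$cohort == "PPA" & is.na(df$severity)]
  if (length(bad) > 0) {
    abort(paste0("severity missing for PPA subject(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  df
}

#' Write / read a long metrics table
#'
#' @param metrics Metrics tibble from [compute_node_metrics()].
#' @param path File path.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_tsv(metrics, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a cohort's time series to a directory
#'
#' One `<subject>_<timepoint>.tsv` per scan plus `nodes.tsv`,
#' `covariates.tsv` and a `ground_truth.json` sidecar.
#'
#' @param cohort A `conn_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "conn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  walk(names(cohort$timeseries), function(key) {
    write_timeseries(cohort$timeseries[[key]],
                     file.path(dir, paste0(key, ".tsv")))
  })
  readr::write_tsv(cohort$design$node_table, file.path(dir, "nodes.tsv"),
                   progress = FALSE)
  write_covariates(cohort$covariates, file.path(dir, "covariates.tsv"))
  truth <- cohort$truth
  truth$partition <- as.list(setNames(truth$partition$module,
                                      truth$partition$label))
  truth$subjects <- as.data.frame(truth$subjects)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a directory of time-series files
#'
#' Reads every `<subject>_<timepoint>.tsv` scan file in `dir` (any file
#' other than `nodes.tsv`, `covariates.tsv` and sidecars).
#'
#' @param dir Directory written by [write_cohort()] or with the same layout.
#' @param transpose Scan files store time points as rows.
#' @return Named list of ROI-by-time matrices.
#' @export
read_timeseries_dir <- function(dir, transpose = FALSE) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  files <- files[!basename(files) %in%
                   c("nodes.tsv", "covariates.tsv", "metrics.tsv",
                     "partition.tsv")]
  if (length(files) == 0) abort(sprintf("no time-series files found in %s", dir))
  ts <- lapply(files, function(f) {
    tryCatch(read_timeseries(f, transpose = transpose),
             error = function(e) {
               abort(sprintf("failed to read time series %s: %s",
                             basename(f), conditionMessage(e)))
             })
  })
  names(ts) <- sub("\\.tsv$", "", basename(files))
  ts
}
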