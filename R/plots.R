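# ggplot2 convenience plots for the main result types.

#' Heatmap of a connectivity matrix ordered by module
#'
#' @param z Symmetric connectivity matrix with node labels.
#' @param partition Optional partition; nodes are reordered by module so
#'   the planted/estimated block structure is visible.
#' @return A ggplot object.
#' @export
plot_connectivity <- function(z, partition = NULL) {
  labels <- rownames(z) %||% paste0("node", seq_len(nrow(z)) - 1L)
  ord <- seq_len(nrow(z))
  if (!is.null(partition)) {
    partition <- validate_partition(partition)
    ord <- order(partition$module, partition$node_id)
  }
  df <- tidyr::expand_grid(row = seq_len(nrow(z)), col = seq_len(ncol(z))) |>
    mutate(value = as.vector(z[ord, ord]))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "Fisher z") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Connectivity (module-ordered)") +
    ggplot2::theme_minimal()
}

#' Pre/post participation coefficient by group
#'
#' Mean +/- SEM of a node's threshold-averaged PC per group and timepoint,
#' the standard display for treatment-arm change.
#'
#' @param metrics Metrics tibble from [compute_node_metrics()].
#' @param covariates Covariate tibble.
#' @param node Node label.
#' @return A ggplot object.
#' @export
plot_pc_change <- function(metrics, covariates, node = "LIFG_tri") {
  df <- metrics |>
    filter(.data$node == !!node) |>
    left_join(dplyr::distinct(covariates, .data$subject_id, .data$cohort,
                              .data$arm),
              by = "subject_id") |>
    mutate(group = ifelse(.data$cohort == "HC", "HC", .data$arm)) |>
    group_by(.data$group, .data$timepoint) |>
    summarise(mean_pc = mean(.data$pc),
              sem = sd(.data$pc) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint, .data$mean_pc,
                                   group = .data$group,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pc - .data$sem,
                                        ymax = .data$mean_pc + .data$sem),
                           width = 0.1) +
    ggplot2::labs(x = NULL, y = "participation coefficient",
                  colour = NULL, title = node) +
    ggplot2::theme_minimal()
}

#' Severity vs participation coefficient scatter
#'
#' Pre-treatment PC of one node against dementia severity across patients,
#' with a linear fit — the display behind the severity-association model.
#'
#' @inheritParams plot_pc_change
#' @return A ggplot object.
#' @export
plot_pc_by_severity <- function(metrics, covariates, node = "LIFG_tri") {
  df <- metrics |>
    filter(.data$node == !!node, .data$timepoint == "pre") |>
    left_join(covariates, by = c("subject_id", "timepoint"))
  ggplot2::ggplot(df, ggplot2::aes(.data$severity, .data$pc)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$arm)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black") +
    ggplot2::labs(x = "dementia severity (0-15)",
                  y = "participation coefficient",
                  colour = NULL, title = paste0(node, ", pre-treatment")) +
    ggplot2::theme_minimal()
}

#' Per-module connection counts of the target node by group/timepoint
#'
#' @param module_counts Tibble from [compute_module_counts()].
#' @param covariates Covariate tibble.
#' @return A ggplot object.
#' @export
plot_module_counts <- function(module_counts, covariates) {
  df <- module_counts |>
    left_join(dplyr::distinct(covariates, .data$subject_id, .data$cohort,
                              .data$arm),
              by = "subject_id") |>
    mutate(group = ifelse(.data$cohort == "HC", "HC",
                          paste(.data$arm, .data$timepoint)),
           module_lab = if ("module_name" %in% names(module_counts))
             .data$module_name else paste0("module_", .data$module)) |>
    group_by(.data$group, .data$module_lab, .data$within) |>
    summarise(mean_count = mean(.data$count), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$module_lab, .data$mean_count,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean connections (across thresholds)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
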