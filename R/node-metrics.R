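# Participation coefficients and within/between-module connection counts,
# averaged across proportional thresholds.

# Fast core: PC for every node of one adjacency matrix given a 0-based
# membership vector. PC_i = 1 - sum_m (k_im / k_i)^2; isolated nodes get 0.
pc_vector <- function(adj, membership) {
  n <- nrow(adj)
  modules <- sort(unique(membership))
  ind <- matrix(0, n, length(modules))
  ind[cbind(seq_len(n), match(membership, modules))] <- 1
  k_im <- (adj * 1) %*% ind
  k_i <- rowSums(k_im)
  pc <- 1 - rowSums((k_im / pmax(k_i, 1))^2)
  pc[k_i == 0] <- 0
  pc
}

#' Participation coefficient of every node in one binary graph
#'
#' For node i with degree \eqn{k_i > 0} and \eqn{k_i(m)} edges into module
#' m, \eqn{PC_i = 1 - \sum_m (k_i(m)/k_i)^2}. A node whose edges all stay
#' in one module scores 0; edges spread evenly over all M modules approach
#' the maximum \eqn{1 - 1/M}. Isolated nodes (degree 0) are assigned 0, the
#' "no diversity" reading, so sparse thresholds never produce undefined
#' values.
#'
#' @param adj Logical/0-1 symmetric adjacency matrix with zero diagonal.
#' @param partition Partition tibble covering the graph's node set.
#' @return Tibble with `node_id`, `label` (if available), `degree`, `pc`.
#' @examples
#' part <- make_partition(default_node_table(), 7)
#' z <- fisher_z_connectivity(matrix(rnorm(76 * 60), nrow = 76))
#' participation_coefficient(proportional_threshold(z, 0.2), part)
#' @export
participation_coefficient <- function(adj, partition) {
  adj <- as.matrix(adj)
  partition <- validate_partition(partition)
  if (nrow(adj) != nrow(partition)) {
    abort("graph has node(s) absent from the partition (sizes differ)")
  }
  memb <- partition_membership(partition, nrow(adj))
  tibble(
    node_id = partition$node_id,
    label = if ("label" %in% names(partition)) partition$label else NA_character_,
    degree = as.integer(rowSums(adj)),
    pc = pc_vector(adj, memb)
  )
}

#' Threshold-averaged participation coefficient
#'
#' Computes PC per node at every threshold of a graph set and averages with
#' equal weights (plain arithmetic mean). Per-threshold values are kept so
#' that effects can be confirmed at each individual threshold.
#'
#' @param graphs A `conn_graphs` object from [multi_threshold_graphs()].
#' @param partition Partition tibble.
#' @return Tibble with `node_id`, `label`, `pc` (threshold mean); the
#'   per-threshold values are available via [pc_by_threshold()].
#' @export
threshold_averaged_pc <- function(graphs, partition) {
  long <- pc_by_threshold(graphs, partition)
  long |>
    group_by(.data$node_id, .data$label) |>
    summarise(pc = mean(.data$pc), .groups = "drop") |>
    arrange(.data$node_id)
}

#' Per-threshold participation coefficients, long format
#'
#' @inheritParams threshold_averaged_pc
#' @return Tibble with `threshold`, `node_id`, `label`, `degree`, `pc`.
#' @export
pc_by_threshold <- function(graphs, partition) {
  stopifnot(inherits(graphs, "conn_graphs"))
  th <- attr(graphs, "thresholds")
  purrr::map2(graphs, th, function(g, p) {
    participation_coefficient(g, partition) |> mutate(threshold = p)
  }) |>
    bind_rows() |>
    select("threshold", "node_id", "label", "degree", "pc")
}

#' Mean per-module connection counts of one node
#'
#' Counts, at each proportional threshold, how many of the node's edges land
#' in each module of the reference partition, then averages the counts
#' across thresholds (fractional values are therefore expected). The entry
#' for the node's own module is its within-module connectivity; the sum of
#' the other entries is its between-module connectivity.
#'
#' @param graphs A `conn_graphs` object.
#' @param partition Partition tibble.
#' @param node Node label or 0-based node id.
#' @return Tibble with `module`, `module_name` (if present), `within`
#'   (logical: the node's own module) and `count` (mean over thresholds).
#' @export
module_connection_counts <- function(graphs, partition, node) {
  stopifnot(inherits(graphs, "conn_graphs"))
  partition <- validate_partition(partition)
  i <- resolve_node(node, partition)
  memb <- partition_membership(partition)
  modules <- sort(unique(memb))

  per_thr <- vapply(graphs, function(adj) {
    nb <- which(adj[i, ])
    vapply(modules, function(m) sum(memb[nb] == m), numeric(1))
  }, numeric(length(modules)))
  counts <- rowMeans(per_thr)

  out <- tibble(module = modules,
                within = modules == memb[i],
                count = counts)
  if ("module_name" %in% names(partition)) {
    name_map <- partition |>
      dplyr::distinct(.data$module, .data$module_name)
    out <- left_join(out, name_map, by = "module") |>
      select("module", "module_name", "within", "count")
  }
  out
}

#' Within/between-module connectivity summary of one node
#'
#' @inheritParams module_connection_counts
#' @return One-row tibble with `within_count`, `between_count` and
#'   `mean_degree` (their sum).
#' @export
within_between_counts <- function(graphs, partition, node) {
  counts <- module_connection_counts(graphs, partition, node)
  tibble(
    within_count = sum(counts$count[counts$within]),
    between_count = sum(counts$count[!counts$within]),
    mean_degree = sum(counts$count)
  )
}

#' Per-hemisphere within/between connection counts of one node
#'
#' Recomputes the within/between-module counts twice, restricting the
#' node's neighbors to left-hemisphere and to right-hemisphere nodes. The
#' two restrictions partition the neighbor set, so the L and R counts sum
#' to the whole-brain counts.
#'
#' @inheritParams module_connection_counts
#' @param node_table Node table carrying the hemisphere of every node.
#' @return Tibble with one row per hemisphere: `hemisphere`,
#'   `within_count`, `between_count`.
#' @export
hemisphere_connection_counts <- function(graphs, partition, node,
                                         node_table = default_node_table()) {
  stopifnot(inherits(graphs, "conn_graphs"))
  partition <- validate_partition(partition)
  node_table <- validate_node_table(node_table)
  if (nrow(node_table) != nrow(partition) || anyNA(node_table$hemisphere)) {
    abort("every node needs a hemisphere annotation")
  }
  i <- resolve_node(node, partition)
  memb <- partition_membership(partition)
  hemi <- node_table$hemisphere

  purrr::map_dfr(c("L", "R"), function(h) {
    per_thr <- vapply(graphs, function(adj) {
      nb <- which(adj[i, ] & hemi == h)
      c(within = sum(memb[nb] == memb[i]),
        between = sum(memb[nb] != memb[i]))
    }, numeric(2))
    tibble(hemisphere = h,
           within_count = mean(per_thr["within", ]),
           between_count = mean(per_thr["between", ]))
  })
}

# Accept a label or a 0-based node id; return a 1-based row index.
resolve_node <- function(node, partition) {
  if (is.character(node)) {
    if (!"label" %in% names(partition) || !node %in% partition$label) {
      abort(sprintf("node '%s' not found in the partition", node))
    }
    match(node, partition$label)
  } else {
    i <- match(as.integer(node), partition$node_id)
    if (is.na(i)) abort(sprintf("node id %s not found in the partition", node))
    i
  }
}

#' Node metrics for a whole cohort
#'
#' Runs the full per-scan pipeline — Fisher-z connectivity, proportional
#' thresholding, threshold-averaged PC and within/between-module counts —
#' for each requested node of every scan in a cohort.
#'
#' @param timeseries Named list of ROI-by-time matrices; names must be
#'   `<subject>_<timepoint>`.
#' @param partition Reference partition (frozen; shared by all scans).
#' @param nodes Character vector of node labels to report (default: the
#'   stimulation target and the four control ROIs).
#' @param thresholds Edge-retention proportions.
#' @param node_table Node table (for hemisphere counts).
#' @return Tibble with one row per scan x node: `subject_id`, `timepoint`,
#'   `node`, `pc`, `within_count`, `between_count`, `mean_degree`.
#' @export
compute_node_metrics <- function(timeseries, partition,
                                 nodes = c("LIFG_tri", "RIFG_tri",
                                           "R_precuneus", "LIFG_orb",
                                           "LIFG_oper"),
                                 thresholds = default_thresholds(),
                                 node_table = default_node_table()) {
  partition <- validate_partition(partition)
  memb <- partition_membership(partition)
  node_idx <- vapply(nodes, resolve_node, integer(1), partition = partition)

  keys <- names(timeseries)
  n_scan <- length(keys)
  n_node <- length(nodes)
  # flat accumulators; one tibble at the end (scan loops run thousands of
  # times in simulation studies, so per-scan tibble construction is avoided)
  pc_out <- within_out <- between_out <- degree_out <-
    numeric(n_scan * n_node)

  for (s in seq_len(n_scan)) {
    graphs <- multi_threshold_graphs(fisher_z_connectivity(timeseries[[s]]),
                                     thresholds)
    pc_mat <- vapply(graphs, function(g) pc_vector(g, memb),
                     numeric(nrow(partition)))
    pc_mean <- rowMeans(pc_mat)
    for (j in seq_len(n_node)) {
      i <- node_idx[j]
      w <- b <- 0
      for (adj in graphs) {
        nbm <- memb[adj[i, ]]
        w <- w + sum(nbm == memb[i])
        b <- b + sum(nbm != memb[i])
      }
      k <- (s - 1L) * n_node + j
      pc_out[k] <- pc_mean[i]
      within_out[k] <- w / length(graphs)
      between_out[k] <- b / length(graphs)
      degree_out[k] <- (w + b) / length(graphs)
    }
  }

  scan_parts <- t(vapply(keys, function(key) {
    strsplit(key, "_(?=[^_]+$)", perl = TRUE)[[1]]
  }, character(2)))
  tibble(
    subject_id = rep(scan_parts[, 1], each = n_node),
    timepoint = rep(scan_parts[, 2], each = n_node),
    node = rep(nodes, times = n_scan),
    pc = pc_out,
    within_count = within_out,
    between_count = between_out,
    mean_degree = degree_out
  )
}

#' Per-module connection counts for a whole cohort
#'
#' Threshold-averaged counts of one node's connections into every module,
#' for each scan — the input to [per_module_tests()].
#'
#' @inheritParams compute_node_metrics
#' @param node Node label (or 0-based id) whose connections are counted.
#' @return Long tibble: `subject_id`, `timepoint`, `module`, `module_name`
#'   (when the partition is named), `within`, `count`.
#' @export
compute_module_counts <- function(timeseries, partition, node = "LIFG_tri",
                                  thresholds = default_thresholds()) {
  partition <- validate_partition(partition)
  purrr::imap(timeseries, function(ts, key) {
    parts <- strsplit(key, "_(?=[^_]+$)", perl = TRUE)[[1]]
    graphs <- multi_threshold_graphs(fisher_z_connectivity(ts), thresholds)
    module_connection_counts(graphs, partition, node) |>
      mutate(subject_id = parts[1], timepoint = parts[2], .before = 1)
  }) |>
    bind_rows()
}
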