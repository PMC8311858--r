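# Modular partitions: every node assigned to exactly one module.
#
# A partition is a tibble with columns node_id, label, module (0-based
# contiguous integer module ids) and optionally module_name. One partition —
# derived from healthy controls or loaded from a file — is frozen and reused
# for every subject and timepoint; participation coefficients are only
# meaningful against a fixed reference organization.

new_partition <- function(node_table, module, module_name = NULL) {
  node_table <- validate_node_table(node_table)
  part <- node_table |>
    mutate(module = as.integer(module))
  if (!is.null(module_name)) part$module_name <- as.character(module_name)
  validate_partition(part)
}

# Contract: every node has one module, module ids contiguous 0..M-1.
validate_partition <- function(partition) {
  partition <- as_tibble(partition)
  if (!all(c("node_id", "module") %in% names(partition))) {
    abort("a partition needs `node_id` and `module` columns")
  }
  if (anyNA(partition$module)) abort("every node must be assigned a module")
  m_ids <- sort(unique(as.integer(partition$module)))
  if (!identical(m_ids, 0:(length(m_ids) - 1L))) {
    abort("module ids must be contiguous integers starting at 0")
  }
  arrange(partition, .data$node_id)
}

n_modules <- function(partition) {
  length(unique(partition$module))
}

# Membership vector in node order (0-based module ids), used by all
# adjacency-matrix computations.
partition_membership <- function(partition, n_nodes = nrow(partition)) {
  partition <- validate_partition(partition)
  if (nrow(partition) != n_nodes) {
    abort("partition and graph disagree on the number of nodes")
  }
  as.integer(partition$module)
}

#' Plant a bilateral modular partition
#'
#' Assigns `n_modules` modules over the nodes of `node_table` so that module
#' sizes are as equal as divisibility allows and every module contains nodes
#' from both hemispheres, mirroring the bilateral resting-state modules the
#' reference organization exhibits. Left- and right-hemisphere nodes are
#' dealt to modules in node-id order, so a node table grouped by intended
#' module yields contiguous blocks.
#'
#' @param node_table Node table (see [default_node_table()]); must contain
#'   nodes of both hemispheres.
#' @param n_modules Number of modules, at most the number of nodes.
#' @return A partition tibble (`node_id`, `label`, `hemisphere`, `module`).
#' @examples
#' make_partition(default_node_table(), n_modules = 7)
#' @export
make_partition <- function(node_table, n_modules) {
  node_table <- validate_node_table(node_table)
  n <- nrow(node_table)
  n_modules <- stopifnot_scalar_count(n_modules, "n_modules")
  if (n_modules > n) {
    abort(sprintf("invalid design: n_modules (%d) exceeds n_nodes (%d)",
                  n_modules, n))
  }
  if (length(unique(node_table$hemisphere)) < 2 && n_modules < n) {
    abort("node table must contain both hemispheres for a bilateral partition")
  }

  # Target sizes differ by at most 1; per-module hemisphere quotas split
  # each module's size as evenly as the hemisphere totals allow.
  sizes <- rep(n %/% n_modules, n_modules)
  extra <- n %% n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  n_left <- sum(node_table$hemisphere == "L")
  left_quota <- pmin(sizes %/% 2L, n_left)
  deficit <- n_left - sum(left_quota)
  i <- 1L
  while (deficit > 0) {
    if (left_quota[i] < sizes[i]) {
      left_quota[i] <- left_quota[i] + 1L
      deficit <- deficit - 1L
    }
    i <- if (i == n_modules) 1L else i + 1L
  }
  right_quota <- sizes - left_quota

  module <- integer(n)
  ord <- order(node_table$node_id)
  left_nodes <- ord[node_table$hemisphere[ord] == "L"]
  right_nodes <- ord[node_table$hemisphere[ord] == "R"]
  module[left_nodes] <- rep(seq_len(n_modules) - 1L, times = left_quota)
  module[right_nodes] <- rep(seq_len(n_modules) - 1L, times = right_quota)

  new_partition(node_table, module)
}

#' Load a reference modular partition from a file
#'
#' Reads a two-column delimited text file (`label`, `module_name`) and binds
#' it to a node table, validating that every node appears exactly once and
#' that no unknown labels are present. Module ids are assigned 0..M-1 in
#' order of first appearance.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param node_table Node table the partition must cover; defaults to
#'   [default_node_table()].
#' @return A partition tibble with `module` and `module_name` columns.
#' @seealso [reference_partition()] for the packaged reference organization.
#' @export
load_reference_partition <- function(path, node_table = default_node_table()) {
  node_table <- validate_node_table(node_table)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("partition file must have two columns: label, module_name")
  names(raw)[1:2] <- c("label", "module_name")

  unknown <- setdiff(raw$label, node_table$label)
  if (length(unknown) > 0) {
    abort(paste0("partition file names unknown node(s): ",
                 paste(unknown, collapse = ", ")))
  }
  dup <- raw$label[duplicated(raw$label)]
  if (length(dup) > 0) {
    abort(paste0("partition file lists node(s) more than once: ",
                 paste(unique(dup), collapse = ", ")))
  }
  missing <- setdiff(node_table$label, raw$label)
  if (length(missing) > 0) {
    abort(paste0("partition file is missing node(s): ",
                 paste(missing, collapse = ", ")))
  }

  module_levels <- unique(raw$module_name)
  raw$module <- match(raw$module_name, module_levels) - 1L
  part <- left_join(node_table, raw, by = "label")
  validate_partition(part)
}

#' Write a partition to a two-column delimited file
#'
#' @param partition Partition tibble with `label` and either `module_name`
#'   or `module`.
#' @param path Output path (tab-separated, header row).
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  partition <- validate_partition(partition)
  out <- tibble(
    label = partition$label,
    module_name = if ("module_name" %in% names(partition)) {
      partition$module_name
    } else {
      paste0("module_", partition$module)
    }
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' The packaged reference modular organization
#'
#' Loads the seven-module bilateral reference organization that ships with
#' the package (perisylvian, temporal, FP, dFP, vmPFC, occipital-temporal,
#' subcortical over the default 76-node table; the stimulation target
#' `LIFG_tri` sits in the perisylvian module). The node memberships are a
#' synthetic stand-in constructed for this package — the clinical study's
#' per-node assignments are not public — with the module structure
#' (seven bilateral modules, target in perisylvian) that analyses assume.
#'
#' @param node_table Node table to bind the partition to.
#' @return A partition tibble.
#' @export
reference_partition <- function(node_table = default_node_table()) {
  path <- system.file("extdata", "reference_modules_synthetic.tsv",
                      package = "connseg", mustWork = TRUE)
  load_reference_partition(path, node_table)
}
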