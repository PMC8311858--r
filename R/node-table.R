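# Node tables: one row per ROI, 0-based contiguous ids, hemisphere L/R.

# 38 gray-matter structures per hemisphere, grouped by the module each is
# assigned to in the packaged synthetic reference organization.
.connseg_regions <- list(
  perisylvian = c("IFG_tri", "IFG_oper", "IFG_orb", "STG", "supramarginal",
                  "Heschl", "insula"),
  temporal = c("MTG", "ITG", "temporal_pole", "PHG", "entorhinal",
               "hippocampus", "amygdala"),
  FP = c("MFG", "angular", "SPL", "frontal_pole"),
  dFP = c("SFG", "precentral", "postcentral", "SMA", "MCC"),
  vmPFC = c("mOFC", "gyrus_rectus", "ACC", "PCC", "precuneus"),
  `occipital-temporal` = c("cuneus", "lingual", "LOC", "pericalcarine",
                           "fusiform"),
  subcortical = c("caudate", "putamen", "pallidum", "thalamus", "accumbens")
)

.node_label <- function(region, hemisphere) {
  # IFG subdivisions use the compact LIFG_tri / RIFG_tri convention common
  # in the stimulation literature; all other structures are L_/R_ prefixed.
  ifelse(grepl("^IFG_", region),
         paste0(hemisphere, region),
         paste0(hemisphere, "_", region))
}

#' Default 76-node ROI table
#'
#' A parcellation-style node table with 76 gray-matter structures, 38 per
#' hemisphere, matching the node set the pipeline's defaults assume. Node
#' ids are 0-based and contiguous; labels are unique anatomical names such
#' as `LIFG_tri` (left inferior frontal gyrus, pars triangularis) or
#' `R_precuneus`.
#'
#' @return A tibble with columns `node_id`, `label`, `hemisphere`.
#' @examples
#' default_node_table()
#' @export
default_node_table <- function() {
  regions <- unlist(.connseg_regions, use.names = FALSE)
  tibble(
    region = rep(regions, each = 2),
    hemisphere = rep(c("L", "R"), times = length(regions))
  ) |>
    mutate(node_id = seq_len(dplyr::n()) - 1L,
           label = .node_label(.data$region, .data$hemisphere)) |>
    select("node_id", "label", "hemisphere")
}

# Validate the NodeTable contract: 0..n-1 ids with no gaps, unique labels,
# every node in {L, R}.
validate_node_table <- function(node_table) {
  node_table <- as_tibble(node_table)
  required <- c("node_id", "label", "hemisphere")
  missing <- setdiff(required, names(node_table))
  if (length(missing) > 0) {
    abort(paste0("node table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(node_table)
  if (n == 0) abort("node table is empty")
  if (!identical(sort(as.integer(node_table$node_id)), 0:(n - 1L))) {
    abort("node_id must be 0-based, contiguous and unique")
  }
  if (anyDuplicated(node_table$label)) {
    abort("node labels must be unique")
  }
  if (!all(node_table$hemisphere %in% c("L", "R"))) {
    abort("hemisphere must be 'L' or 'R' for every node")
  }
  arrange(node_table, .data$node_id)
}

node_labels <- function(node_table) {
  validate_node_table(node_table)$label
}
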