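# Deriving the reference modular organization from healthy-control data.

#' Entrywise mean of connectivity matrices
#'
#' Averages a list of connectivity matrices over subjects (typically the
#' healthy-control group), the input to reference clustering.
#'
#' @param matrices Non-empty list of symmetric matrices over the same node
#'   set (same dimension and, if named, the same labels in the same order).
#' @return A symmetric matrix of the same dimension.
#' @export
group_mean_matrix <- function(matrices) {
  if (length(matrices) == 0) {
    abort("need at least one connectivity matrix (is the HC group empty?)")
  }
  ref_dim <- dim(matrices[[1]])
  ref_names <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(dim(m), ref_dim) ||
        (!is.null(ref_names) && !identical(rownames(m), ref_names))) {
      abort("all matrices must share the same node set")
    }
  }
  Reduce(`+`, matrices) / length(matrices)
}

#' Ward clustering of the group-mean connectivity matrix
#'
#' Derives a modular partition by agglomerative hierarchical clustering with
#' Ward's criterion. Each node's feature vector is its row of the mean
#' Fisher-z matrix with the diagonal entry set to 0; inter-node distance is
#' Euclidean between rows, and the dendrogram is cut to exactly `k`
#' clusters. The procedure is fully deterministic given its input.
#'
#' Module ids are renumbered 0..k-1 in order of each module's first node,
#' so the labeling is stable under relabeling-invariant comparisons.
#'
#' @param mean_matrix Symmetric group-mean connectivity matrix.
#' @param k Number of modules (1 to n). The number of modules is a design
#'   input, not something this function estimates; see
#'   [silhouette_profile()] for guidance.
#' @param node_table Node table binding rows to nodes.
#' @return A partition tibble.
#' @export
ward_partition <- function(mean_matrix, k, node_table = default_node_table()) {
  node_table <- validate_node_table(node_table)
  k <- stopifnot_scalar_count(k, "k")
  mean_matrix <- as.matrix(mean_matrix)
  n <- nrow(mean_matrix)
  if (n != nrow(node_table)) {
    abort("mean matrix and node table disagree on the number of nodes")
  }
  if (k > n) abort(sprintf("k (%d) exceeds the number of nodes (%d)", k, n))

  feats <- mean_matrix
  diag(feats) <- 0
  hc <- hclust(dist(feats, method = "euclidean"), method = "ward.D2")
  raw <- cutree(hc, k = k)
  # renumber by first appearance
  module <- match(raw, unique(raw)) - 1L
  new_partition(node_table, module)
}

#' Silhouette profile over candidate module counts
#'
#' Mean silhouette width of the Ward solution at each candidate `k`,
#' computed on the same row-feature Euclidean distances the clustering
#' uses. Guidance only — the pipeline never picks `k` automatically.
#'
#' @param mean_matrix Symmetric group-mean connectivity matrix.
#' @param ks Candidate module counts (each between 2 and n-1).
#' @return Tibble with `k` and `mean_silhouette`.
#' @export
silhouette_profile <- function(mean_matrix, ks = 2:12) {
  mean_matrix <- as.matrix(mean_matrix)
  feats <- mean_matrix
  diag(feats) <- 0
  d <- as.matrix(dist(feats, method = "euclidean"))
  n <- nrow(d)
  hc <- hclust(stats::as.dist(d), method = "ward.D2")
  purrr::map_dfr(ks[ks >= 2 & ks < n], function(k) {
    cl <- cutree(hc, k = k)
    sil <- vapply(seq_len(n), function(i) {
      own <- cl == cl[i]
      own[i] <- FALSE
      a <- if (any(own)) mean(d[i, own]) else 0
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(g) mean(d[i, cl == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    tibble(k = k, mean_silhouette = mean(sil))
  })
}
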