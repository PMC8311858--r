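# Shared fixtures and independent oracles, built in code at test time.

# Small bilateral node table: n nodes alternating L/R.
tiny_node_table <- function(n, hemispheres = rep(c("L", "R"), length.out = n)) {
  tibble::tibble(
    node_id = seq_len(n) - 1L,
    label = sprintf("n%02d", seq_len(n) - 1L),
    hemisphere = hemispheres
  )
}

# Partition tibble from an explicit membership vector.
tiny_partition <- function(membership, node_table = tiny_node_table(length(membership))) {
  dplyr::mutate(node_table, module = as.integer(membership))
}

# Seeded Erdos-Renyi adjacency matrix (symmetric, zero diagonal).
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(FALSE, n, n)
  a[upper.tri(a)] <- stats::runif(n * (n - 1) / 2) < p
  a | t(a)
}

# Brute-force participation coefficient: explicit per-node loop over
# modules, independent of the package's vectorized path.
pc_bruteforce <- function(adj, membership) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k == 0) return(0)
    s <- 0
    for (m in unique(membership)) {
      k_m <- sum(membership[nb] == m)
      s <- s + (k_m / k)^2
    }
    1 - s
  }, numeric(1))
}

# Top-m edge selection by full sort of the upper triangle — the oracle for
# proportional thresholding (value descending, then (i, j) lexicographic).
top_edges_oracle <- function(z, m) {
  n <- nrow(z)
  pairs <- which(upper.tri(z), arr.ind = TRUE)
  ord <- order(-z[upper.tri(z)], pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(m)], , drop = FALSE]
  keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
}

# Edge matrix (i < j, sorted) of an adjacency matrix, comparable with the
# sort oracle's output.
edge_matrix <- function(adj) {
  e <- which(adj & upper.tri(adj), arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- NULL
  e
}

# A small deterministic cohort for stats/pipeline tests (kept cheap).
small_cohort <- function(seed = 11, t_len = 80, n_hc = 6, n_per_group = 6, ...) {
  simulate_cohort(cohort_design(n_hc = n_hc, n_per_group = n_per_group,
                                t_len = t_len, seed = seed, ...))
}
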