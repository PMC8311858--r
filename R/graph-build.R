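# From ROI time series to Fisher-z connectivity matrices and proportional-
# threshold binary graphs.

#' Default proportional thresholds
#'
#' The six edge-retention proportions (top 5, 10, 20, 25, 30 and 40% of all
#' node pairs) over which network measures are averaged.
#' @export
default_thresholds <- function() c(0.05, 0.10, 0.20, 0.25, 0.30, 0.40)

#' Fisher z-transformed connectivity matrix
#'
#' Computes all pairwise Pearson correlations between ROI time courses and
#' applies the Fisher z transform (`atanh`). Values are capped at
#' `atanh(1 - 1e-7)` in magnitude so perfectly correlated signals cannot
#' produce infinities. The diagonal is stored as 0 and ignored by all
#' consumers.
#'
#' @param ts ROI-by-time numeric matrix (one row per ROI, at least 3
#'   columns); row names, if present, become node labels.
#' @return A symmetric n-by-n matrix of Fisher z values with zero diagonal.
#' @examples
#' ts <- matrix(rnorm(4 * 50), nrow = 4)
#' fisher_z_connectivity(ts)
#' @export
fisher_z_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) {
    abort("need at least 3 time points to estimate correlations")
  }
  sds <- sqrt(rowSums((ts - rowMeans(ts))^2) / (ncol(ts) - 1))
  if (any(sds == 0)) {
    which_bad <- which(sds == 0)
    bad <- if (is.null(rownames(ts))) paste0("row ", which_bad) else rownames(ts)[which_bad]
    abort(paste0("constant signal (undefined correlation) for ROI(s): ",
                 paste(bad, collapse = ", ")))
  }
  r <- cor(t(ts))
  cap <- 1 - 1e-7
  r <- pmin(pmax(r, -cap), cap)
  z <- atanh(r)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}

# Number of retained edges at proportion p for n nodes:
# round-half-away-from-zero of p * n(n-1)/2.
edge_count_at <- function(p, n) {
  as.integer(round_half_away(p * n * (n - 1) / 2))
}

#' Binarize a connectivity matrix at one proportional threshold
#'
#' Keeps exactly `round(p * n(n-1)/2)` undirected edges (rounding half away
#' from zero) with the largest signed z values and binarizes them; strongly
#' negative correlations are never among the "strongest connections". Ties
#' are broken by ascending `(i, j)` node-index order, making the edge set
#' deterministic even on degenerate inputs.
#'
#' @param z Symmetric connectivity matrix (see [fisher_z_connectivity()]).
#' @param p Edge-retention proportion in (0, 1].
#' @return A logical n-by-n adjacency matrix (symmetric, zero diagonal).
#' @examples
#' z <- fisher_z_connectivity(matrix(rnorm(5 * 60), nrow = 5))
#' adj <- proportional_threshold(z, 0.4)
#' sum(adj) / 2  # retained edges
#' @export
proportional_threshold <- function(z, p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p > 1) {
    abort("threshold proportion must be in (0, 1]")
  }
  z <- as.matrix(z)
  n <- nrow(z)
  ut <- upper.tri(z)
  idx <- which(ut, arr.ind = TRUE)
  vals <- z[ut]
  m <- edge_count_at(p, n)
  # Sort by value descending, then lexicographic (i, j) for ties.
  ord <- order(-vals, idx[, 1], idx[, 2])
  keep <- ord[seq_len(min(m, length(ord)))]

  adj <- matrix(FALSE, n, n, dimnames = dimnames(z))
  adj[idx[keep, , drop = FALSE]] <- TRUE
  adj | t(adj)
}

#' Binary graphs at a set of proportional thresholds
#'
#' Applies [proportional_threshold()] at each proportion, in the order
#' given. For a matrix with all-distinct values the graphs are nested:
#' every edge retained at a smaller proportion is retained at a larger one.
#'
#' @param z Symmetric connectivity matrix.
#' @param thresholds Proportions in (0, 1]; defaults to
#'   [default_thresholds()].
#' @return A `conn_graphs` object: a named list of logical adjacency
#'   matrices with a `thresholds` attribute.
#' @export
multi_threshold_graphs <- function(z, thresholds = default_thresholds()) {
  if (length(thresholds) == 0) abort("need at least one threshold")
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("threshold proportion must be in (0, 1]")
  }
  z <- as.matrix(z)
  n <- nrow(z)
  # One shared ranking serves every threshold: same value-then-(i,j) order
  # as proportional_threshold().
  ut <- upper.tri(z)
  idx <- which(ut, arr.ind = TRUE)
  vals <- z[ut]
  ord <- order(-vals, idx[, 1], idx[, 2])
  lin_upper <- (idx[, 2] - 1L) * n + idx[, 1]
  lin_lower <- (idx[, 1] - 1L) * n + idx[, 2]

  graphs <- lapply(thresholds, function(p) {
    m <- min(edge_count_at(p, n), length(ord))
    keep <- ord[seq_len(m)]
    adj <- matrix(FALSE, n, n, dimnames = dimnames(z))
    adj[lin_upper[keep]] <- TRUE
    adj[lin_lower[keep]] <- TRUE
    adj
  })
  names(graphs) <- format(thresholds, trim = TRUE)
  structure(graphs, thresholds = thresholds, class = "conn_graphs")
}

#' @export
print.conn_graphs <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("<conn_graphs> %d graphs over %d nodes at thresholds %s\n",
              length(x), nrow(x[[1]]), paste(th, collapse = ", ")))
  invisible(x)
}

#' Edge list of a binary graph
#'
#' @param adj Logical adjacency matrix.
#' @return Tibble with 0-based `from`, `to` (from < to) and labels if the
#'   matrix carries dimnames.
#' @export
graph_edges <- function(adj) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  out <- tibble(from = as.integer(idx[, 1]) - 1L,
                to = as.integer(idx[, 2]) - 1L)
  if (!is.null(rownames(adj))) {
    out$from_label <- rownames(adj)[idx[, 1]]
    out$to_label <- rownames(adj)[idx[, 2]]
  }
  arrange(out, .data$from, .data$to)
}
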