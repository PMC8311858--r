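# Shared numeric helpers.

# Round half away from zero. base::round() rounds half to even, which would
# drop an edge at e.g. p = 0.05 on 76 nodes (142.5 pairs -> 142); the
# documented edge-count rule is half-away-from-zero.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' here to score recovery of planted modules by the reference-clustering
#' step. 1 means identical partitions up to relabeling; 0 is the expected
#' agreement of independent random partitions.
#'
#' @param a,b Vectors of cluster labels (any type coercible to factor),
#'   equal length.
#' @return A single number in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    abort("partitions must label the same items (lengths differ)")
  }
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Nearest-PSD repair: clip eigenvalues below `floor`, re-symmetrize, rescale
# to unit diagonal. Errors if any entry moves by more than `max_drift`, so a
# repair can never silently erase a planted contrast.
repair_psd <- function(mat, floor = 1e-8, max_drift = 0.05) {
  mat <- (mat + t(mat)) / 2
  ch <- tryCatch(chol(mat), error = function(e) NULL)
  if (!is.null(ch)) {
    return(list(cov = mat, chol = ch, drift = 0))
  }
  eg <- eigen(mat, symmetric = TRUE)
  vals <- pmax(eg$values, floor)
  rep_mat <- eg$vectors %*% (vals * t(eg$vectors))
  rep_mat <- (rep_mat + t(rep_mat)) / 2
  d <- sqrt(diag(rep_mat))
  rep_mat <- rep_mat / tcrossprod(d)
  diag(rep_mat) <- 1
  drift <- max(abs(rep_mat - mat))
  if (drift > max_drift) {
    abort(sprintf(
      "covariance is too far from positive semi-definite: PSD repair moved an entry by %.4f (bound %.4f)",
      drift, max_drift
    ))
  }
  list(cov = rep_mat, chol = chol(rep_mat + diag(1e-10, nrow(rep_mat))), drift = drift)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != as.integer(x) || x < 1) {
    abort(sprintf("`%s` must be a single positive integer", name))
  }
  as.integer(x)
}
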