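# Downstream analysis of the cell embedding: neighbor-graph community
# clustering and the evaluation statistics (ARI, Kendall tau-b, pseudo-bulk
# Pearson correlation).

#' Cluster cells in the latent space
#'
#' Builds a k-nearest-neighbor graph on Euclidean distances between rows of
#' the embedding and partitions it with the Leiden algorithm (modularity
#' objective) at the given resolution. The graph is the union of directed
#' kNN relations, unweighted.
#'
#' @param Z n x d embedding matrix.
#' @param n_neighbors neighbors per cell (default 15).
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed integer; community detection is seeded and deterministic.
#' @return Integer vector of n cluster labels, 0-based and contiguous.
#' @export
cluster_embedding <- function(Z, n_neighbors = 15, resolution = 1, seed = 0) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n_neighbors >= n)
    stop("n_neighbors (", n_neighbors, ") must be smaller than the number of cells (",
         n, ")")
  D <- as.matrix(stats::dist(Z))
  nbr <- t(apply(D, 1, function(r) order(r)[2:(n_neighbors + 1)]))
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nbr)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  labels <- .with_local_seed(seed, function() {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 5))
  })
  as.integer(factor(labels)) - 1L
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model;
#' 1 exactly when the partitions are identical up to label renaming, about
#' 0 for independent labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("adjusted_rand_index: label vectors have different lengths")
  n <- length(a)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)   # both partitions trivial / identical
  (sum_ij - expected) / (max_idx - expected)
}

#' Tie-aware Kendall rank correlation (tau-b)
#'
#' Concordant-minus-discordant pair count normalized by the geometric mean
#' of tie-corrected pair totals. Ties are expected: developmental stage
#' labels are discrete. Quadratic in n (vectorized sign comparison),
#' adequate for the tens of thousands of cells this package targets.
#'
#' @param order_a,order_b numeric vectors of equal length (orderings,
#'   pseudotimes, or stage codes).
#' @return Scalar in `[-1, 1]`; `NA` if either vector is constant.
#' @export
kendall_tau <- function(order_a, order_b) {
  if (length(order_a) != length(order_b))
    stop("kendall_tau: input vectors have different lengths")
  n <- length(order_a)
  sa <- sign(outer(order_a, order_a, "-"))
  sb <- sign(outer(order_b, order_b, "-"))
  up <- upper.tri(sa)
  s <- sum(sa[up] * sb[up])
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(x) {
    t <- table(x)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_pairs(order_a)
  n2 <- tie_pairs(order_b)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) return(NA_real_)
  s / denom
}

#' Pseudo-bulk Pearson correlation against a reference profile
#'
#' Pools cells of each labeled group into a pseudo-bulk profile (mean over
#' cells) restricted to a marker feature set, then correlates each group's
#' profile with the matching row of a bulk reference. Pearson correlation
#' over a fixed marker set is insensitive to any global per-group scale, so
#' mean versus sum pooling does not change the statistic.
#'
#' @param X_expr n x p expression matrix (normalized scale recommended).
#' @param labels n group assignments; every group must appear in the
#'   reference rownames.
#' @param reference group x p matrix with rownames naming the groups.
#' @param marker_idx integer or character index of marker features (>= 3
#'   recommended).
#' @return Named numeric vector: Pearson r per group.
#' @export
pseudobulk_correlation <- function(X_expr, labels, reference, marker_idx) {
  X_expr <- .as_dense(X_expr)
  if (length(labels) != nrow(X_expr))
    stop("pseudobulk_correlation: labels length != number of cells")
  groups <- unique(as.character(labels))
  missing_g <- setdiff(groups, rownames(reference))
  if (length(missing_g) > 0)
    stop("groups missing from reference: ", paste(missing_g, collapse = ", "))
  if (is.numeric(marker_idx) && any(marker_idx > ncol(X_expr)))
    stop("marker_idx out of range")
  out <- vapply(groups, function(g) {
    pb <- colMeans(X_expr[as.character(labels) == g, marker_idx, drop = FALSE])
    stats::cor(pb, as.numeric(reference[g, marker_idx]))
  }, numeric(1))
  names(out) <- groups
  out
}

#' Assemble an evaluation report for an embedding
#'
#' Convenience wrapper computing the statistics this package uses to score
#' an embedding against reference annotations: clustering ARI, optional
#' Kendall tau-b of a pseudotime against stage labels, and optional
#' pseudo-bulk correlations.
#'
#' @param Z n x d embedding.
#' @param labels reference annotations (ground truth).
#' @param n_neighbors,resolution,seed passed to [cluster_embedding].
#' @param pseudotime,stages optional equal-length numeric vectors for
#'   trajectory evaluation.
#' @param X_expr,reference,marker_idx optional inputs for
#'   [pseudobulk_correlation].
#' @return List of class `eval_report`: `ari`, `n_clusters_found`,
#'   `kendall_tau` (or NULL), `group_correlations` (or NULL).
#' @export
eval_report <- function(Z, labels, n_neighbors = 15, resolution = 1, seed = 0,
                        pseudotime = NULL, stages = NULL, X_expr = NULL,
                        reference = NULL, marker_idx = NULL) {
  cl <- cluster_embedding(Z, n_neighbors = n_neighbors,
                          resolution = resolution, seed = seed)
  rep <- list(ari = adjusted_rand_index(cl, labels),
              n_clusters_found = length(unique(cl)),
              kendall_tau = NULL, group_correlations = NULL)
  if (!is.null(pseudotime) && !is.null(stages))
    rep$kendall_tau <- kendall_tau(pseudotime, stages)
  if (!is.null(X_expr) && !is.null(reference) && !is.null(marker_idx))
    rep$group_correlations <- pseudobulk_correlation(X_expr, labels,
                                                     reference, marker_idx)
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: ARI %.3f over %d clusters", x$ari,
              x$n_clusters_found))
  if (!is.null(x$kendall_tau)) cat(sprintf("; Kendall tau-b %.3f", x$kendall_tau))
  if (!is.null(x$group_correlations))
    cat(sprintf("; mean pseudo-bulk r %.3f", mean(x$group_correlations)))
  cat("\n")
  invisible(x)
}
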