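# Clustering of the embedding and the evaluation statistics.

test_that("cluster_embedding separates distant clouds and keeps identical
          points together", {
  set.seed(1)
  Z <- rbind(matrix(rnorm(100), ncol = 2),
             matrix(rnorm(100) + 100, ncol = 2))
  truth <- rep(0:1, each = 50)
  cl <- cluster_embedding(Z, n_neighbors = 10, resolution = 0.1, seed = 1)
  expect_identical(length(unique(cl)), 2L)
  expect_identical(adjusted_rand_index(cl, truth), 1)
  expect_identical(sort(unique(cl)), 0:1)  # labels contiguous, 0-based
  cl1 <- cluster_embedding(matrix(1, 30, 3), n_neighbors = 5, seed = 1)
  expect_identical(length(unique(cl1)), 1L)
  expect_error(cluster_embedding(Z, n_neighbors = 100), "smaller")
})

test_that("cluster_embedding is invariant to row permutation of Z", {
  set.seed(4)
  Z <- rbind(matrix(rnorm(80), ncol = 2),
             matrix(rnorm(80) + 8, ncol = 2),
             matrix(rnorm(80) - 8, ncol = 2))
  cl <- cluster_embedding(Z, n_neighbors = 10, resolution = 0.2, seed = 2)
  perm <- sample(nrow(Z))
  clp <- cluster_embedding(Z[perm, ], n_neighbors = 10, resolution = 0.2,
                           seed = 2)
  expect_identical(adjusted_rand_index(clp, cl[perm]), 1)
})

test_that("adjusted_rand_index matches brute-force pair counting and its
          invariances", {
  a <- rep(1:3, times = c(2, 2, 2))
  expect_identical(adjusted_rand_index(a, a), 1)
  expect_identical(adjusted_rand_index(1:10, rep(1, 10)), 0)
  # contingency {{2,1},{1,2}} over n = 6
  b <- c(1, 1, 2, 1, 2, 2)
  a2 <- rep(1:2, each = 3)
  expect_equal(adjusted_rand_index(a2, b), brute_ari(a2, b))
  set.seed(9)
  for (rep_i in 1:20) {
    n <- sample(4:12, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), brute_ari(x, y))
    expect_equal(adjusted_rand_index(y, x), adjusted_rand_index(x, y))
    # invariance to label permutation
    relab <- sample(10)[x]
    expect_equal(adjusted_rand_index(relab, y), adjusted_rand_index(x, y))
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "lengths")
})

test_that("kendall_tau is an exact tie-aware tau-b", {
  expect_identical(kendall_tau(1:5, 1:5), 1)
  expect_identical(kendall_tau(1:5, 5:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  set.seed(10)
  for (rep_i in 1:20) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE)     # heavy ties, like stage labels
    y <- rnorm(n)
    expect_equal(kendall_tau(x, y), brute_tau_b(x, y))
  }
  expect_true(is.na(kendall_tau(rep(1, 4), 1:4)))
  expect_error(kendall_tau(1:3, 1:4), "lengths")
})

test_that("pseudobulk_correlation reproduces a two-pass oracle", {
  set.seed(30)
  n <- 200
  p <- 25
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("g", 1:p)
  labels <- sample(c("A", "B"), n, replace = TRUE)
  markers <- sample(p, 10)
  # reference equal to the pseudo-bulk itself -> r = 1 everywhere
  ref <- rbind(A = colMeans(X[labels == "A", ]),
               B = colMeans(X[labels == "B", ]))
  r <- pseudobulk_correlation(X, labels, ref, markers)
  expect_equal(unname(r[c("A", "B")]), c(1, 1))
  # perturb one marker of group A only
  ref2 <- ref
  ref2["A", markers[1]] <- ref2["A", markers[1]] + 5
  r2 <- pseudobulk_correlation(X, labels, ref2, markers)
  expect_lt(r2[["A"]], 1)
  expect_equal(r2[["B"]], 1)
  # independent mean-then-correlate computation
  oracle <- sapply(c("A", "B"), function(g) {
    pb <- apply(X[labels == g, markers], 2, mean)
    cor(pb, ref2[g, markers])
  })
  expect_equal(r2[names(oracle)], oracle)
  expect_error(pseudobulk_correlation(X, c(labels[-1], "C"), ref, markers),
               "missing from reference: C")
  expect_error(pseudobulk_correlation(X, labels, ref, c(1, 99)), "range")
})

test_that("eval_report assembles the statistics it is given", {
  set.seed(5)
  Z <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60) + 20, ncol = 2))
  labels <- rep(c("a", "b"), each = 30)
  rep_ <- eval_report(Z, labels, n_neighbors = 8, resolution = 0.1, seed = 1,
                      pseudotime = seq_len(60), stages = rep(1:2, each = 30))
  expect_identical(rep_$ari, 1)
  expect_identical(rep_$n_clusters_found, 2L)
  # perfect cross-group concordance with within-group ties: C = 900 of the
  # n0 = 1770 pairs, 870 tied in the stage vector -> tau-b = sqrt(900/1770)
  expect_equal(rep_$kendall_tau, sqrt(900 / 1770))
})
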