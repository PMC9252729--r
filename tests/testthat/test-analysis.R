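same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

test_that("normalization post-conditions are exact and idempotent", {
  tbl <- feature_tbl(matrix(c(1, 2, 3, 5, 5, 5), 3), c("a", "b", "c"))
  mm <- feat_mat(normalize_features(tbl, "minmax"))
  expect_equal(unname(mm[, 1]), c(0, 0.5, 1))
  expect_equal(unname(mm[, 2]), c(0, 0, 0))  # constant column -> zeros

  zs <- feat_mat(normalize_features(tbl, "zscore"))
  expect_equal(unname(zs[, 1]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(unname(zs[, 2]), c(0, 0, 0))

  big <- blob_tbl()
  for (meth in c("zscore", "minmax")) {
    once <- normalize_features(big, meth)
    twice <- normalize_features(once, meth)
    expect_lt(max(abs(feat_mat(once) - feat_mat(twice))), 1e-9)
  }
  z <- feat_mat(normalize_features(big, "zscore"))
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, function(c) sqrt(mean((c - mean(c))^2))) - 1)), 1e-9)
  expect_error(normalize_features(big[0, ], "zscore"), "empty|samples")
})

test_that("every clustering algorithm separates two clear blobs or obeys its contract", {
  tbl <- blob_tbl()
  truth <- rep(1:2, each = 10)
  for (alg in c("kmeans", "minibatch_kmeans", "gaussian_mixture",
                "hierarchical_agglomerative", "spectral", "markov_clustering",
                "affinity_propagation", "mean_shift")) {
    fit <- cluster_features(tbl, alg, k = 2, seed = 3)
    expect_true(same_partition(tidy(fit)$cluster, truth),
                label = paste("blob recovery:", alg))
  }
  # dbscan: eps below every pairwise distance -> all noise
  noise <- cluster_features(tbl, "dbscan", seed = 1, eps = 1e-6, min_pts = 2)
  expect_true(all(tidy(noise)$cluster == -1))
  # with a workable eps it also finds the two blobs
  ok <- cluster_features(tbl, "dbscan", seed = 1, eps = 4, min_pts = 3)
  expect_true(same_partition(tidy(ok)$cluster, truth))
  # height-cut hierarchical clustering respects its h parameter
  hcut <- cluster_features(tbl, "hclust_tree_cut", seed = 1, h = 1e6)
  expect_equal(length(unique(tidy(hcut)$cluster)), 1)
  expect_error(cluster_features(tbl, "kmeans", k = 99), "k larger")
  expect_error(cluster_features(tbl, "fuzzy_cmeans"), "unknown")
})

test_that("markov clustering resolves disconnected similarity components", {
  set.seed(9)
  m <- rbind(matrix(stats::rnorm(12, 0, 0.1), 4), matrix(stats::rnorm(12, 50, 0.1), 4))
  tbl <- feature_tbl(m, letters[1:8])
  fit <- cluster_features(tbl, "markov_clustering", seed = 2)
  cl <- tidy(fit)$cluster
  expect_equal(length(unique(cl)), 2)
  expect_true(same_partition(cl, rep(1:2, each = 4)))
})

test_that("cluster and reduction runs are reproducible for a fixed seed", {
  tbl <- blob_tbl(7)
  for (alg in c("kmeans", "minibatch_kmeans", "gaussian_mixture", "spectral")) {
    a <- cluster_features(tbl, alg, k = 2, seed = 11)
    b <- cluster_features(tbl, alg, k = 2, seed = 11)
    expect_identical(tidy(a), tidy(b), label = alg)
  }
  for (alg in c("pca", "tsne")) {
    a <- reduce_features(tbl, alg, 2, seed = 11)
    b <- reduce_features(tbl, alg, 2, seed = 11)
    expect_identical(a$coords, b$coords, label = alg)
  }
})

test_that("PCA matches an independent covariance eigendecomposition up to sign", {
  set.seed(5)
  m <- matrix(stats::rnorm(20), 5, 4)
  tbl <- feature_tbl(m, letters[1:5])
  fit <- reduce_features(tbl, "pca", 3, seed = 1)
  cov <- stats::cov(scale(m, center = TRUE, scale = FALSE)) * (4 / 4)
  eig <- eigen(stats::cov(m))
  centered <- scale(m, center = TRUE, scale = FALSE)
  for (j in 1:3) {
    proj <- centered %*% eig$vectors[, j]
    same <- max(abs(fit$coords[, j] - proj))
    flipped <- max(abs(fit$coords[, j] + proj))
    expect_lt(min(same, flipped), 1e-9)
  }
  expect_true(all(diff(fit$explained) <= 1e-12))
  expect_lte(sum(fit$explained), 1 + 1e-12)

  # collinear points: first component carries all variance
  lin <- feature_tbl(cbind(1:6, 2 * (1:6)), letters[1:6])
  f2 <- reduce_features(lin, "pca", 2)
  expect_equal(f2$explained[1], 1, tolerance = 1e-9)
})

test_that("LDA needs labels and respects the component bound", {
  tbl <- blob_tbl()
  fit <- reduce_features(tbl, "lda", 1, seed = 1)
  expect_equal(ncol(fit$coords), 1)
  # embedding separates the labelled groups
  sc <- tidy(fit)
  expect_true(max(sc$LDA1[sc$label == "a"]) < min(sc$LDA1[sc$label == "b"]) ||
                min(sc$LDA1[sc$label == "a"]) > max(sc$LDA1[sc$label == "b"]))
  expect_error(reduce_features(tbl, "lda", 2), "classes - 1")
  unlab <- feature_tbl(feat_mat(tbl), tbl$id)
  expect_error(reduce_features(unlab, "lda", 1), "label")
  expect_error(reduce_features(tbl, "pca", 99), "exceeds")
})

test_that("tidy/glance summaries carry the fitted metadata", {
  tbl <- blob_tbl()
  fit <- cluster_features(tbl, "kmeans", k = 2, seed = 4)
  td <- tidy(fit)
  expect_equal(names(td), c("id", "cluster"))
  expect_equal(sort(unique(td$cluster)), 1:2)
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 2)
  expect_equal(gl$method, "kmeans")
  red <- reduce_features(tbl, "pca", 2, seed = 4)
  expect_equal(nrow(tidy(red)), 20)
  expect_equal(glance(red)$n_components, 2)
})
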