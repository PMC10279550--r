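# k-means, embeddings, validity indices (with brute-force oracles), votes.

test_that("k-means handles the exact edge cases", {
  X <- make_blobs(rbind(c(0, 0), c(100, 100)), n_per = 10, sd = 1, seed = 1)
  sol <- kmeans_assign(X, 2, seed = 3)
  expect_equal(adjusted_rand_index(sol$labels, attr(X, "truth")), 1.0)
  # k = n: zero within-cluster SS
  sol_n <- kmeans_assign(X, nrow(X), seed = 3)
  expect_equal(sol_n$wss, 0)
  # k = 1: SS around the grand centroid
  sol_1 <- kmeans_assign(X, 1, seed = 3)
  expect_equal(sol_1$wss, sum(sweep(X, 2, colMeans(X))^2))
  expect_error(kmeans_assign(X, nrow(X) + 1, seed = 1), "exceed")
})

test_that("k-means labels are canonical and runs are seeded", {
  X <- make_blobs(rbind(c(0, 0), c(10, 0), c(0, 10)), n_per = c(5),
                  sd = 0.3, seed = 2)
  a <- kmeans_assign(X, 3, seed = 9)
  b <- kmeans_assign(X, 3, seed = 9)
  expect_identical(a$labels, b$labels)
  # canonical numbering: cluster sizes non-increasing
  expect_true(!is.unsorted(rev(as.integer(table(a$labels)))))
  # within-SS comparable to stats::kmeans on the same data
  km <- stats::kmeans(X, 3, nstart = 25)
  expect_equal(a$wss, km$tot.withinss, tolerance = 1e-6)
})

test_that("embedding contracts hold for none and pca", {
  X <- make_blobs(rbind(c(0, 0, 0), c(5, 5, 5)), n_per = 10, sd = 1, seed = 4)
  expect_equal(embed(X, embed_config("none")), X)
  # exact rank-2 case: 2-component PCA reconstructs projected data
  B <- matrix(rnorm(30 * 2), 30) %*% matrix(rnorm(2 * 6), 2)
  sc <- embed(B, embed_config("pca", n_components = 2))
  rec <- sc %*% t(attr(sc, "rotation"))
  Bc <- sweep(B, 2, colMeans(B))
  expect_lt(max(abs(rec - Bc)), 1e-8)
  # the two eigendecomposition routes agree
  wide <- cbind(B, matrix(rnorm(30 * 40, 0, 0.01), 30))
  sc_w <- embed(wide, embed_config("pca", n_components = 2))
  pr <- prcomp(wide)
  expect_equal(abs(matrix(sc_w, nrow(sc_w))), abs(unname(pr$x[, 1:2])),
               tolerance = 1e-6)
  expect_error(embed(X[1:2, ], embed_config("pca")), "observations")
})

test_that("umap embedding is deterministic under a fixed seed", {
  skip_if_not(protraj:::.umap_available())
  X <- make_blobs(rbind(c(0, 0, 0), c(8, 8, 8)), n_per = 25, sd = 1, seed = 5)
  cfg <- embed_config("umap", n_neighbors = 10, seed = 42)
  e1 <- embed(X, cfg)
  e2 <- embed(X, cfg)
  expect_equal(e1, e2)
  expect_equal(dim(e1), c(50L, 2L))
  expect_error(embed(X, embed_config("umap", n_neighbors = 100)),
               "n_neighbors")
})

test_that("Calinski-Harabasz and silhouette match hand-computed values", {
  # 1-D points {0, 0.1 | 10, 10.1}: CH = (100/1)/(0.01/2) = 20000
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1L, 1L, 2L, 2L)
  expect_equal(protraj:::.index_ch(X, lab), 20000)
  # mean silhouette from the a/b definition: the outer points see the
  # neighbour cluster at mean distance 10.05, the inner points at 9.95
  D <- as.matrix(dist(X))
  sil_hand <- mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                     (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05))
  expect_equal(protraj:::.index_silhouette(D, lab), sil_hand,
               tolerance = 1e-9)
  expect_equal(protraj:::.index_silhouette(D, lab), oracle_silhouette(D, lab),
               tolerance = 1e-12)
})

test_that("degenerate partitions follow the stated conventions", {
  X <- matrix(0, 6, 2)
  lab <- rep(1:2, each = 3)
  D <- as.matrix(dist(X))
  expect_equal(protraj:::.index_silhouette(D, lab), 0)
  expect_true(is.na(protraj:::.index_db(X, lab)))
  expect_true(is.na(protraj:::.index_dunn(D, lab)))
})

test_that("all seven indices match brute-force oracles on random instances", {
  set.seed(2024)
  for (r in 1:20) {
    n <- sample(10:30, 1)
    d <- sample(2:3, 1)
    X <- matrix(rnorm(n * d), n)
    rownames(X) <- sprintf("r%02d", seq_len(n))
    k <- sample(2:4, 1)
    sols <- lapply(2:(k + 1), function(kk) kmeans_assign(X, kk, seed = r))
    names(sols) <- 2:(k + 1)
    vi <- validity_indices(X, sols, k_range = 2:k, gap_B = 5,
                           seed = r, keep_refs = TRUE)
    D <- as.matrix(dist(X))
    for (kk in 2:k) {
      lab <- unname(sols[[as.character(kk)]]$labels)
      col <- as.character(kk)
      expect_equal(vi$values["silhouette", col], oracle_silhouette(D, lab),
                   tolerance = 1e-9)
      expect_equal(vi$values["calinski_harabasz", col], oracle_ch(X, lab),
                   tolerance = 1e-9)
      if (!is.na(vi$values["davies_bouldin", col]))
        expect_equal(vi$values["davies_bouldin", col], oracle_db(X, lab),
                     tolerance = 1e-9)
      expect_equal(vi$values["dunn", col], oracle_dunn(D, lab),
                   tolerance = 1e-9)
      expect_equal(vi$values["c_index", col], oracle_cindex(D, lab),
                   tolerance = 1e-9)
      expect_equal(vi$values["hartigan", col],
                   unname(oracle_hartigan(vi$wss[col],
                                          vi$wss[as.character(kk + 1)],
                                          n, kk)), tolerance = 1e-9)
      expect_equal(vi$values["gap", col],
                   unname(oracle_gap(vi$gap_detail$logW_ref[, col],
                                     vi$wss[col])), tolerance = 1e-9)
      expect_equal(unname(vi$gap_se[col]),
                   oracle_gap_se(vi$gap_detail$logW_ref[, col]),
                   tolerance = 1e-9)
    }
  }
})

test_that("vote follows majority with ties toward smaller k", {
  expect_equal(vote(c(4, 4, 4, 2, 3, 4, 4)), 4)
  expect_equal(vote(c(2, 2, 3, 3)), 2)
  expect_equal(vote(c(5)), 5)
  expect_equal(vote(c(NA, 3, NA)), 3)
  expect_error(vote(c(NA_integer_, NA_integer_)), "failed")
})

test_that("index votes pick the planted k on well-separated blobs", {
  X <- make_blobs(rbind(c(0, 0), c(12, 0), c(0, 12), c(12, 12)),
                  n_per = 15, sd = 0.5, seed = 6)
  sols <- lapply(2:9, function(k) kmeans_assign(X, k, seed = k))
  names(sols) <- 2:9
  vi <- validity_indices(X, sols, k_range = 2:8, seed = 1)
  expect_equal(vote(vi$votes), 4)
})
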