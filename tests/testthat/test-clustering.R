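test_that("log-normalization is exact and depth-invariant", {
  cnt <- tiny_matrix(matrix(c(1, 9999, 2, 19998), 2, 2))
  norm <- log_normalize(cnt, scale_factor = 10000)
  expect_equal(norm[1, 1], log(2))            # 1/10000 * 1e4 -> ln(1 + 1)
  # proportional columns map to identical columns
  expect_equal(unname(norm[, 1]), unname(norm[, 2]))
  z <- tiny_matrix(matrix(c(0, 5, 0, 0), 2, 2))
  expect_error(log_normalize(z), "zero total")
  expect_equal(log_normalize(tiny_matrix(matrix(c(0, 5), 2, 1)))[1, 1], 0)
})

test_that("PCA embedding matches a brute-force eigendecomposition", {
  set.seed(6)
  x <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:10)))
  norm <- expr_mat(abs(x), "lognorm")
  cfg <- clustering_config(n_pcs = 4)
  emb <- pca_embed(norm, cfg)
  # oracle: standardize + clip, then eigenvectors of the cell covariance
  z <- t(scale(t(abs(x))))
  z[z > 10] <- 10; z[z < -10] <- -10
  zc <- scale(t(z), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(zc) / (nrow(zc) - 1))
  want <- zc %*% ev$vectors[, 1:4]
  for (j in 1:4) {
    # sign convention: largest-|loading| positive
    v <- ev$vectors[, j]
    s <- sign(v[which.max(abs(v))])
    expect_equal(unname(emb[, j]), unname(want[, j] * s), tolerance = 1e-8)
  }
})

test_that("rank-1 structure loads PC1 and duplicated cells embed identically", {
  set.seed(2)
  # rank-1 structure: every gene follows the same cell-direction signal
  s <- seq_len(40) / 10
  base <- outer(runif(30, 0.5, 2), s) +
    matrix(rnorm(30 * 40, 0, 1e-3), 30, 40)
  norm <- tiny_matrix(abs(base), "lognorm",
                      genes = sprintf("g%02d", 1:30),
                      cells = sprintf("c%02d", 1:40))
  emb <- pca_embed(norm, clustering_config(n_pcs = 3))
  v <- apply(emb, 2, var)
  expect_gt(v[1] / sum(v), 0.99)
  # duplicated cell columns -> identical embedding rows
  dup <- ncembryo:::.as_plain(norm)
  dup <- cbind(dup, dup[, 1, drop = FALSE])
  colnames(dup) <- c(colnames(norm), "dup1")
  emb2 <- pca_embed(expr_mat(dup, "lognorm"), clustering_config(n_pcs = 3))
  expect_equal(unname(emb2["dup1", ]), unname(emb2["c01", ]),
               tolerance = 1e-9)
})

test_that("well-separated blobs are recovered exactly and deterministically", {
  set.seed(3)
  emb <- rbind(matrix(rnorm(100 * 5), 100, 5),
               matrix(rnorm(100 * 5, mean = 20), 100, 5))
  rownames(emb) <- sprintf("c%03d", 1:200)
  cfg <- clustering_config(seed = 3)
  lab <- cluster_cells(emb, cfg)
  expect_equal(length(unique(lab)), 2)
  expect_equal(mclust::adjustedRandIndex(lab, rep(0:1, each = 100)), 1)
  expect_identical(lab, cluster_cells(emb, cfg))
  # labels are 0..K-1 ordered by decreasing size
  expect_equal(sort(unique(unname(lab))), 0:1)
  # permuting cell order permutes labels consistently (same partition)
  perm <- sample(nrow(emb))
  lab_p <- cluster_cells(emb[perm, ], cfg)
  expect_equal(mclust::adjustedRandIndex(lab_p[names(lab)], lab), 1)
})

test_that("degenerate embeddings collapse to one cluster", {
  emb <- matrix(1, 50, 3, dimnames = list(sprintf("c%02d", 1:50), NULL))
  lab <- cluster_cells(emb, clustering_config(knn_k = 10, seed = 1))
  expect_equal(length(unique(lab)), 1)
  expect_error(cluster_cells(emb[1:5, ], clustering_config(knn_k = 10)),
               "smaller k")
})

test_that("partition comparison reports contingency, ARI and dispersion", {
  a <- setNames(rep(c(0, 1, 2), c(10, 10, 10)), sprintf("c%02d", 1:30))
  cmp_id <- compare_partitions(a, a)
  expect_equal(cmp_id$ari, 1)
  expect_true(all(cmp_id$dispersion == 1))
  # splitting one cluster of A evenly into 5 clusters of B -> dispersion 5
  b <- a
  b[a == 0] <- 10 + rep(1:5, each = 2)
  cmp <- compare_partitions(a, b)
  expect_equal(unname(cmp$dispersion[names(cmp$dispersion) == "0"]), 5)
  expect_equal(unname(rowSums(cmp$contingency)), c(10, 10, 10))
  expect_error(compare_partitions(a, a[1:10]), "same cell set")
})

test_that("2-D embedding is shaped, finite and seeded", {
  skip_if_not_installed("uwot")
  set.seed(5)
  emb <- matrix(rnorm(60 * 4), 60, 4,
                dimnames = list(sprintf("c%02d", 1:60), NULL))
  u1 <- embed_2d(emb, seed = 7)
  u2 <- embed_2d(emb, seed = 7)
  expect_equal(dim(u1), c(60, 2))
  expect_true(all(is.finite(u1)))
  expect_equal(u1, u2)
  expect_error(embed_2d(emb[1:5, ]), "at least 10")
})

test_that("ncRNA-only clustering isolates the planted ncRNA-defined type", {
  sim <- simulate_embryo(sim_config(n_cells = 600, seed = 5))
  cc <- clustering_config(seed = 5)
  lab_nc <- run_feature_set_clustering(sim$counts, sim$genes, "ncrna", cc)
  lab_cod <- run_feature_set_clustering(sim$counts, sim$genes, "coding", cc)
  is_muscle <- setNames(sim$truth$cells$type == "muscle",
                        sim$truth$cells$cell_id)
  # ncRNA features: the muscle cells dominate (>= 90%) one cluster
  tab_nc <- table(lab_nc[names(is_muscle)], is_muscle)
  purity <- max(tab_nc[, "TRUE"] / rowSums(tab_nc))
  expect_gte(purity, 0.9)
  # coding features: the same cells scatter over >= 2 clusters
  tab_cod <- table(lab_cod[names(is_muscle)], is_muscle)
  expect_gte(sum(tab_cod[, "TRUE"] > 0), 2)
  expect_lt(max(tab_cod[, "TRUE"] / rowSums(tab_cod)), 0.5)
})

test_that("without informative ncRNAs combined and coding clusterings agree", {
  # a synchronized population (narrow time window) whose only structure is
  # discrete cell type, with no ncRNA markers, no ncRNA-defined type and no
  # hubs: ncRNA features are pure noise, so the combined clustering must
  # match the coding-only one
  ct <- default_cell_types()[1:5, ]
  ct$proportion <- ct$proportion / sum(ct$proportion)
  sim <- simulate_embryo(sim_config(
    n_cells = 500, seed = 4, cell_types = ct, ncrna_only_type = NULL,
    ncrna_marker_fraction = 0, n_hubs_pos = 0, n_hubs_neg = 0,
    time_range_min = c(400, 430),
    bulk_timepoints_min = c(390, 400, 410, 420, 430, 440)))
  cc <- clustering_config(seed = 4)
  la <- run_feature_set_clustering(sim$counts, sim$genes, "combined", cc)
  lb <- run_feature_set_clustering(sim$counts, sim$genes, "coding", cc)
  expect_gte(compare_partitions(la, lb)$ari, 0.9)
})

test_that("an annotation without ncRNAs cannot feed ncRNA clustering", {
  set.seed(1)
  cnt <- tiny_matrix(matrix(rpois(40, 5) + 1, 4, 10),
                     genes = sprintf("g%d", 1:4),
                     cells = sprintf("c%02d", 1:10))
  genes <- gene_records(sprintf("g%d", 1:4), rep("protein_coding", 4))
  expect_error(run_feature_set_clustering(cnt, genes, "ncrna"),
               "empty feature subset")
})
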