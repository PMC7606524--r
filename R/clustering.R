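#' Clustering configuration
#'
#' @param scale_factor depth-normalization scale factor (10,000).
#' @param n_pcs number of principal components kept (20).
#' @param resolution modularity resolution of the community detection (1.0).
#' @param clip_value symmetric clip applied to standardized expression before
#'   PCA (10).
#' @param knn_k neighbors used for the shared-nearest-neighbor graph (20).
#' @param seed RNG seed for the graph clustering and 2-D embedding.
#' @return a `clustering_config` list.
#' @export
clustering_config <- function(scale_factor = 10000, n_pcs = 20,
                              resolution = 1.0, clip_value = 10,
                              knn_k = 20, seed = 1) {
  if (n_pcs < 2) stop("n_pcs must be >= 2")
  if (resolution <= 0) stop("resolution must be > 0")
  structure(as.list(environment()), class = "clustering_config")
}

#' Depth normalization with natural-log transform
#'
#' Per cell: `ln(1 + scale_factor * count / total_counts)`. Proportional
#' columns map to identical columns, so the transform is invariant to
#' sequencing depth.
#'
#' @param counts an [expr_mat()] of kind `counts`.
#' @param scale_factor scale factor (10,000 by default).
#' @return an [expr_mat()] of kind `lognorm`.
#' @export
log_normalize <- function(counts, scale_factor = 10000) {
  .check_kind(counts, "counts")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(counts)[tot == 0], 5), collapse = ", "))
  }
  out <- log1p(sweep(.as_plain(counts), 2, tot / scale_factor, `/`))
  expr_mat(out, "lognorm")
}

#' PCA embedding of cells
#'
#' Genes are standardized across cells (zero mean, unit variance;
#' zero-variance genes dropped), standardized values are clipped at
#' `+/- clip_value`, and cells are projected onto the top `n_pcs` principal
#' components. The sign of each component is fixed by making its
#' largest-magnitude gene loading positive, so embeddings are reproducible
#' across platforms.
#'
#' @param norm an [expr_mat()] of kind `lognorm` (or `log2tpm`).
#' @param config a [clustering_config()].
#' @return cells x n_pcs coordinate matrix.
#' @export
pca_embed <- function(norm, config = clustering_config()) {
  .check_kind(norm, c("lognorm", "log2tpm"))
  x <- .as_plain(norm)
  if (ncol(x) < config$n_pcs + 1) stop("need more cells than n_pcs")
  sds <- apply(x, 1, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  if (nrow(x) < config$n_pcs) {
    stop("fewer non-constant genes (", nrow(x), ") than n_pcs")
  }
  z <- (x - rowMeans(x)) / sds[sds > 0]
  z[z > config$clip_value] <- config$clip_value
  z[z < -config$clip_value] <- -config$clip_value
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE, rank. = config$n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  emb <- sweep(pc$x, 2, flip, `*`)
  rownames(emb) <- colnames(norm)
  emb
}

#' Graph-based clustering of cells
#'
#' Builds a shared-nearest-neighbor (SNN) graph in PC space (k nearest
#' neighbors by Euclidean distance, Jaccard edge weights, pruned below 1/15)
#' and partitions it by modularity community detection (Louvain) at the
#' configured resolution. Labels are `0..K-1` ordered by decreasing cluster
#' size and are deterministic given the seed.
#'
#' @param embedding cells x PCs matrix from [pca_embed()].
#' @param config a [clustering_config()].
#' @return integer vector of cluster labels named by cell.
#' @export
cluster_cells <- function(embedding, config = clustering_config()) {
  if (!all(is.finite(embedding))) stop("embedding must be finite")
  n <- nrow(embedding)
  k <- config$knn_k
  if (n < k) stop("n_cells (", n, ") < knn_k (", k, "); use a smaller k")
  d <- as.matrix(stats::dist(embedding))
  # neighbor sets include the cell itself, then Jaccard overlap
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)])   # k x n
  A <- matrix(0L, n, n)
  A[cbind(rep(seq_len(n), each = k), as.vector(nn))] <- 1L
  shared <- A %*% t(A)
  jac <- shared / (2 * k - shared)
  jac[jac < 1 / 15] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(config$seed)
  cm <- igraph::cluster_louvain(g, resolution = config$resolution)
  memb <- igraph::membership(cm)
  # relabel 0..K-1 by decreasing size (ties by first appearance)
  sizes <- sort(table(memb), decreasing = TRUE)
  lab <- match(as.character(memb), names(sizes)) - 1L
  names(lab) <- rownames(embedding)
  lab
}

#' Two-dimensional embedding for visualization
#'
#' UMAP of the PC coordinates, deterministic given the seed. Used only for
#' plots; all quantitative claims are made in PC space.
#'
#' @param embedding cells x PCs matrix.
#' @param seed RNG seed.
#' @param n_neighbors UMAP neighborhood size.
#' @return cells x 2 coordinate matrix.
#' @export
embed_2d <- function(embedding, seed = 1, n_neighbors = 30) {
  if (nrow(embedding) < 10) stop("need at least 10 cells for a 2-D embedding")
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("embed_2d requires the uwot package")
  }
  set.seed(seed)
  out <- uwot::umap(embedding,
                    n_neighbors = min(n_neighbors, nrow(embedding) - 1),
                    n_threads = 1, n_sgd_threads = 1)
  rownames(out) <- rownames(embedding)
  colnames(out) <- c("dim1", "dim2")
  out
}

#' Compare two cell partitions
#'
#' Contingency table, adjusted Rand index, and per-cluster dispersion: for
#' each cluster of labeling A, the number of clusters of labeling B its
#' cells occupy (the statistic behind "the new ncRNA cluster's cells were
#' dispersed in five combined clusters").
#'
#' @param labels_a,labels_b named label vectors over the same cells.
#' @return list with `contingency`, `ari`, `dispersion`.
#' @export
compare_partitions <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)) ||
      !setequal(names(labels_a), names(labels_b))) {
    stop("labelings must be named over the same cell set")
  }
  labels_b <- labels_b[names(labels_a)]
  tab <- table(A = labels_a, B = labels_b)
  disp <- apply(tab, 1, function(r) sum(r > 0))
  list(contingency = tab,
       ari = mclust::adjustedRandIndex(labels_a, labels_b),
       dispersion = disp)
}

#' Cluster cells on a biotype-restricted feature set
#'
#' Subsets the count matrix to the requested feature set (`combined` = all
#' genes, `coding` = protein-coding only, `ncrna` = the 8 ncRNA classes),
#' then runs the identical normalize / PCA / SNN-cluster chain, mirroring
#' the strategy of re-clustering the same cells with the same parameters on
#' different gene universes.
#'
#' @param counts an [expr_mat()] of kind `counts`.
#' @param genes annotation data.frame.
#' @param feature_set `"combined"`, `"coding"` or `"ncrna"`.
#' @param config a [clustering_config()].
#' @return named integer label vector as from [cluster_cells()].
#' @export
run_feature_set_clustering <- function(counts, genes,
                                       feature_set = c("combined", "coding",
                                                       "ncrna"),
                                       config = clustering_config()) {
  feature_set <- match.arg(feature_set)
  .check_kind(counts, "counts")
  bt <- genes$biotype[match(rownames(counts), genes$gene_id)]
  keep <- switch(feature_set,
                 combined = rep(TRUE, nrow(counts)),
                 coding = !is.na(bt) & bt == "coding",
                 ncrna = !is.na(bt) & bt %in% NCRNA_CLASSES)
  if (!any(keep)) stop("empty feature subset: ", feature_set)
  sub <- expr_mat(.as_plain(counts)[keep, , drop = FALSE], "counts")
  norm <- log_normalize(sub, config$scale_factor)
  emb <- pca_embed(norm, config)
  cluster_cells(emb, config)
}
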