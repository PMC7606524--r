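#' Two-sided Wilcoxon rank-sum p-value (normal approximation)
#'
#' Rank-sum test of `x` vs `y` using the normal approximation with tie
#' correction and continuity correction — the approximation conventionally
#' used for per-gene marker testing, where exact enumeration over thousands
#' of genes is not affordable. The approximation is accurate in the body of
#' the distribution and conservative-to-approximate in the far tails.
#'
#' @param x,y numeric vectors.
#' @return two-sided p-value.
#' @export
wilcox_rank_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nt <- n1 + n2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sig2 <= 0) return(1)
  z <- U - n1 * n2 / 2
  z <- z - sign(z) * 0.5
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sig2)))
}

#' Cluster-specific marker detection
#'
#' FindAllMarkers-style marker discovery for one cluster: for each gene,
#' `pct_in` / `pct_out` are the fractions of expressing cells (normalized
#' value > 0) inside and outside the cluster, and the natural-log fold
#' change is computed on back-transformed means with a pseudocount of 1,
#' `ln_fc = ln(mean(exp(x) - 1 | in) + 1) - ln(mean(exp(x) - 1 | out) + 1)`.
#' A gene is reported iff `pct_in >= min_pct` and `ln_fc > ln_fc_min`;
#' reported genes get a two-sided Wilcoxon rank-sum p (in vs out cells) and
#' a Bonferroni-adjusted p over the total number of genes in the matrix.
#'
#' @param norm an [expr_mat()] of kind `lognorm`.
#' @param labels named cluster labels covering every cell.
#' @param cluster the cluster to characterize.
#' @param min_pct minimum expressing fraction inside the cluster (0.75).
#' @param ln_fc_min natural-log fold-change threshold (0.25, i.e. fold
#'   change > e^0.25).
#' @return data.frame of MarkerRecords: `gene_id`, `cluster`, `ln_fc`,
#'   `pct_in`, `pct_out`, `p`, `p_adj`, sorted by decreasing `ln_fc`.
#' @export
find_markers <- function(norm, labels, cluster, min_pct = 0.75,
                         ln_fc_min = 0.25) {
  .check_kind(norm, "lognorm")
  labels <- labels[colnames(norm)]
  if (anyNA(labels)) stop("labels must cover every cell in the matrix")
  sel <- labels == cluster
  if (!any(sel)) stop("unknown cluster: ", cluster)
  if (sum(sel) < 3 || sum(!sel) < 3) {
    stop("need >= 3 cells inside and outside the cluster")
  }
  x <- .as_plain(norm)
  xin <- x[, sel, drop = FALSE]
  xout <- x[, !sel, drop = FALSE]
  pct_in <- rowMeans(xin > 0)
  pct_out <- rowMeans(xout > 0)
  ln_fc <- log(rowMeans(expm1(xin)) + 1) - log(rowMeans(expm1(xout)) + 1)
  keep <- which(pct_in >= min_pct & ln_fc > ln_fc_min)
  n_tested <- nrow(x)
  p <- vapply(keep, function(i) wilcox_rank_p(xin[i, ], xout[i, ]), numeric(1))
  out <- data.frame(gene_id = rownames(x)[keep],
                    cluster = rep(cluster, length(keep)),
                    ln_fc = ln_fc[keep],
                    pct_in = pct_in[keep], pct_out = pct_out[keep],
                    p = p, p_adj = pmin(1, p * n_tested),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ln_fc, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' @rdname find_markers
#' @description `find_all_markers()` runs [find_markers()] for every cluster
#'   present in `labels` and binds the results.
#' @export
find_all_markers <- function(norm, labels, min_pct = 0.75, ln_fc_min = 0.25) {
  cl <- sort(unique(labels))
  do.call(rbind, lapply(cl, function(k) {
    find_markers(norm, labels, k, min_pct = min_pct, ln_fc_min = ln_fc_min)
  }))
}

#' Top markers of one cluster
#'
#' Keeps records with `p_adj < 0.05`, sorts by decreasing natural-log fold
#' change (ties broken lexicographically by gene id) and returns the top
#' `k`; fewer than `k` may qualify.
#'
#' @param records marker records of one cluster from [find_markers()].
#' @param k number to keep (10).
#' @export
top_markers <- function(records, k = 10) {
  if (length(unique(records$cluster)) > 1) {
    stop("top_markers expects records from a single cluster")
  }
  q <- records[records$p_adj < 0.05, , drop = FALSE]
  q <- q[order(-q$ln_fc, q$gene_id), , drop = FALSE]
  utils::head(q, k)
}
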