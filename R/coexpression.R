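#' Pearson correlation and its two-sided p-value
#'
#' `pearson_r` is the sample Pearson correlation; it is undefined (NA with a
#' warning) for constant input. `pearson_p` converts a correlation into a
#' two-sided p-value through the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom;
#' `|r| = 1` gives p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) {
    warning("correlation undefined for constant input")
    return(NA_real_)
  }
  sum(xc * yc) / (sx * sy)
}

#' @rdname pearson_r
#' @param r correlation in [-1, 1].
#' @param n sample size (>= 3).
#' @export
pearson_p <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r) * sqrt(n - 2) / sqrt(1 - r^2), n - 2))
  ifelse(is.na(r), NA_real_, p)
}

#' Pairwise ncRNA-coding co-expression screen
#'
#' Pearson correlation between every (ncRNA, protein-coding) gene pair on
#' the log2(TPM + 1) matrix across all cells, retaining pairs with
#' `|r| > r_min` (strictly) and `p < p_max` (strictly). Constant genes are
#' skipped; their count is attached as attribute `n_constant_skipped`.
#'
#' @param log2tpm an [expr_mat()] of kind `log2tpm`.
#' @param genes annotation data.frame.
#' @param r_min correlation gate (0.6).
#' @param p_max p-value gate (1e-5).
#' @return data.frame of edges: `ncrna_id`, `coding_id`, `r`, `p`, `sign`
#'   (`pos` iff r > 0), ordered by ncRNA then coding id.
#' @export
screen_pairs <- function(log2tpm, genes, r_min = 0.6, p_max = 1e-5) {
  .check_kind(log2tpm, "log2tpm")
  x <- .as_plain(log2tpm)
  bt <- genes$biotype[match(rownames(x), genes$gene_id)]
  nc <- rownames(x)[!is.na(bt) & bt %in% NCRNA_CLASSES]
  cod <- rownames(x)[!is.na(bt) & bt == "coding"]
  if (length(nc) == 0 || length(cod) == 0) {
    stop("matrix must contain at least one ncRNA and one coding gene")
  }
  n <- ncol(x)
  sds <- apply(x, 1, stats::sd)
  skip <- sum(sds[c(nc, cod)] == 0)
  nc_ok <- nc[sds[nc] > 0]
  cod_ok <- cod[sds[cod] > 0]
  R <- stats::cor(t(x[nc_ok, , drop = FALSE]), t(x[cod_ok, , drop = FALSE]))
  hits <- which(abs(R) > r_min, arr.ind = TRUE)
  if (nrow(hits) > 0) {
    r <- R[hits]
    p <- pearson_p(r, n)
    keep <- p < p_max
    edges <- data.frame(ncrna_id = nc_ok[hits[, 1]][keep],
                        coding_id = cod_ok[hits[, 2]][keep],
                        r = r[keep], p = p[keep],
                        sign = ifelse(r[keep] > 0, "pos", "neg"),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$ncrna_id, edges$coding_id), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(ncrna_id = character(0), coding_id = character(0),
                        r = numeric(0), p = numeric(0), sign = character(0),
                        stringsAsFactors = FALSE)
  }
  attr(edges, "n_constant_skipped") <- skip
  edges
}

#' The same-sign partner rule for candidate regulatory ncRNAs
#'
#' An ncRNA passes iff it is positively co-expressed with at least
#' `min_partners` protein-coding genes (r > r_min, p < partner_p_max) **or**
#' negatively co-expressed with at least `min_partners` (r < -r_min); the
#' two signs are not pooled. The rationale: an ncRNA that genuinely
#' influences expression should influence several genes, which screens out
#' single-pair correlations arising from stochastic, non-biological
#' fluctuation.
#'
#' @param edges edge table from [screen_pairs()].
#' @param min_partners same-sign partner threshold (4).
#' @param r_min,partner_p_max per-partner gates (defaults match the pair
#'   screen).
#' @return data.frame: `ncrna_id`, `n_pos_partners`, `n_neg_partners`,
#'   `passes`.
#' @export
select_hubs <- function(edges, min_partners = 4, r_min = 0.6,
                        partner_p_max = 1e-5) {
  pos <- edges$r > r_min & edges$p < partner_p_max
  neg <- edges$r < -r_min & edges$p < partner_p_max
  ids <- sort(unique(edges$ncrna_id))
  n_pos <- vapply(ids, function(i) sum(pos & edges$ncrna_id == i), numeric(1))
  n_neg <- vapply(ids, function(i) sum(neg & edges$ncrna_id == i), numeric(1))
  data.frame(ncrna_id = ids,
             n_pos_partners = as.integer(n_pos),
             n_neg_partners = as.integer(n_neg),
             passes = n_pos >= min_partners | n_neg >= min_partners,
             stringsAsFactors = FALSE)
}

#' Hub report with partner lists and opposite-sign pairs
#'
#' One row per passing ncRNA, sorted by total partner count descending:
#' partner ids (semicolon-joined), counts by sign, and an `opposite_pairs`
#' column flagging coding genes that this ncRNA shares with another passing
#' ncRNA under the opposite sign (the "co-expressed with the same
#' protein-coding genes in opposite manners" pattern). When cluster labels
#' are supplied, per-cluster mean expression of the ncRNA is appended.
#'
#' @param hubs output of [select_hubs()].
#' @param edges edge table from [screen_pairs()].
#' @param log2tpm optional [expr_mat()] for per-cluster means.
#' @param labels optional named cluster labels matching `log2tpm` cells.
#' @export
hub_report <- function(hubs, edges, log2tpm = NULL, labels = NULL) {
  pass <- hubs[hubs$passes, , drop = FALSE]
  if (nrow(pass) == 0) {
    return(data.frame(ncrna_id = character(0), n_pos_partners = integer(0),
                      n_neg_partners = integer(0), partners = character(0),
                      opposite_pairs = character(0), stringsAsFactors = FALSE))
  }
  e <- edges[edges$ncrna_id %in% pass$ncrna_id, , drop = FALSE]
  rows <- lapply(pass$ncrna_id, function(id) {
    mine <- e[e$ncrna_id == id, , drop = FALSE]
    other <- e[e$ncrna_id != id, , drop = FALSE]
    opp_sign <- ifelse(mine$sign == "pos", "neg", "pos")
    opp <- mine$coding_id[paste(mine$coding_id, opp_sign) %in%
                            paste(other$coding_id, other$sign)]
    data.frame(ncrna_id = id,
               n_pos_partners = sum(mine$sign == "pos"),
               n_neg_partners = sum(mine$sign == "neg"),
               partners = paste(sort(mine$coding_id), collapse = ";"),
               opposite_pairs = paste(sort(unique(opp)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-(out$n_pos_partners + out$n_neg_partners),
                   out$ncrna_id), , drop = FALSE]
  if (!is.null(log2tpm) && !is.null(labels)) {
    labels <- labels[colnames(log2tpm)]
    for (cl in sort(unique(labels))) {
      col <- paste0("mean_expr_cluster_", cl)
      out[[col]] <- rowMeans(.as_plain(log2tpm)[out$ncrna_id,
                                                labels == cl, drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
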