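#' Transcripts per million
#'
#' Length-normalized expression: per cell, `rate_g = count_g / length_bp_g`
#' and `TPM_g = 1e6 * rate_g / sum(rate)`. Cells with zero total counts give
#' an all-zero column (with a warning) rather than an error, so sparse
#' synthetic corners do not abort a run.
#'
#' @param counts an [expr_mat()] of kind `counts`.
#' @param genes annotation from [gene_records()]; every matrix gene must be
#'   present with a length.
#' @return an [expr_mat()] of kind `TPM`.
#' @export
compute_tpm <- function(counts, genes) {
  .check_kind(counts, "counts")
  len <- genes$length_bp[match(rownames(counts), genes$gene_id)]
  if (anyNA(len)) {
    stop("no gene length for: ",
         paste(utils::head(rownames(counts)[is.na(len)], 5), collapse = ", "))
  }
  rate <- .as_plain(counts) / len
  tot <- colSums(rate)
  empty <- tot == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) with zero total counts yield all-zero TPM")
    tot[empty] <- 1
  }
  expr_mat(sweep(rate, 2, tot, `/`) * 1e6, "TPM")
}

#' log2(TPM + 1) transform
#'
#' @param tpm an [expr_mat()] of kind `TPM`.
#' @return an [expr_mat()] of kind `log2tpm`.
#' @export
log2_tpm <- function(tpm) {
  .check_kind(tpm, "TPM")
  out <- log2(.as_plain(tpm) + 1)
  expr_mat(out, "log2tpm")
}

#' Detection under the TPM > 1 rule
#'
#' A gene is detected in a cell iff its TPM is strictly greater than 1 (a
#' gene at exactly 1 TPM is not detected), and detected overall iff detected
#' in at least one cell.
#'
#' @param tpm an [expr_mat()] of kind `TPM`.
#' @param genes annotation data.frame.
#' @param biotype_filter optional subset of [BIOTYPES] restricting which
#'   genes are counted.
#' @return list with `per_cell` (named integer vector of detected-gene
#'   counts) and `per_gene` (named logical vector: detected in >= 1 cell),
#'   both restricted to the filter if given.
#' @export
count_detected <- function(tpm, genes, biotype_filter = NULL) {
  .check_kind(tpm, "TPM")
  bt <- genes$biotype[match(rownames(tpm), genes$gene_id)]
  keep <- rep(TRUE, nrow(tpm))
  if (!is.null(biotype_filter)) {
    bad <- setdiff(biotype_filter, BIOTYPES)
    if (length(bad)) stop("unknown biotype(s): ", paste(bad, collapse = ", "))
    keep <- !is.na(bt) & bt %in% biotype_filter
  }
  det <- .as_plain(tpm)[keep, , drop = FALSE] > 1
  list(per_cell = colSums(det),
       per_gene = rowSums(det) >= 1)
}

#' Detection ratio, percent with two decimals
#'
#' `round(100 * detected / annotated, 2)` with half-up rounding, matching
#' how detect ratios are conventionally printed.
#'
#' @param detected_total,annotated_total non-negative integers with
#'   `detected_total <= annotated_total` and `annotated_total > 0`.
#' @return percentage rounded half-up to 2 decimals.
#' @export
detect_ratio <- function(detected_total, annotated_total) {
  if (any(annotated_total == 0)) stop("annotated_total must be > 0")
  if (any(detected_total < 0) || any(detected_total > annotated_total)) {
    stop("need 0 <= detected_total <= annotated_total")
  }
  x <- 100 * detected_total / annotated_total
  floor(x * 100 + 0.5 + 1e-9) / 100
}

#' Per-biotype detection summary
#'
#' The detection accounting table: for each biotype (and for all ncRNA
#' classes pooled), the per-cell median and range of detected genes, the
#' dataset-level detected total, the annotated total and the detect ratio.
#'
#' @inheritParams count_detected
#' @return data.frame with one row per biotype present in the annotation
#'   plus an `ncRNA_all` row pooling the 8 ncRNA classes.
#' @export
detection_summary <- function(tpm, genes) {
  .check_kind(tpm, "TPM")
  groups <- c(as.list(BIOTYPES), list(NCRNA_CLASSES))
  names(groups) <- c(BIOTYPES, "ncRNA_all")
  ann_bt <- table(factor(genes$biotype, levels = BIOTYPES))
  rows <- lapply(names(groups), function(g) {
    cls <- groups[[g]]
    annotated <- sum(ann_bt[cls])
    if (annotated == 0) return(NULL)
    d <- count_detected(tpm, genes, biotype_filter = cls)
    data.frame(biotype = g,
               median_per_cell = stats::median(d$per_cell),
               min_per_cell = min(d$per_cell),
               max_per_cell = max(d$per_cell),
               detected_total = sum(d$per_gene),
               annotated_total = as.integer(annotated),
               detect_ratio_pct = detect_ratio(sum(d$per_gene), annotated),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Coding vs ncRNA detection correlation per embryo-time interval
#'
#' Within each embryo-time interval, the Pearson correlation (and two-sided
#' p) between the per-cell number of detected protein-coding genes and the
#' per-cell number of detected ncRNAs. Intervals with fewer than 3 cells, or
#' where either count is constant, are reported missing with a reason.
#'
#' @inheritParams count_detected
#' @param annotation data.frame with `cell_id` and `time_interval` for every
#'   matrix cell.
#' @return data.frame: interval, r, p, n_cells, reason (NA when computed).
#' @export
per_interval_detection_correlation <- function(tpm, genes, annotation) {
  .check_kind(tpm, "TPM")
  iv <- annotation$time_interval[match(colnames(tpm), annotation$cell_id)]
  if (anyNA(iv)) stop("every cell needs a time_interval")
  n_cod <- count_detected(tpm, genes, "coding")$per_cell
  n_nc <- count_detected(tpm, genes, NCRNA_CLASSES)$per_cell
  ivs <- intersect(TIME_INTERVALS, unique(iv))
  rows <- lapply(ivs, function(v) {
    sel <- iv == v
    n <- sum(sel)
    if (n < 3) {
      return(data.frame(interval = v, r = NA_real_, p = NA_real_,
                        n_cells = n, reason = "n<3"))
    }
    if (stats::sd(n_cod[sel]) == 0 || stats::sd(n_nc[sel]) == 0) {
      return(data.frame(interval = v, r = NA_real_, p = NA_real_,
                        n_cells = n, reason = "constant"))
    }
    r <- pearson_r(n_cod[sel], n_nc[sel])
    data.frame(interval = v, r = r, p = pearson_p(r, n), n_cells = n,
               reason = NA_character_)
  })
  do.call(rbind, rows)
}
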