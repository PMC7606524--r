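#' Gene biotype classes
#'
#' The nine-way biotype partition used throughout the pipeline: protein-coding
#' genes plus the eight ncRNA classes detectable by poly(A)-primed full-length
#' scRNA-seq (miRNA and piRNA lack poly-A tails and are out of scope).
#' Every gene carries exactly one of these labels; annotation biotype strings
#' that match none of the recognized ncRNA classes are folded into
#' `unknown_ncRNA`.
#'
#' @format A character vector of length 9.
#' @export
BIOTYPES <- c("coding", "antisense", "lincRNA", "rRNA", "snoRNA",
              "pseudogene", "snRNA", "tRNA", "unknown_ncRNA")

#' @rdname BIOTYPES
#' @export
NCRNA_CLASSES <- BIOTYPES[BIOTYPES != "coding"]

# Ensembl-style biotype strings -> our nine classes. Anything unmatched and
# not protein-coding becomes unknown_ncRNA.
.map_biotype <- function(s) {
  s0 <- tolower(s)
  out <- rep("unknown_ncRNA", length(s))
  out[s0 %in% c("protein_coding", "coding", "protein-coding")] <- "coding"
  out[s0 %in% c("antisense", "antisense_rna")] <- "antisense"
  out[s0 %in% c("lincrna", "lncrna", "lnc_rna")] <- "lincRNA"
  out[s0 == "rrna"] <- "rRNA"
  out[s0 == "snorna"] <- "snoRNA"
  out[grepl("pseudogene", s0)] <- "pseudogene"
  out[s0 == "snrna"] <- "snRNA"
  out[s0 == "trna"] <- "tRNA"
  out
}

#' Construct a gene annotation table
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param biotype character vector; either one of the nine canonical classes
#'   (see [BIOTYPES]) or a raw annotation string which is mapped onto them.
#' @param length_bp positive integer gene lengths (defaults to 1000 when the
#'   source provides none; transcripts-per-million needs a length).
#' @return data.frame with columns `gene_id`, `biotype`, `length_bp`.
#' @export
gene_records <- function(gene_id, biotype, length_bp = NULL) {
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("duplicated gene_id in annotation: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  bt <- ifelse(biotype %in% BIOTYPES, biotype, .map_biotype(biotype))
  if (is.null(length_bp)) length_bp <- rep(1000L, length(gene_id))
  length_bp <- as.integer(round(length_bp))
  if (any(is.na(length_bp)) || any(length_bp < 1)) {
    stop("length_bp must be a positive integer for every gene")
  }
  data.frame(gene_id = as.character(gene_id),
             biotype = factor(bt, levels = BIOTYPES),
             length_bp = length_bp,
             stringsAsFactors = FALSE)
}

#' Read gene annotation from GTF/GFF3 or a plain biotype table
#'
#' For GTF/GFF3 the biotype is taken from the `gene_biotype` (or `biotype`)
#' attribute and the gene length is the exonic length of the longest
#' transcript (sum of exon widths, maximized over transcripts), the
#' convention a length-normalized quantification needs when the source gives
#' no explicit length. The plain-table dialect is headerless TSV with columns
#' gene_id, biotype and (optionally) length_bp; rows without a length get
#' 1000 bp.
#'
#' @param path file path.
#' @param format `"gtf"`, `"gff3"` or `"two_column_tsv"`.
#' @return data.frame as from [gene_records()].
#' @export
read_annotation <- function(path, format = c("gtf", "gff3", "two_column_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "two_column_tsv") {
    return(.read_annotation_tsv(path))
  }
  .read_annotation_gxf(path, format)
}

.read_annotation_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty annotation file: ", path)
    return(gene_records(character(0), character(0), integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2)) {
    stop("unparseable annotation line ", which(nfield < 2)[1],
         " in ", path, " (need at least gene_id<TAB>biotype)")
  }
  gene_id <- vapply(parts, `[[`, "", 1)
  biotype <- vapply(parts, `[[`, "", 2)
  len <- rep(1000L, length(parts))
  has3 <- nfield >= 3
  if (any(has3)) {
    v <- suppressWarnings(as.integer(vapply(parts[has3], `[[`, "", 3)))
    if (any(is.na(v))) {
      stop("unparseable annotation line ",
           which(has3)[which(is.na(v))[1]], " in ", path,
           " (third column must be an integer length)")
    }
    len[has3] <- v
  }
  .check_consistent_duplicates(gene_id, biotype)
  keep <- !duplicated(gene_id)
  gene_records(gene_id[keep], biotype[keep], len[keep])
}

.read_annotation_gxf <- function(path, format) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF/GFF3 requires the rtracklayer package")
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = ifelse(format == "gtf", "gtf", "gff3")),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  if (length(gr) == 0) {
    warning("empty annotation file: ", path)
    return(gene_records(character(0), character(0), integer(0)))
  }
  md <- as.data.frame(gr)
  bt_col <- intersect(c("gene_biotype", "biotype", "gene_type"), names(md))
  if (length(bt_col) == 0) stop("no biotype attribute in ", path)
  ex <- md[md$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("annotation has no exon records: ", path)
  tx_col <- intersect(c("transcript_id", "Parent"), names(md))[1]
  if (is.na(tx_col)) stop("annotation has no transcript grouping attribute")
  tx <- as.character(ex[[tx_col]])
  # exonic length per transcript, then the longest transcript per gene
  tx_len <- tapply(ex$width, tx, sum)
  tx_gene <- tapply(as.character(ex$gene_id), tx, `[`, 1)
  gene_len <- tapply(as.numeric(tx_len), as.character(tx_gene), max)
  gene_bt <- md[!is.na(md$gene_id), c("gene_id", bt_col[1])]
  gene_bt <- gene_bt[!is.na(gene_bt[[2]]), ]
  .check_consistent_duplicates(gene_bt$gene_id, .map_biotype(gene_bt[[2]]))
  gene_bt <- gene_bt[!duplicated(gene_bt$gene_id), ]
  ids <- as.character(gene_bt$gene_id)
  len <- gene_len[ids]
  len[is.na(len)] <- 1000
  gene_records(ids, as.character(gene_bt[[2]]), len)
}

.check_consistent_duplicates <- function(gene_id, biotype) {
  mapped <- ifelse(biotype %in% BIOTYPES, biotype, .map_biotype(biotype))
  n_bt <- tapply(mapped, gene_id, function(b) length(unique(b)))
  if (any(n_bt > 1)) {
    stop("gene(s) annotated with conflicting biotypes: ",
         paste(utils::head(names(n_bt)[n_bt > 1], 5), collapse = ", "))
  }
  invisible(TRUE)
}
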