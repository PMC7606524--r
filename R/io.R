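#' Read an expression matrix
#'
#' Two on-disk forms are supported: a dense TSV with gene identifiers in the
#' first column and cell identifiers in the header, and Matrix-Market triplet
#' form (`matrix.mtx` plus side files `genes.tsv` / `cells.tsv` holding the
#' row and column identifiers, one per line). Entries absent from the triplet
#' file are zero.
#'
#' @param path for `tsv`, the file; for `matrix_market_triplet`, either the
#'   `.mtx` file (side files are looked up next to it) or the directory
#'   containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @param format `"tsv"` or `"matrix_market_triplet"`.
#' @param kind value scale of the stored matrix (the file does not record it);
#'   see [expr_mat()].
#' @return an [expr_mat()].
#' @export
read_matrix <- function(path, format = c("tsv", "matrix_market_triplet"),
                        kind = "counts") {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]])) stop("duplicated gene identifiers in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (anyDuplicated(colnames(m))) stop("duplicated cell identifiers in ", path)
    storage.mode(m) <- "double"
  } else {
    if (dir.exists(path)) {
      mtx <- file.path(path, "matrix.mtx")
      gf <- file.path(path, "genes.tsv")
      cf <- file.path(path, "cells.tsv")
    } else {
      mtx <- path
      gf <- file.path(dirname(path), "genes.tsv")
      cf <- file.path(dirname(path), "cells.tsv")
    }
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(gf, warn = FALSE)
    cells <- readLines(cf, warn = FALSE)
    if (anyDuplicated(genes)) stop("duplicated gene identifiers in ", gf)
    if (anyDuplicated(cells)) stop("duplicated cell identifiers in ", cf)
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop("side files do not match matrix dimensions in ", mtx)
    }
    dimnames(m) <- list(genes, cells)
  }
  if (any(m < 0)) stop("negative value in expression matrix ", path)
  expr_mat(m, kind = kind)
}

#' Write an expression matrix
#'
#' Inverse of [read_matrix()]; the round trip is exact for integer counts and
#' accurate to full double precision for real-valued matrices.
#'
#' @param m an [expr_mat()] or plain named matrix.
#' @param path destination (file for `tsv`; directory for triplet form).
#' @param format `"tsv"` or `"matrix_market_triplet"`.
#' @export
write_matrix <- function(m, path, format = c("tsv", "matrix_market_triplet")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(m), as.data.frame(.as_plain(m)),
                     check.names = FALSE)
    write_table(df, path)
  } else {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create directory ", path)
    }
    Matrix::writeMM(Matrix::Matrix(.as_plain(m), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "genes.tsv"))
    writeLines(colnames(m), file.path(path, "cells.tsv"))
  }
  invisible(path)
}

#' Write / read a result table
#'
#' Plain TSV with a header; numeric columns are written at full precision
#' (via [format()] with 17 significant digits) so that tables round-trip
#' losslessly through [read_table()].
#'
#' @param records a data.frame (may have zero rows: a header-only file is
#'   written).
#' @param path destination file; its directory must exist.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) stop("`records` must not be NULL")
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path))
  }
  df <- as.data.frame(records)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- "NA"
      df[[j]] <- v
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
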