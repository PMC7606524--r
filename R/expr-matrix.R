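#' Expression matrix container
#'
#' A thin wrapper around a base numeric matrix (genes in rows, cells in
#' columns) carrying a `kind` tag that records which scale the values are on:
#' raw `counts`, `TPM` (each cell column sums to 1e6), `log2tpm`
#' (log2(TPM + 1)) or `lognorm` (depth-normalized, natural-log transformed).
#' Downstream operations check the tag so that, e.g., the detection rule is
#' never applied to log-scaled values by accident.
#'
#' @param values numeric matrix, genes x cells, with unique row and column
#'   names and no negative entries.
#' @param kind one of `"counts"`, `"TPM"`, `"log2tpm"`, `"lognorm"`.
#' @return `values` with class `expr_mat` and a `kind` attribute.
#' @export
expr_mat <- function(values, kind = c("counts", "TPM", "log2tpm", "lognorm")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene (row) and cell (column) names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicated cell identifiers")
  if (any(values < 0)) stop("negative expression values are not allowed")
  if (kind == "TPM") {
    cs <- colSums(values)
    bad <- cs > 0 & abs(cs - 1e6) > 1e6 * 1e-6
    if (any(bad)) {
      stop("TPM columns must sum to 1e6; offending cells: ",
           paste(utils::head(colnames(values)[bad], 5), collapse = ", "))
    }
  }
  structure(values, kind = kind, class = c("expr_mat", "matrix", "array"))
}

#' @rdname expr_mat
#' @param x an object.
#' @export
expr_kind <- function(x) attr(x, "kind")

# internal gate used by every transform that is only meaningful on one scale
.check_kind <- function(x, expected) {
  k <- expr_kind(x)
  if (is.null(k) || !k %in% expected) {
    stop("expected an expression matrix of kind ",
         paste(expected, collapse = "/"), ", got ",
         if (is.null(k)) "an untagged matrix" else k)
  }
  invisible(TRUE)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d cells, kind = %s\n",
              nrow(x), ncol(x), expr_kind(x)))
  invisible(x)
}

# strip the class but keep dimnames; used before handing to code that
# dispatches on plain matrices
.as_plain <- function(x) {
  attr(x, "kind") <- NULL
  class(x) <- NULL
  x
}
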