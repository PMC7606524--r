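#' Per-gene z-scoring
#'
#' Subtracts the mean and divides by the SD of a log2-TPM row across cells
#' (the "scaled log2-TPM" that temporal trend curves are drawn on). Constant
#' rows cannot be scaled and are reported as skipped.
#'
#' @param x numeric vector (one gene across cells).
#' @return z-scored vector, or NULL (with a warning) for constant input.
#' @export
scale_per_gene <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) {
    warning("constant row skipped: cannot z-score")
    return(NULL)
  }
  (x - mean(x)) / s
}

#' Detect monotonically decreasing temporal trends
#'
#' Operationalizes "expression continuously decreased along embryo time":
#' each gene's log2-TPM row is z-scored across the cells staged inside the
#' window, smoothed along embryo time by loess (span 0.5, [loess_fit()]) and
#' evaluated on a 10-minute grid; the gene is flagged iff the fitted curve
#' is pointwise non-increasing (tolerance `eps`) **and** declines by at
#' least `min_decline` scaled units from the first to the last grid point.
#' Genes on an exclusion list (e.g. known maternally deposited transcripts)
#' are never flagged.
#'
#' Because all genes share the cells' times, a single loess hat matrix
#' smooths the whole matrix at once.
#'
#' @param log2tpm an [expr_mat()] of kind `log2tpm`.
#' @param times named embryo times (minutes) per cell, e.g.
#'   `embryo_time_min` from [stage_cells()].
#' @param window_min time window (minutes) over which the decline is
#'   assessed; default c(270, 830).
#' @param span loess span (0.5).
#' @param degree local polynomial degree for the trend fit. Defaults to 1:
#'   monotonicity is called on the fitted curve with essentially zero
#'   tolerance, and local-quadratic fits flare at window boundaries, which
#'   produces spurious sign changes in the derivative of a genuinely
#'   monotone curve; the local-linear fit is the standard stable choice for
#'   trend calling. (Display curves drawn with [loess_fit()] keep the
#'   classic degree-2 default.)
#' @param eps pointwise monotonicity tolerance (1e-6).
#' @param min_decline minimum total decline in scaled units (0.5).
#' @param exclude gene ids excluded from calling.
#' @param grid_by grid step in minutes (10).
#' @return data.frame with one row per flagged gene: `gene_id`,
#'   `total_decline`, `monotone_decreasing`; the full fitted curves are in
#'   attribute `curves` (genes x grid matrix) with grid times in attribute
#'   `grid_times_min`.
#' @export
detect_decreasing <- function(log2tpm, times, window_min = c(270, 830),
                              span = 0.5, degree = 1, eps = 1e-6,
                              min_decline = 0.5, exclude = character(0),
                              grid_by = 10) {
  .check_kind(log2tpm, "log2tpm")
  times <- times[colnames(log2tpm)]
  sel <- !is.na(times) & times >= window_min[1] & times <= window_min[2]
  if (sum(sel) < 10) stop("fewer than 10 staged cells in the window")
  x <- .as_plain(log2tpm)[, sel, drop = FALSE]
  tt <- as.numeric(times[sel])
  keep_genes <- setdiff(rownames(x), exclude)
  x <- x[keep_genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  x <- x[sds > 0, , drop = FALSE]
  z <- (x - rowMeans(x)) / sds[sds > 0]
  grid <- seq(max(window_min[1], min(tt)), min(window_min[2], max(tt)),
              by = grid_by)
  H <- loess_hat(tt, grid, span = span, degree = degree)
  fitted <- z %*% t(H)                     # genes x grid
  mono <- apply(fitted, 1, function(f) all(diff(f) <= eps))
  decline <- fitted[, 1] - fitted[, ncol(fitted)]
  flag <- mono & decline >= min_decline
  out <- data.frame(gene_id = rownames(z)[flag],
                    total_decline = unname(decline[flag]),
                    monotone_decreasing = rep(TRUE, sum(flag)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_decline), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "curves") <- fitted
  attr(out, "grid_times_min") <- grid
  out
}
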