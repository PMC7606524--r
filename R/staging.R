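#' Embryo-time interval labels
#'
#' The ten embryo-time intervals (minutes) used to bin staged cells,
#' half-open on the right: `<150, [150,270), [270,330), [330,390), [390,450),
#' [450,510), [510,580), [580,690), [690,760), >=760` (labelled `">760"`).
#'
#' @export
TIME_INTERVALS <- c("<150", "150-270", "270-330", "330-390", "390-450",
                    "450-510", "510-580", "580-690", "690-760", ">760")

.INTERVAL_BREAKS <- c(0, 150, 270, 330, 390, 450, 510, 580, 690, 760, Inf)

#' Bin an embryo time into its interval
#'
#' @param t embryo time(s) in minutes, strictly positive.
#' @return factor over [TIME_INTERVALS]. Shared endpoints go to the interval
#'   they open (e.g. 270 min is `"270-330"`, 760 min is `">760"`).
#' @export
bin_time_interval <- function(t) {
  if (any(is.na(t)) || any(t <= 0)) stop("embryo times must be positive")
  cut(t, breaks = .INTERVAL_BREAKS, labels = TIME_INTERVALS, right = FALSE)
}

#' Stage cells against a bulk time course
#'
#' For each cell: (1) Pearson correlation between the cell's log-scaled
#' expression and every bulk column, restricted to the time-variable genes;
#' (2) a loess fit (span 0.75, via [loess_fit()]) of correlation against
#' timepoint; (3) the continuous embryo time is the argmax of the fitted
#' curve on a 1-minute grid over the timepoint range; (4) the assigned bulk
#' timepoint is the reference timepoint nearest that argmax. Cells whose
#' profile is constant over the staging genes cannot be staged and are
#' flagged (`NA` time) rather than aborting the batch; cells whose best
#' correlation is below `min_r` are flagged low-confidence.
#'
#' Because the loess curve is linear in the correlation profile and every
#' cell shares the same timepoints, one hat matrix serves all cells.
#'
#' @param log2tpm an [expr_mat()] of kind `log2tpm` (any log-scaled matrix
#'   works; Pearson correlation is affine-invariant).
#' @param bulk a [bulk_course()].
#' @param span loess span (0.75 by default).
#' @param min_r low-confidence threshold on the best correlation.
#' @return data.frame: `cell_id`, `embryo_time_min`,
#'   `assigned_bulk_timepoint`, `max_r`, `interval`, `low_confidence`.
#' @export
stage_cells <- function(log2tpm, bulk, span = 0.75, min_r = 0.3) {
  .check_kind(log2tpm, c("log2tpm", "lognorm"))
  stopifnot(inherits(bulk, "bulk_course"))
  tp <- bulk$timepoints_min
  if (length(tp) < 3) stop("need at least 3 bulk timepoints")
  gg <- intersect(bulk$time_variable_genes, rownames(log2tpm))
  if (length(gg) < 3) stop("too few time-variable genes shared with matrix")
  prof <- .as_plain(log2tpm)[gg, , drop = FALSE]
  ref <- bulk$values[gg, , drop = FALSE]
  const <- apply(prof, 2, stats::sd) == 0
  # correlation of every cell against every bulk column
  R <- matrix(NA_real_, ncol(prof), length(tp),
              dimnames = list(colnames(prof), colnames(ref)))
  if (any(!const)) {
    R[!const, ] <- t(stats::cor(ref, prof[, !const, drop = FALSE]))
  }
  grid <- seq(tp[1], tp[length(tp)], by = 1)
  H <- loess_hat(tp, grid, span = span)
  fitted <- R %*% t(H)                      # cells x grid
  amax <- apply(fitted, 1, function(r) {
    if (anyNA(r)) NA_real_ else grid[which.max(r)]
  })
  max_r <- suppressWarnings(apply(R, 1, max))
  est <- ifelse(const, NA_real_, amax)
  out <- data.frame(
    cell_id = colnames(prof),
    embryo_time_min = est,
    assigned_bulk_timepoint = ifelse(const, NA_real_,
                                     vapply(amax, function(a) {
                                       if (is.na(a)) NA_real_ else
                                         tp[which.min(abs(tp - a))]
                                     }, numeric(1))),
    max_r = ifelse(const, NA_real_, max_r),
    stringsAsFactors = FALSE
  )
  out$interval <- as.character(ifelse(is.na(est), NA,
                                      as.character(bin_time_interval(
                                        ifelse(is.na(est), 1, est)))))
  out$low_confidence <- is.na(est) | out$max_r < min_r
  rownames(out) <- NULL
  out
}

#' @rdname stage_cells
#' @param cell_profile named numeric vector of log-scaled expression for one
#'   cell.
#' @export
stage_cell <- function(cell_profile, bulk, span = 0.75, min_r = 0.3) {
  m <- matrix(cell_profile, ncol = 1,
              dimnames = list(names(cell_profile), "cell"))
  stage_cells(expr_mat(pmax(m, 0), "log2tpm"), bulk,
              span = span, min_r = min_r)
}
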