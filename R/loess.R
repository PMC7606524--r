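#' Local polynomial (loess) smoother
#'
#' Classic locally weighted polynomial regression, the smoother used both for
#' embryo-time staging (span 0.75 over the correlation-vs-timepoint profile)
#' and for temporal trend curves (span 0.5 along embryo time). For each
#' evaluation point the `ceiling(span * n)` nearest x-neighbors are taken,
#' weighted by the tricube kernel on distance scaled to the furthest included
#' neighbor, and a weighted least-squares polynomial of the requested degree
#' is fitted; the fitted value at the evaluation point is returned.
#'
#' Because the fit is linear in `y`, the smoother is exposed in two forms:
#' [loess_fit()] returns fitted values for one response, while [loess_hat()]
#' returns the hat matrix `L` mapping any response observed at `x` to its
#' fitted values at `xout` (`fitted = L %*% y`), which is what batch staging
#' and per-gene trend smoothing use.
#'
#' The local normal equations carry a ridge of 1e-10 so that duplicated x
#' values (common when several cells share an estimated time) stay solvable.
#'
#' @param x,y numeric vectors of equal length.
#' @param span fraction of points in each local window, in (0, 1].
#' @param degree local polynomial degree (2 by default, the classic choice).
#' @param xout evaluation grid; defaults to `x` itself.
#' @return `loess_fit`: numeric vector of fitted values at `xout`.
#'   `loess_hat`: a `length(xout) x length(x)` matrix.
#' @export
loess_fit <- function(x, y, span, degree = 2, xout = x) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  drop(loess_hat(x, xout, span = span, degree = degree) %*% y)
}

#' @rdname loess_fit
#' @export
loess_hat <- function(x, xout, span, degree = 2) {
  n <- length(x)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  q <- ceiling(span * n)
  if (n < max(degree + 2, q)) {
    stop("too few points (", n, ") for span ", span,
         " and degree ", degree)
  }
  L <- matrix(0, length(xout), n)
  for (i in seq_along(xout)) {
    x0 <- xout[i]
    d <- abs(x - x0)
    idx <- order(d)[seq_len(q)]
    h <- max(d[idx])
    w <- if (h > 0) pmax(0, 1 - (d[idx] / h)^3)^3 else rep(1, q)
    # local basis centered at x0 for conditioning
    X <- outer(x[idx] - x0, 0:degree, `^`)
    XtW <- t(X * w)
    A <- XtW %*% X + diag(1e-10, degree + 1)
    # fitted value at x0 is the intercept of the local fit, so the hat-matrix
    # row is the first row of (X'WX + ridge)^-1 X'W on the window
    L[i, idx] <- solve(A, XtW)[1, ]
  }
  L
}
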