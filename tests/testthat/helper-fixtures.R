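# small in-code fixtures shared across test files

tiny_matrix <- function(values, kind = "counts",
                        genes = sprintf("g%d", seq_len(nrow(values))),
                        cells = sprintf("c%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, cells)
  expr_mat(values, kind)
}

tiny_genes <- function(n_coding = 2, n_trna = 1, length_bp = NULL) {
  ids <- c(sprintf("g%d", seq_len(n_coding + n_trna)))
  bt <- c(rep("coding", n_coding), rep("tRNA", n_trna))
  gene_records(ids, bt, length_bp)
}

# TPM matrix with exact column sums, for detection tests
tpm_from_values <- function(values, ...) {
  m <- tiny_matrix(values, kind = "counts", ...)
  sums <- colSums(m)
  sums[sums == 0] <- 1
  expr_mat(sweep(ncembryo:::.as_plain(m), 2, sums, `/`) * 1e6, "TPM")
}

# independently coded brute-force local-WLS loess oracle: one lm.wfit per
# evaluation point (the package solves the windowed normal equations and
# returns a hat matrix instead)
oracle_loess <- function(x, y, xout, span, degree = 2) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(xout, function(x0) {
    d <- abs(x - x0)
    idx <- order(d)[seq_len(q)]
    h <- max(d[idx])
    w <- if (h > 0) pmax(0, 1 - (d[idx] / h)^3)^3 else rep(1, q)
    X <- outer(x[idx] - x0, 0:degree, `^`)
    fit <- stats::lm.wfit(X, y[idx], w)
    unname(fit$coefficients[1])
  }, numeric(1))
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracle_wilcox_exact <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  cmb <- utils::combn(n, n1)
  stats <- colSums(matrix(r[cmb], nrow = n1))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# a vector pair whose sample Pearson correlation is a chosen value, built
# from an orthonormal basis
make_pair_with_r <- function(r, n = 8) {
  x <- scale(seq_len(n))[, 1]
  z <- scale(stats::resid(stats::lm(stats::rnorm(n) ~ x)))[, 1]
  x <- x / sqrt(sum(x^2))
  z <- z - mean(z)
  z <- z / sqrt(sum(z^2))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}
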