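test_that("TPM is forced by count/length ratios", {
  counts <- tiny_matrix(matrix(c(10, 10), 2, 1))
  genes <- tiny_genes(n_coding = 2, n_trna = 0, length_bp = c(1000, 2000))
  tpm <- compute_tpm(counts, genes)
  # equal counts, 2:1 length ratio -> 2/3 and 1/3 of a million
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # single-gene matrix: any positive count -> 1e6
  one <- compute_tpm(tiny_matrix(matrix(7, 1, 1)),
                     tiny_genes(1, 0, length_bp = 500))
  expect_equal(unname(one[1, 1]), 1e6)
})

test_that("all-zero cells give all-zero TPM columns with a warning", {
  counts <- tiny_matrix(matrix(c(5, 3, 0, 0), 2, 2))
  genes <- tiny_genes(2, 0)
  expect_warning(tpm <- compute_tpm(counts, genes), "zero total")
  expect_equal(unname(tpm[, 2]), c(0, 0))
  expect_equal(sum(tpm[, 1]), 1e6)
})

test_that("a missing gene length is an error naming the gene", {
  counts <- tiny_matrix(matrix(1, 2, 1), genes = c("g1", "gX"))
  expect_error(compute_tpm(counts, tiny_genes(2, 0)), "gX")
})

test_that("log2(TPM+1) hits its fixed points", {
  tpm <- tpm_from_values(matrix(c(0, 1, 3, 999996), 4, 1))
  # column sums to 1e6 by construction; check the elementwise transform
  lt <- log2_tpm(tpm)
  expect_equal(unname(lt[1:3, 1]), c(0, 1, 2))
})

test_that("detection is strictly TPM > 1", {
  v <- matrix(c(0.5, 1.0, 2.0, 10), 4, 1)
  tpm <- tiny_matrix(rbind(v, 1e6 - sum(v)), kind = "TPM",
                     genes = sprintf("g%d", 1:5))
  genes <- gene_records(sprintf("g%d", 1:5),
                        c("coding", "coding", "coding", "coding", "tRNA"))
  d <- count_detected(tpm, genes, biotype_filter = "coding")
  expect_equal(unname(d$per_cell), 2)   # 1.0 excluded by strictness
  expect_equal(unname(d$per_gene), c(FALSE, FALSE, TRUE, TRUE))
  # filter on an absent biotype counts zero everywhere
  d2 <- count_detected(tpm, genes, biotype_filter = "snoRNA")
  expect_equal(unname(d2$per_cell), 0)
  expect_error(count_detected(tpm, genes, "mRNA"), "unknown biotype")
})

test_that("detect_ratio reproduces printed percentages half-up", {
  expect_equal(detect_ratio(20431, 20447), 99.92)
  expect_equal(detect_ratio(20436, 20447), 99.95)
  expect_equal(detect_ratio(571, 637), 89.64)
  expect_equal(detect_ratio(1546, 1590), 97.23)
  expect_equal(detect_ratio(169, 169), 100.00)
  expect_error(detect_ratio(1, 0), "> 0")
  expect_error(detect_ratio(5, 4))
})

test_that("detect_ratio is monotone and 100 only at equality", {
  det <- 0:50
  r <- detect_ratio(det, 50)
  expect_true(all(diff(r) > 0))
  expect_equal(sum(r == 100), 1)
  expect_equal(which(r == 100), 51L)
})

test_that("per-biotype detected totals partition the all-ncRNA total", {
  sim <- simulate_embryo(sim_config(n_cells = 60, seed = 2))
  summ <- detection_summary(sim$tpm, sim$genes)
  nc_rows <- summ[summ$biotype %in% NCRNA_CLASSES, ]
  all_row <- summ[summ$biotype == "ncRNA_all", ]
  expect_equal(sum(nc_rows$detected_total), all_row$detected_total)
  expect_equal(sum(nc_rows$annotated_total), all_row$annotated_total)
  expect_true(all(summ$detected_total <= summ$annotated_total))
  # TPM column sums
  cs <- colSums(sim$tpm)
  expect_true(all(abs(cs[cs > 0] - 1e6) < 1e-3))
})

test_that("per-interval detection correlation matches a direct recount", {
  sim <- simulate_embryo(sim_config(n_cells = 120, seed = 7))
  lt <- log2_tpm(sim$tpm)
  st <- stage_cells(lt, sim$bulk)
  ann <- data.frame(cell_id = st$cell_id, time_interval = st$interval)
  res <- per_interval_detection_correlation(sim$tpm, sim$genes, ann)
  # independent recount from the raw flags
  det_c <- colSums(ncembryo:::.as_plain(sim$tpm)[
    sim$genes$gene_id[sim$genes$biotype == "coding"], ] > 1)
  det_n <- colSums(ncembryo:::.as_plain(sim$tpm)[
    sim$genes$gene_id[sim$genes$biotype != "coding"], ] > 1)
  for (i in seq_len(nrow(res))) {
    sel <- ann$time_interval == res$interval[i]
    if (res$n_cells[i] >= 3 && is.na(res$reason[i])) {
      expect_equal(res$r[i], cor(det_c[sel], det_n[sel]), tolerance = 1e-12)
    }
  }
  # an interval with 2 cells is reported missing with reason
  ann2 <- data.frame(cell_id = colnames(sim$tpm)[1:5],
                     time_interval = c("<150", "<150", "270-330", "270-330",
                                       "270-330"))
  sub <- expr_mat(ncembryo:::.as_plain(sim$tpm)[, 1:5], "TPM")
  res2 <- per_interval_detection_correlation(sub, sim$genes, ann2)
  expect_equal(res2$reason[res2$interval == "<150"], "n<3")
  expect_true(is.na(res2$r[res2$interval == "<150"]))
})

test_that("perfectly proportional detection counts give r = 1", {
  # 10 coding genes, 1 ncRNA-ish construction: build counts so that
  # detected ncRNA = 0.1 * detected coding exactly across cells
  g <- gene_records(sprintf("g%02d", 1:40),
                    c(rep("coding", 30), rep("lincRNA", 10)))
  m <- matrix(0, 40, 3, dimnames = list(g$gene_id, sprintf("c%d", 1:3)))
  for (j in 1:3) {
    m[seq_len(10 * j), j] <- 1000          # 10j detected coding genes
    m[30 + seq_len(j), j] <- 1000          # exactly j detected ncRNAs
  }
  tpm <- tpm_from_values(m, genes = g$gene_id)
  ann <- data.frame(cell_id = colnames(tpm), time_interval = "330-390")
  res <- per_interval_detection_correlation(tpm, g, ann)
  expect_equal(res$r, 1, tolerance = 1e-12)
})
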