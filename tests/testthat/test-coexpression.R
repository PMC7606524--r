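test_that("pearson_r matches hand arithmetic and its fixed points", {
  expect_equal(pearson_r(1:4, 4:1), -1)
  expect_equal(pearson_r(1:5, 1:5), 1)
  # brute-force formula evaluation for an asymmetric case
  x <- c(1, 2, 3); y <- c(1, 2, 10)
  want <- sum((x - 2) * (y - 13 / 3)) /
    sqrt(sum((x - 2)^2) * sum((y - 13 / 3)^2))
  expect_equal(pearson_r(x, y), want, tolerance = 1e-14)
  expect_warning(r <- pearson_r(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson_p fixed points and t-transform", {
  expect_equal(pearson_p(0, 10), 1)
  expect_equal(pearson_p(1, 10), 0)
  expect_equal(pearson_p(-1, 25), 0)
  r <- 0.37; n <- 14
  t0 <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(pearson_p(r, n), 2 * pt(-abs(t0), n - 2), tolerance = 1e-14)
  expect_error(pearson_p(0.5, 2), "n >= 3")
})

test_that("pearson_p agrees with a permutation null at r = 0.6, n = 20", {
  n <- 20
  x <- as.numeric(scale(qnorm(ppoints(n))))
  y <- as.numeric(scale(qnorm(ppoints(n))))
  xs <- x / sqrt(sum(x^2))
  set.seed(123)
  B <- 200000
  perm <- vapply(seq_len(B), function(i) {
    yp <- sample(y)
    yp <- yp - mean(yp)
    sum(xs * yp) / sqrt(sum(yp^2))
  }, numeric(1))
  p_perm <- mean(abs(perm) >= 0.6)
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(pearson_p(0.6, n) - p_perm), 3 * se)
})

test_that("a pair at exactly the correlation gate is excluded", {
  set.seed(11)
  pr <- make_pair_with_r(0.6, n = 12)
  expect_equal(pearson_r(pr$x, pr$y), 0.6, tolerance = 1e-12)
  m <- rbind(nc1 = pmax(pr$x + 2, 0), cg1 = pmax(pr$y + 2, 0))
  colnames(m) <- sprintf("c%02d", 1:12)
  genes <- gene_records(c("nc1", "cg1"), c("lincRNA", "coding"))
  lt <- expr_mat(m, "log2tpm")
  edges <- screen_pairs(lt, genes, r_min = 0.6, p_max = 1)
  expect_equal(nrow(edges), 0)
  # nudging r above the gate admits the pair (p gate relaxed)
  pr2 <- make_pair_with_r(0.75, n = 12)
  m2 <- rbind(nc1 = pmax(pr2$x + 2, 0), cg1 = pmax(pr2$y + 2, 0))
  colnames(m2) <- colnames(m)
  e2 <- screen_pairs(expr_mat(m2, "log2tpm"), genes, r_min = 0.6, p_max = 1)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$sign, "pos")
})

test_that("planted perfect correlation yields r = 1, p = 0 edges", {
  base <- seq(0.5, 4, length.out = 20)
  m <- rbind(hub = base,
             p1 = 2 * base, p2 = 0.5 * base + 1, p3 = base + 3,
             p4 = 3 * base, p5 = 1.5 * base)
  colnames(m) <- sprintf("c%02d", 1:20)
  genes <- gene_records(rownames(m),
                        c("unknown", rep("protein_coding", 5)))
  edges <- screen_pairs(expr_mat(m, "log2tpm"), genes)
  expect_equal(nrow(edges), 5)
  expect_true(all(edges$sign == "pos"))
  expect_equal(edges$r, rep(1, 5), tolerance = 1e-12)
  expect_equal(edges$p, rep(0, 5))
})

test_that("the edge set equals a brute-force double-loop recomputation", {
  ct <- default_cell_types()
  ct$n_marker_genes <- c(3L, 3L, 3L, 3L, 3L, 4L)
  sim <- simulate_embryo(sim_config(
    n_cells = 120, seed = 13, n_coding = 150,
    n_ncrna_per_class = c(antisense = 5, lincRNA = 10, rRNA = 2, snoRNA = 5,
                          pseudogene = 10, snRNA = 3, tRNA = 5,
                          unknown_ncRNA = 20),
    cell_types = ct, n_time_variable_genes = 40, n_trend_genes = 5,
    n_hubs_pos = 2, n_hubs_neg = 0, partners_per_hub = 3))
  lt <- log2_tpm(sim$tpm)
  edges <- screen_pairs(lt, sim$genes)
  # independent double loop over all (ncRNA, coding) pairs
  x <- ncembryo:::.as_plain(lt)
  nc <- sim$genes$gene_id[sim$genes$biotype != "coding"]
  cod <- sim$genes$gene_id[sim$genes$biotype == "coding"]
  want <- list()
  for (a in nc) {
    if (sd(x[a, ]) == 0) next
    for (b in cod) {
      if (sd(x[b, ]) == 0) next
      r <- suppressWarnings(pearson_r(x[a, ], x[b, ]))
      p <- pearson_p(r, ncol(x))
      if (abs(r) > 0.6 && p < 1e-5) {
        want[[length(want) + 1]] <- data.frame(
          ncrna_id = a, coding_id = b, r = r, p = p,
          sign = ifelse(r > 0, "pos", "neg"), stringsAsFactors = FALSE)
      }
    }
  }
  want <- do.call(rbind, want)
  want <- want[order(want$ncrna_id, want$coding_id), ]
  rownames(want) <- NULL
  expect_equal(edges, want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the same-sign partner rule never pools signs", {
  edges <- data.frame(
    ncrna_id = c(rep("n1", 6), rep("n2", 4)),
    coding_id = sprintf("c%d", 1:10),
    r = c(0.7, 0.8, 0.9, -0.7, -0.8, -0.9, 0.7, 0.75, 0.8, 0.85),
    p = 1e-9, sign = c(rep(c("pos", "neg"), each = 3), rep("pos", 4)),
    stringsAsFactors = FALSE)
  hubs <- select_hubs(edges, min_partners = 4)
  expect_false(hubs$passes[hubs$ncrna_id == "n1"])   # 3 + 3, not pooled
  expect_true(hubs$passes[hubs$ncrna_id == "n2"])    # 4 same-sign
  # boundary: removing one partner of a minimal hub makes it fail
  hubs2 <- select_hubs(edges[edges$coding_id != "c7", ], min_partners = 4)
  expect_false(hubs2$passes[hubs2$ncrna_id == "n2"])
})

test_that("gate monotonicity: stricter thresholds never add edges or hubs", {
  sim <- simulate_embryo(sim_config(n_cells = 150, seed = 31))
  lt <- log2_tpm(sim$tpm)
  e1 <- screen_pairs(lt, sim$genes, r_min = 0.6, p_max = 1e-5)
  e2 <- screen_pairs(lt, sim$genes, r_min = 0.7, p_max = 1e-5)
  e3 <- screen_pairs(lt, sim$genes, r_min = 0.6, p_max = 1e-8)
  key <- function(e) paste(e$ncrna_id, e$coding_id)
  expect_true(all(key(e2) %in% key(e1)))
  expect_true(all(key(e3) %in% key(e1)))
  h1 <- select_hubs(e1, min_partners = 4)
  h2 <- select_hubs(e1, min_partners = 6)
  expect_true(all(h2$ncrna_id[h2$passes] %in% h1$ncrna_id[h1$passes]))
})

test_that("independent null data yields no hubs across seeds", {
  for (s in 1:10) {
    set.seed(s)
    n_cells <- 1000
    m <- matrix(rexp(60 * n_cells), 60, n_cells,
                dimnames = list(sprintf("g%02d", 1:60),
                                sprintf("c%04d", 1:n_cells)))
    genes <- gene_records(sprintf("g%02d", 1:60),
                          c(rep("lincRNA", 15), rep("protein_coding", 45)))
    edges <- screen_pairs(expr_mat(m, "log2tpm"), genes)
    hubs <- select_hubs(edges)
    expect_equal(sum(hubs$passes), 0)
  }
})

test_that("hub recovery against planted truth is precise and complete", {
  sim <- simulate_embryo(sim_config(n_cells = 800, seed = 17))
  lt <- log2_tpm(sim$tpm)
  edges <- screen_pairs(lt, sim$genes)
  hubs <- select_hubs(edges)
  found <- hubs$ncrna_id[hubs$passes]
  planted <- unique(sim$truth$hubs$ncrna_id)
  expect_gte(mean(found %in% planted), 0.9)    # precision
  expect_gte(mean(planted %in% found), 0.9)    # recall
  # sign of recovered hubs matches the planted sign
  sgn <- tapply(sim$truth$hubs$sign, sim$truth$hubs$ncrna_id, `[`, 1)
  for (h in intersect(found, planted)) {
    row <- hubs[hubs$ncrna_id == h, ]
    if (sgn[h] == "pos") expect_gte(row$n_pos_partners, 4)
    if (sgn[h] == "neg") expect_gte(row$n_neg_partners, 4)
  }
})

test_that("the hub report counts partners and flags opposite-sign sharing", {
  edges <- data.frame(
    ncrna_id = c(rep("n1", 4), rep("n2", 4)),
    coding_id = c("cA", "cB", "cC", "cD", "cA", "cE", "cF", "cG"),
    r = c(rep(0.8, 4), -0.8, -0.7, -0.75, -0.9),
    p = 0, sign = c(rep("pos", 4), rep("neg", 4)),
    stringsAsFactors = FALSE)
  hubs <- select_hubs(edges, min_partners = 4)
  rep_tab <- hub_report(hubs, edges)
  expect_equal(nrow(rep_tab), 2)
  # cA is shared with opposite signs
  expect_true(all(rep_tab$opposite_pairs == "cA"))
  # partner counts equal a recount from the edge table
  for (i in seq_len(nrow(rep_tab))) {
    id <- rep_tab$ncrna_id[i]
    expect_equal(rep_tab$n_pos_partners[i] + rep_tab$n_neg_partners[i],
                 sum(edges$ncrna_id == id))
  }
  expect_equal(nrow(hub_report(hubs[0, ], edges)), 0)
})
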