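#' Bulk time-course container
#'
#' Genes x reference timepoints (minutes of embryonic development) on a log
#' scale, together with the list of time-variable genes used for staging.
#'
#' @param values numeric matrix, genes x timepoints, log-scale expression.
#' @param timepoints_min strictly increasing positive timepoints in minutes.
#' @param time_variable_genes non-empty subset of `rownames(values)`.
#' @return a `bulk_course` list.
#' @export
bulk_course <- function(values, timepoints_min, time_variable_genes) {
  if (length(timepoints_min) < 3) stop("need at least 3 bulk timepoints")
  if (any(diff(timepoints_min) <= 0) || any(timepoints_min <= 0)) {
    stop("timepoints must be strictly increasing and positive")
  }
  if (ncol(values) != length(timepoints_min)) {
    stop("values must have one column per timepoint")
  }
  if (length(time_variable_genes) == 0) {
    stop("time_variable_genes must be non-empty")
  }
  if (!all(time_variable_genes %in% rownames(values))) {
    stop("time_variable_genes must be a subset of the bulk gene set")
  }
  colnames(values) <- as.character(timepoints_min)
  structure(list(values = values,
                 timepoints_min = as.numeric(timepoints_min),
                 time_variable_genes = as.character(time_variable_genes)),
            class = "bulk_course")
}

#' Default synthetic cell-type composition
#'
#' Six embryonic cell types patterned on the tissues resolved in *C. elegans*
#' embryo scRNA-seq: anterior and posterior intestine, pharynx, hypodermis,
#' undifferentiated early cells, and a muscle type whose identity is carried
#' solely by ncRNA expression (its protein-coding profile is drawn from a
#' host mixture of other types, so coding-only clustering scatters it).
#'
#' Each ordinary type carries a program of 40 differentially boosted genes
#' (3/4 coding, 1/4 ncRNA) -- real tissue identities involve dozens to
#' hundreds of differential genes, and the type signal must coexist in PCA
#' space with the (strong) temporal signal of the staging genes. The
#' ncRNA-defined muscle type carries a compact, stronger all-ncRNA program.
#'
#' @return data.frame with columns `name`, `proportion`, `n_marker_genes`,
#'   `marker_ln_fc`.
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("undiff_early", "intestine_anterior", "intestine_posterior",
             "pharynx", "hypodermis", "muscle"),
    proportion = c(0.20, 0.15, 0.15, 0.20, 0.20, 0.10),
    n_marker_genes = c(40L, 40L, 40L, 40L, 40L, 16L),
    marker_ln_fc = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.5),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic embryo dataset. Defaults emulate the scale of
#' the real study: 1031 cells over embryo times 150-800 min, a ten-timepoint
#' bulk reference at the interval midpoints, a biotype-partitioned gene set,
#' planted positively/negatively co-expressed ncRNA hubs, planted
#' cluster-specific markers, one ncRNA-defined cell type, and genes with
#' monotonically decreasing temporal profiles. Noise is negative binomial
#' with logistic (in log mean) dropout, the standard scRNA-seq assumption
#' under which a TPM > 1 detection rule is meaningful.
#'
#' @param n_cells number of cells.
#' @param n_coding number of protein-coding genes.
#' @param n_ncrna_per_class named integer vector over the 8 ncRNA classes.
#' @param cell_types data.frame as [default_cell_types()].
#' @param time_range_min range of true embryo times (minutes).
#' @param bulk_timepoints_min reference timepoints of the bulk course.
#' @param n_time_variable_genes number of coding genes given smooth logistic
#'   temporal ramps (these form the staging gene list).
#' @param n_hubs_pos,n_hubs_neg number of planted positive/negative ncRNA
#'   hubs.
#' @param partners_per_hub coding partners per hub (>= 1).
#' @param hub_latent_sd SD of the per-cell latent log-normal factor shared by
#'   a hub and its partners.
#' @param hub_expr_mult baseline multiplier for hub ncRNAs; planted hubs are
#'   abundant transcripts, as the empirical screen's top hubs (rRNAs,
#'   highly expressed lincRNAs) are.
#' @param n_trend_genes number of genes with strictly decreasing exponential
#'   temporal decay.
#' @param trend_log2_decline range (log2 units over the full time range) of
#'   planted decline amplitudes.
#' @param nb_dispersion negative-binomial dispersion (0 = Poisson).
#' @param dropout logical; apply logistic dropout?
#' @param dropout_midpoint,dropout_slope dropout is Bernoulli with
#'   probability `plogis(dropout_slope * (dropout_midpoint - log(mu)))` where
#'   `mu` is the expected count.
#' @param dropout_extra extra uniform dropout probability (0 by default);
#'   used to study staging degradation under increasing dropout.
#' @param ncrna_marker_fraction fraction of each ordinary type's markers
#'   drawn from ncRNA classes (0 plants no informative ncRNA markers).
#' @param ncrna_only_type name of the cell type distinguishable only by
#'   ncRNA expression, or NULL for none.
#' @param ncrna_only_host_types types whose coding profiles the
#'   `ncrna_only_type` cells borrow (drawn per cell, proportional to the host
#'   types' own proportions).
#' @param mean_depth median sequencing depth (total counts per cell). The
#'   default reflects a high-depth full-length protocol in which
#'   well-expressed genes receive tens to hundreds of counts per cell.
#' @param seed integer RNG seed; the full output is bit-reproducible given
#'   the seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 1031,
                       n_coding = 2000,
                       n_ncrna_per_class = c(antisense = 20, lincRNA = 30,
                                             rRNA = 5, snoRNA = 40,
                                             pseudogene = 150, snRNA = 15,
                                             tRNA = 60, unknown_ncRNA = 300),
                       cell_types = default_cell_types(),
                       time_range_min = c(150, 800),
                       bulk_timepoints_min = c(100, 210, 300, 360, 420, 480,
                                               545, 635, 725, 800),
                       n_time_variable_genes = 300,
                       n_hubs_pos = 6, n_hubs_neg = 2,
                       partners_per_hub = 6,
                       hub_latent_sd = 1.2,
                       hub_expr_mult = 25,
                       n_trend_genes = 20,
                       trend_log2_decline = c(3, 5),
                       nb_dispersion = 0.1,
                       dropout = TRUE,
                       dropout_midpoint = 0, dropout_slope = 1,
                       dropout_extra = 0,
                       ncrna_marker_fraction = 0.25,
                       ncrna_only_type = "muscle",
                       ncrna_only_host_types = c("hypodermis", "undiff_early",
                                                 "pharynx"),
                       mean_depth = 200000,
                       seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(cell_types$proportion) - 1) > 1e-9) {
    stop("cell type proportions must sum to 1")
  }
  if (partners_per_hub < 1) stop("partners_per_hub must be >= 1")
  counts <- c(n_cells, n_coding, n_ncrna_per_class, n_time_variable_genes,
              n_hubs_pos, n_hubs_neg, n_trend_genes)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (!setequal(names(n_ncrna_per_class), NCRNA_CLASSES)) {
    stop("n_ncrna_per_class must name exactly the 8 ncRNA classes")
  }
  if (!is.null(ncrna_only_type)) {
    if (!ncrna_only_type %in% cell_types$name) {
      stop("ncrna_only_type must be one of the configured cell types")
    }
    if (!all(ncrna_only_host_types %in% cell_types$name)) {
      stop("unknown host type(s)")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# class-typical transcript lengths (bp, log-normal medians)
.LEN_MEDIAN <- c(coding = 1500, antisense = 600, lincRNA = 800, rRNA = 1500,
                 snoRNA = 100, pseudogene = 1000, snRNA = 150, tRNA = 75,
                 unknown_ncRNA = 140)

#' Simulate a synthetic embryo dataset
#'
#' Generative model, fully determined by `config$seed`:
#' \enumerate{
#'   \item each cell draws a type by the configured proportions and an embryo
#'     time uniform on `time_range_min`;
#'   \item the mean of gene g in a cell is its log-normal baseline, times
#'     `exp(marker_ln_fc)` if g is a marker of the cell's type, times a
#'     smooth logistic ramp in time for time-variable genes, times a strictly
#'     decreasing exponential decay for trend genes;
#'   \item each hub contributes a per-cell latent `a ~ N(0, hub_latent_sd)`
#'     multiplying the hub ncRNA mean by `exp(a)` and each coding partner by
#'     `exp(a)` (positive hub) or `exp(-a)` (negative hub);
#'   \item cells of the `ncrna_only_type` receive their protein-coding
#'     profile (including coding marker boosts) from a per-cell host type, so
#'     that only ncRNA features carry their identity;
#'   \item counts are negative binomial around depth-scaled means, thinned by
#'     logistic dropout; TPM follows from counts and gene lengths via
#'     [compute_tpm()];
#'   \item the bulk course records the log2 population-mean expression of
#'     every gene at each bulk timepoint, free of sampling noise.
#' }
#'
#' @param config a [sim_config()].
#' @return list with elements `counts`, `tpm` (both [expr_mat()]), `genes`
#'   (annotation data.frame), `bulk` ([bulk_course()]) and `truth` (list of
#'   planted-parameter tables; see [truth_report()]).
#' @export
simulate_embryo <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ct <- config$cell_types

  ## ---- gene universe -------------------------------------------------
  gene_id <- c(sprintf("cg%04d", seq_len(config$n_coding)),
               unlist(lapply(NCRNA_CLASSES, function(cl) {
                 n <- config$n_ncrna_per_class[[cl]]
                 if (n == 0) character(0) else sprintf("%s%03d", cl, seq_len(n))
               })))
  biotype <- c(rep("coding", config$n_coding),
               rep(NCRNA_CLASSES, config$n_ncrna_per_class[NCRNA_CLASSES]))
  G <- length(gene_id)
  length_bp <- pmax(30L, as.integer(round(
    stats::rlnorm(G, log(.LEN_MEDIAN[biotype]), 0.5))))
  genes <- gene_records(gene_id, biotype, length_bp)
  coding_ids <- gene_id[biotype == "coding"]
  ncrna_ids <- gene_id[biotype != "coding"]
  baseline <- stats::rlnorm(G, meanlog = log(5), sdlog = 1)
  names(baseline) <- gene_id

  ## ---- planted gene roles (disjoint sets) ----------------------------
  # Planted signal genes (markers, hub members, trend genes) are drawn from
  # the well-expressed half of their pool -- ranked by baseline * length, a
  # proxy for expected read counts -- mirroring the fact that markers and
  # co-expression hits are only discoverable among robustly detected genes.
  expr_weight <- baseline * length_bp
  names(expr_weight) <- gene_id
  pool <- coding_ids
  take <- function(n, from) {
    if (n > length(from)) stop("infeasible config: gene pool exhausted")
    sample(from, n)
  }
  hi <- function(ids) ids[expr_weight[ids] >= stats::median(expr_weight[ids])]
  tv_genes <- take(config$n_time_variable_genes, pool)
  pool <- setdiff(pool, tv_genes)
  trend_genes <- take(config$n_trend_genes, hi(pool))
  pool <- setdiff(pool, trend_genes)
  n_hubs <- config$n_hubs_pos + config$n_hubs_neg
  partner_pool <- take(n_hubs * config$partners_per_hub, hi(pool))
  pool <- setdiff(pool, partner_pool)

  hub_candidates <- ncrna_ids[sub("[0-9]+$", "", ncrna_ids) %in%
                                c("lincRNA", "unknown_ncRNA")]
  hub_ncrnas <- take(n_hubs, hi(hub_candidates))
  hub_sign <- rep(c(1, -1), c(config$n_hubs_pos, config$n_hubs_neg))
  hub_partners <- split(partner_pool,
                        rep(seq_len(max(n_hubs, 1)),
                            each = config$partners_per_hub)[
                              seq_along(partner_pool)])
  # hub ncRNAs are abundant, constitutively expressed transcripts (the
  # empirical screen's top hubs are rRNAs and highly expressed lincRNAs)
  baseline[hub_ncrnas] <- baseline[hub_ncrnas] * config$hub_expr_mult

  # the ncRNA-only type takes all of its markers from ncRNA classes, every
  # other type takes 3/4 coding, 1/4 ncRNA
  ncrna_marker_pool <- setdiff(ncrna_ids, hub_ncrnas)
  coding_marker_pool <- hi(pool)
  ncrna_marker_pool <- hi(ncrna_marker_pool)
  markers <- list()
  for (i in seq_len(nrow(ct))) {
    ty <- ct$name[i]
    nm <- ct$n_marker_genes[i]
    if (!is.null(config$ncrna_only_type) && ty == config$ncrna_only_type) {
      mk <- take(nm, ncrna_marker_pool)
      ncrna_marker_pool <- setdiff(ncrna_marker_pool, mk)
    } else {
      nc <- round(nm * config$ncrna_marker_fraction)
      mk_c <- take(nm - nc, coding_marker_pool)
      coding_marker_pool <- setdiff(coding_marker_pool, mk_c)
      mk_n <- take(nc, ncrna_marker_pool)
      ncrna_marker_pool <- setdiff(ncrna_marker_pool, mk_n)
      mk <- c(mk_c, mk_n)
    }
    markers[[ty]] <- mk
  }

  ## ---- per-cell states ----------------------------------------------
  n <- config$n_cells
  cell_id <- sprintf("cell%04d", seq_len(n))
  type <- sample(ct$name, n, replace = TRUE, prob = ct$proportion)
  t_min <- stats::runif(n, config$time_range_min[1], config$time_range_min[2])
  host <- type
  is_nconly <- if (is.null(config$ncrna_only_type)) rep(FALSE, n) else
    type == config$ncrna_only_type
  if (any(is_nconly)) {
    hp <- ct$proportion[match(config$ncrna_only_host_types, ct$name)]
    host[is_nconly] <- sample(config$ncrna_only_host_types, sum(is_nconly),
                              replace = TRUE, prob = hp)
  }

  ## ---- temporal profiles ---------------------------------------------
  tv_amp <- stats::runif(length(tv_genes), 1, 2.5) *
    sample(c(-1, 1), length(tv_genes), replace = TRUE)
  tv_mid <- stats::runif(length(tv_genes), config$time_range_min[1],
                         config$time_range_min[2])
  tv_scale <- stats::runif(length(tv_genes), 30, 80)
  tv_factor <- function(t) {
    # genes x times matrix of multiplicative logistic ramps
    exp(tv_amp * stats::plogis(outer(-tv_mid, t, `+`) / tv_scale))
  }
  tr_amp <- stats::runif(length(trend_genes), config$trend_log2_decline[1],
                         config$trend_log2_decline[2])
  tr_factor <- function(t) {
    frac <- (t - config$time_range_min[1]) /
      diff(config$time_range_min)
    exp(-log(2) * outer(tr_amp, frac))
  }

  ## ---- expected expression matrix ------------------------------------
  mu <- matrix(baseline, G, n, dimnames = list(gene_id, cell_id))
  # marker boosts: own type for ncRNA genes, host type for coding genes
  is_coding_gene <- biotype == "coding"
  for (i in seq_len(nrow(ct))) {
    ty <- ct$name[i]
    boost <- exp(ct$marker_ln_fc[i])
    mk <- markers[[ty]]
    mk_c <- mk[mk %in% coding_ids]
    mk_n <- setdiff(mk, mk_c)
    if (length(mk_c)) mu[mk_c, host == ty] <- mu[mk_c, host == ty] * boost
    if (length(mk_n)) mu[mk_n, type == ty] <- mu[mk_n, type == ty] * boost
  }
  if (length(tv_genes)) {
    mu[tv_genes, ] <- mu[tv_genes, ] * tv_factor(t_min)
  }
  if (length(trend_genes)) {
    mu[trend_genes, ] <- mu[trend_genes, ] * tr_factor(t_min)
  }
  for (j in seq_len(n_hubs)) {
    a <- stats::rnorm(n, 0, config$hub_latent_sd)
    mu[hub_ncrnas[j], ] <- mu[hub_ncrnas[j], ] * exp(a)
    mu[hub_partners[[j]], ] <- mu[hub_partners[[j]], ] *
      rep(exp(hub_sign[j] * a), each = config$partners_per_hub)
  }

  ## ---- counts: NB + logistic dropout ---------------------------------
  w <- mu * length_bp
  depth <- stats::rlnorm(n, log(config$mean_depth), 0.3)
  lambda <- sweep(w, 2, colSums(w) / depth, `/`)
  cnt <- if (config$nb_dispersion > 0) {
    stats::rnbinom(G * n, mu = lambda, size = 1 / config$nb_dispersion)
  } else {
    stats::rpois(G * n, lambda)
  }
  cnt <- matrix(as.numeric(cnt), G, n, dimnames = dimnames(mu))
  if (isTRUE(config$dropout)) {
    p_drop <- stats::plogis(config$dropout_slope *
                              (config$dropout_midpoint - log(lambda)))
    cnt[stats::runif(G * n) < p_drop] <- 0
  }
  if (config$dropout_extra > 0) {
    cnt[stats::runif(G * n) < config$dropout_extra] <- 0
  }
  counts <- expr_mat(cnt, "counts")
  tpm <- suppressWarnings(compute_tpm(counts, genes))

  ## ---- noise-free bulk reference -------------------------------------
  tp <- config$bulk_timepoints_min
  hub_e <- rep(1, G)
  names(hub_e) <- gene_id
  hub_e[c(hub_ncrnas, partner_pool)] <- exp(config$hub_latent_sd^2 / 2)
  bulkv <- matrix(0, G, length(tp), dimnames = list(gene_id, tp))
  # population mean at time t: mix cell types by proportion (coding profile
  # of the ncRNA-only type comes from its hosts, matching the generator)
  type_mu <- matrix(baseline, G, nrow(ct), dimnames = list(gene_id, ct$name))
  for (i in seq_len(nrow(ct))) {
    ty <- ct$name[i]
    mk <- markers[[ty]]
    type_mu[mk, ty] <- type_mu[mk, ty] * exp(ct$marker_ln_fc[i])
  }
  eff_prop <- ct$proportion
  names(eff_prop) <- ct$name
  # coding-gene mixture weights: ncRNA-only type's mass goes to its hosts
  prop_coding <- eff_prop
  nco <- config$ncrna_only_type
  if (!is.null(nco)) {
    hostw <- eff_prop[config$ncrna_only_host_types]
    prop_coding[config$ncrna_only_host_types] <-
      hostw + eff_prop[nco] * hostw / sum(hostw)
    prop_coding[nco] <- 0
  }
  mean_c <- drop(type_mu[is_coding_gene, , drop = FALSE] %*% prop_coding)
  mean_n <- drop(type_mu[!is_coding_gene, , drop = FALSE] %*% eff_prop)
  mean_type <- numeric(G)
  mean_type[is_coding_gene] <- mean_c
  mean_type[!is_coding_gene] <- mean_n
  for (k in seq_along(tp)) {
    mt <- mean_type * hub_e
    if (length(tv_genes)) {
      mt[tv_genes] <- mt[tv_genes] * drop(tv_factor(tp[k]))
    }
    if (length(trend_genes)) {
      mt[trend_genes] <- mt[trend_genes] * drop(tr_factor(tp[k]))
    }
    bulkv[, k] <- log2(1e6 * mt / sum(mt) + 1)
  }
  bulk <- bulk_course(bulkv, tp, tv_genes)

  ## ---- ground truth ---------------------------------------------------
  truth <- list(
    cells = data.frame(cell_id = cell_id, type = type, host_type = host,
                       time_min = t_min, stringsAsFactors = FALSE),
    hubs = if (n_hubs > 0) data.frame(
      hub_id = rep(sprintf("hub%02d", seq_len(n_hubs)),
                   each = config$partners_per_hub),
      ncrna_id = rep(hub_ncrnas, each = config$partners_per_hub),
      sign = rep(ifelse(hub_sign > 0, "pos", "neg"),
                 each = config$partners_per_hub),
      partner_id = unlist(hub_partners, use.names = FALSE),
      stringsAsFactors = FALSE
    ) else data.frame(hub_id = character(0), ncrna_id = character(0),
                      sign = character(0), partner_id = character(0)),
    markers = data.frame(
      type = rep(names(markers), lengths(markers)),
      gene_id = unlist(markers, use.names = FALSE),
      stringsAsFactors = FALSE),
    trend_genes = data.frame(gene_id = trend_genes,
                             log2_decline = tr_amp,
                             stringsAsFactors = FALSE),
    expected_mean_count = data.frame(gene_id = gene_id,
                                     mean_count = rowMeans(lambda),
                                     stringsAsFactors = FALSE)
  )
  truth <- lapply(truth, function(df) { rownames(df) <- NULL; df })
  list(counts = counts, tpm = tpm, genes = genes, bulk = bulk, truth = truth)
}

#' Serialize / restore planted ground truth
#'
#' Writes the truth tables of [simulate_embryo()] as TSVs (`cells.tsv`,
#' `hubs.tsv`, `markers.tsv`, `trend_genes.tsv`, `expected_mean_count.tsv`)
#' into a directory, and reads them back. The round trip is lossless.
#'
#' @param truth the `truth` element of a simulation.
#' @param dir destination directory (created if missing; its parent must
#'   exist).
#' @export
truth_report <- function(truth, dir) {
  if (!dir.exists(dir)) {
    if (!dir.exists(dirname(dir))) stop("parent directory missing: ", dir)
    dir.create(dir)
  }
  for (nm in names(truth)) {
    write_table(truth[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' @rdname truth_report
#' @export
read_truth <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, read_table)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out[c("cells", "hubs", "markers", "trend_genes",
        "expected_mean_count")[c("cells", "hubs", "markers", "trend_genes",
                                 "expected_mean_count") %in% names(out)]]
}
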