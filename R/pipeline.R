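#' Pipeline configuration
#'
#' A flat list of paths, stage parameters and a global seed driving
#' [run_pipeline()]. The global seed fans out to per-stage seeds derived
#' from a hash of the stage name, so inserting or dropping a stage does not
#' shift the randomness of the others.
#'
#' @param stages ordered subset of `simulate`, `profile`, `stage_time`,
#'   `cluster`, `markers`, `coexpr`, `trends`. Missing upstream dependencies
#'   that `simulate` can satisfy are added automatically.
#' @param outdir output directory (created if missing).
#' @param seed global integer seed.
#' @param sim a [sim_config()] (used when `simulate` runs).
#' @param clustering a [clustering_config()].
#' @param paths named list of input files for runs on real data: `matrix`
#'   (counts TSV), `annotation` (+ `annotation_format`), `bulk_values`,
#'   `bulk_time_variable`, `exclude` (maternal-transcript list, one id per
#'   line). Ignored for stages that `simulate` feeds.
#' @param staging_span,trend_span loess spans (0.75 / 0.5).
#' @param trend_window_min decline window in minutes.
#' @param min_pct,ln_fc_min marker gates.
#' @param r_min,p_max,min_partners co-expression screen gates.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "profile", "stage_time",
                                       "cluster", "markers", "coexpr",
                                       "trends"),
                            outdir = tempfile("ncembryo_run_"),
                            seed = 1,
                            sim = sim_config(seed = seed),
                            clustering = clustering_config(seed = seed),
                            paths = list(),
                            staging_span = 0.75, trend_span = 0.5,
                            trend_window_min = c(270, 830),
                            min_pct = 0.75, ln_fc_min = 0.25,
                            r_min = 0.6, p_max = 1e-5, min_partners = 4) {
  known <- c("simulate", "profile", "stage_time", "cluster", "markers",
             "coexpr", "trends")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "pipeline_config")
}

# stage -> stages it needs
.STAGE_DEPS <- list(simulate = character(0),
                    profile = character(0),
                    stage_time = character(0),
                    cluster = character(0),
                    markers = "cluster",
                    coexpr = "profile",
                    trends = c("profile", "stage_time"))

.stage_seed <- function(seed, stage) {
  (seed + sum(utf8ToInt(stage)) * 1009L) %% .Machine$integer.max
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order, writing every result
#' as TSV under `config$outdir` and recording a manifest (stage, file, rows,
#' md5 checksum) plus a parameter snapshot. Re-running with an identical
#' config reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest data.frame (also written to `manifest.tsv`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- unique(config$stages)
  # pull in implicit dependencies, keeping canonical order
  repeat {
    need <- unique(unlist(.STAGE_DEPS[stages]))
    missing <- setdiff(need, stages)
    if (!length(missing)) break
    stages <- c(stages, missing)
  }
  canonical <- c("simulate", "profile", "stage_time", "cluster", "markers",
                 "coexpr", "trends")
  stages <- canonical[canonical %in% stages]
  data_stages <- setdiff(stages, "simulate")
  needs_data <- length(data_stages) > 0
  use_sim <- "simulate" %in% stages

  out <- config$outdir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list()
  add <- function(stage, file, nrows) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = basename(file), n_rows = nrows,
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }

  counts <- tpm <- genes <- bulk <- truth <- NULL
  exclude <- character(0)
  if (use_sim) {
    cfg <- config$sim
    cfg$seed <- .stage_seed(config$seed, "simulate")
    sim <- simulate_embryo(cfg)
    counts <- sim$counts; tpm <- sim$tpm; genes <- sim$genes
    bulk <- sim$bulk; truth <- sim$truth
    write_matrix(counts, file.path(out, "counts.tsv"))
    add("simulate", file.path(out, "counts.tsv"), nrow(counts))
    write_table(genes, file.path(out, "genes.tsv"))
    add("simulate", file.path(out, "genes.tsv"), nrow(genes))
    truth_report(truth, file.path(out, "truth"))
    for (f in list.files(file.path(out, "truth"), full.names = TRUE)) {
      add("simulate", f, NA)
    }
  } else if (needs_data) {
    p <- config$paths
    if (is.null(p$matrix) || is.null(p$annotation)) {
      stop("stages ", paste(data_stages, collapse = ", "),
           " need input data: supply paths$matrix and paths$annotation, ",
           "or include the simulate stage")
    }
    counts <- read_matrix(p$matrix, "tsv", kind = "counts")
    genes <- read_annotation(p$annotation,
                             p$annotation_format %||% "two_column_tsv")
    tpm <- compute_tpm(counts, genes)
    if ("stage_time" %in% stages || "trends" %in% stages) {
      if (is.null(p$bulk_values) || is.null(p$bulk_time_variable)) {
        stop("stage_time needs paths$bulk_values and paths$bulk_time_variable")
      }
      bv <- read_matrix(p$bulk_values, "tsv", kind = "log2tpm")
      bulk <- bulk_course(.as_plain(bv), as.numeric(colnames(bv)),
                          readLines(p$bulk_time_variable, warn = FALSE))
    }
    if (!is.null(p$exclude)) exclude <- readLines(p$exclude, warn = FALSE)
  }

  ltpm <- if (!is.null(tpm)) suppressWarnings(log2_tpm(tpm))
  staging <- NULL
  labels <- NULL

  if ("profile" %in% stages) {
    summ <- detection_summary(tpm, genes)
    write_table(summ, file.path(out, "detection_summary.tsv"))
    add("profile", file.path(out, "detection_summary.tsv"), nrow(summ))
  }
  if ("stage_time" %in% stages) {
    if (is.null(bulk)) stop("stage_time needs a bulk course")
    staging <- stage_cells(ltpm, bulk, span = config$staging_span)
    write_table(staging, file.path(out, "staging.tsv"))
    add("stage_time", file.path(out, "staging.tsv"), nrow(staging))
    if ("profile" %in% stages) {
      ann <- data.frame(cell_id = staging$cell_id,
                        time_interval = staging$interval)
      ok <- !is.na(ann$time_interval)
      ivc <- per_interval_detection_correlation(
        expr_mat(.as_plain(tpm)[, ok, drop = FALSE], "TPM"), genes, ann[ok, ])
      write_table(ivc, file.path(out, "interval_detection_correlation.tsv"))
      add("stage_time", file.path(out, "interval_detection_correlation.tsv"),
          nrow(ivc))
    }
  }
  if ("cluster" %in% stages) {
    cc <- config$clustering
    cc$seed <- .stage_seed(config$seed, "cluster")
    lab <- lapply(c(combined = "combined", coding = "coding",
                    ncrna = "ncrna"),
                  function(fs) run_feature_set_clustering(counts, genes, fs,
                                                          cc))
    labels <- lab$combined
    ltab <- data.frame(cell_id = names(labels),
                       cluster_combined = unname(lab$combined),
                       cluster_coding = unname(lab$coding[names(labels)]),
                       cluster_ncrna = unname(lab$ncrna[names(labels)]),
                       stringsAsFactors = FALSE)
    write_table(ltab, file.path(out, "clusters.tsv"))
    add("cluster", file.path(out, "clusters.tsv"), nrow(ltab))
    cmpcn <- compare_partitions(lab$combined, lab$ncrna)
    cmp_df <- as.data.frame(cmpcn$contingency, stringsAsFactors = FALSE)
    names(cmp_df) <- c("cluster_combined", "cluster_ncrna", "n_cells")
    cmp_df$ari_combined_vs_ncrna <- cmpcn$ari
    write_table(cmp_df, file.path(out, "partition_comparison.tsv"))
    add("cluster", file.path(out, "partition_comparison.tsv"), nrow(cmp_df))
  }
  if ("markers" %in% stages) {
    norm <- log_normalize(counts, config$clustering$scale_factor)
    mk <- find_all_markers(norm, labels, min_pct = config$min_pct,
                           ln_fc_min = config$ln_fc_min)
    mk$biotype <- as.character(genes$biotype[match(mk$gene_id,
                                                   genes$gene_id)])
    top <- do.call(rbind, lapply(split(mk, mk$cluster), top_markers))
    write_table(mk, file.path(out, "markers.tsv"))
    add("markers", file.path(out, "markers.tsv"), nrow(mk))
    write_table(top, file.path(out, "top_markers.tsv"))
    add("markers", file.path(out, "top_markers.tsv"), nrow(top))
  }
  if ("coexpr" %in% stages) {
    edges <- screen_pairs(ltpm, genes, r_min = config$r_min,
                          p_max = config$p_max)
    hubs <- select_hubs(edges, min_partners = config$min_partners,
                        r_min = config$r_min,
                        partner_p_max = config$p_max)
    rep_tab <- hub_report(hubs, edges)
    write_table(edges, file.path(out, "edges.tsv"))
    add("coexpr", file.path(out, "edges.tsv"), nrow(edges))
    write_table(hubs, file.path(out, "hubs.tsv"))
    add("coexpr", file.path(out, "hubs.tsv"), nrow(hubs))
    write_table(rep_tab, file.path(out, "hub_report.tsv"))
    add("coexpr", file.path(out, "hub_report.tsv"), nrow(rep_tab))
  }
  if ("trends" %in% stages) {
    tms <- stats::setNames(staging$embryo_time_min, staging$cell_id)
    tr <- detect_decreasing(ltpm, tms, window_min = config$trend_window_min,
                            span = config$trend_span, exclude = exclude)
    tr$biotype <- as.character(genes$biotype[match(tr$gene_id,
                                                   genes$gene_id)])
    write_table(tr, file.path(out, "trends.tsv"))
    add("trends", file.path(out, "trends.tsv"), nrow(tr))
  }

  man <- do.call(rbind, manifest)
  params <- config[c("stages", "seed", "staging_span", "trend_span",
                     "trend_window_min", "min_pct", "ln_fc_min", "r_min",
                     "p_max", "min_partners")]
  params$stages_run <- stages
  yaml::write_yaml(params, file.path(out, "params.yaml"))
  write_table(man, file.path(out, "manifest.tsv"))
  invisible(man)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Human-readable run report
#'
#' @param outdir a directory produced by [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
summarize_run <- function(outdir) {
  mf <- file.path(outdir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", outdir)
  man <- read_table(mf)
  if (nrow(man) == 0) {
    warning("empty manifest")
    return(character(0))
  }
  lines <- c(sprintf("pipeline run in %s", outdir),
             sprintf("  %-10s %-38s %6s rows", "stage", "file", ""),
             sprintf("  %-10s %-38s %6s", man$stage, man$file,
                     ifelse(is.na(man$n_rows), "-", man$n_rows)))
  det <- file.path(outdir, "detection_summary.tsv")
  if (file.exists(det)) {
    d <- read_table(det)
    lines <- c(lines, "", "detection summary (TPM > 1):",
               sprintf("  %-14s detected %5d / %5d  (%.2f%%)",
                       d$biotype, d$detected_total, d$annotated_total,
                       d$detect_ratio_pct))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
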