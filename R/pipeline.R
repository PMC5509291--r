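# Stage orchestration: file-based pipeline with stable filenames and a
# manifest. Stages communicate only through TSV files under the run
# directory; no stage mutates its inputs.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Pipeline run configuration
#'
#' Holds the paths and the analysis thresholds. The threshold defaults are
#' the pipeline's canonical operating point: depth >= 10 in >= 3 samples per
#' group, 500-bp merge gap, >= 10 percentage-point methylation difference
#' with >= 2 FDR < 0.05 CpGs, 0.5 RPKM floor, rank-test p < 0.05 with 2-fold
#' expression change, and 50 expression bins.
#'
#' @param out_dir Output/run directory (created if missing).
#' @param seed Seed for the simulate stage.
#' @param min_depth,min_samples,merge_gap,min_delta,alpha,min_sig_cpgs
#'   Methylation-side thresholds.
#' @param rpkm_floor,de_p,fold Expression-side thresholds.
#' @param n_bins Expression bins for the correlation curves.
#' @param sim Optional `sim_config` for the simulate stage (its seed is
#'   overridden by `seed`).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, min_depth = 10, min_samples = 3,
                       merge_gap = 500, min_delta = 10, alpha = 0.05,
                       min_sig_cpgs = 2, rpkm_floor = 0.5, de_p = 0.05,
                       fold = 2, n_bins = 50, sim = NULL) {
  num <- c(min_depth, min_samples, merge_gap, min_delta, alpha, min_sig_cpgs,
           rpkm_floor, de_p, fold, n_bins)
  if (any(num <= 0)) stop("run_config: thresholds must be positive")
  if (is.null(sim)) sim <- sim_config(seed = seed)
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 min_depth = min_depth, min_samples = min_samples,
                 merge_gap = merge_gap, min_delta = min_delta, alpha = alpha,
                 min_sig_cpgs = min_sig_cpgs, rpkm_floor = rpkm_floor,
                 de_p = de_p, fold = fold, n_bins = n_bins, sim = sim),
            class = "run_config")
}

.manifest_entry <- function(path) {
  n <- length(readLines(path, warn = FALSE)) - 1L
  data.table::data.table(file = basename(path), n_rows = n,
                         md5 = unname(tools::md5sum(path)))
}

#' Run a pipeline stage
#'
#' Stages: `simulate` writes synthetic inputs (coverage files, sample sheets,
#' gene models, CGI BED, counts, lengths, truth table); `methylome` filters
#' CpGs and merges regions; `dmr` calls promoter and gene-body DMRs;
#' `expression` calls differential expression; `integrate` computes bin
#' curves and the concordance analysis; `all` runs everything in order. Each
#' stage writes TSVs with stable names under the run directory and the
#' manifest (file, row count, md5) is written to `manifest.tsv`.
#'
#' @param stage One of "simulate", "methylome", "dmr", "expression",
#'   "integrate", "all".
#' @param config A `run_config`.
#' @return The manifest data.table, invisibly.
#' @export
run_stage <- function(stage = c("all", "simulate", "methylome", "dmr",
                                "expression", "integrate"),
                      config) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("simulate", "methylome", "dmr", "expression", "integrate")
  else stage
  files <- character(0)
  for (s in stages) {
    message(sprintf("[gestmeth] stage %s (out_dir=%s, seed=%d)", s,
                    config$out_dir, config$seed))
    files <- c(files, switch(s,
      simulate = .stage_simulate(config),
      methylome = .stage_methylome(config),
      dmr = .stage_dmr(config),
      expression = .stage_expression(config),
      integrate = .stage_integrate(config)))
  }
  manifest <- data.table::rbindlist(lapply(files, .manifest_entry))
  .write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(manifest)
}

.path <- function(config, name) file.path(config$out_dir, name)

.require_inputs <- function(config, names) {
  p <- vapply(names, function(n) .path(config, n), character(1))
  missing <- p[!file.exists(p)]
  if (length(missing))
    stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  p
}

.stage_simulate <- function(config) {
  genome <- simulate_genome(config$sim)
  meth <- simulate_methylome(config$sim, genome)
  expr <- simulate_counts(config$sim, genome)

  files <- character(0)
  cov_dir <- .path(config, "coverage")
  dir.create(cov_dir, showWarnings = FALSE)
  # paths are stored relative to the run directory so reruns in different
  # directories produce byte-identical sheets
  sheet <- data.table::rbindlist(lapply(meth, function(s) {
    f <- file.path(cov_dir, paste0(s$sample_id, ".cov.tsv"))
    utils::write.table(s$calls, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    data.table::data.table(sample_id = s$sample_id, group = s$group,
                           path = file.path("coverage",
                                            paste0(s$sample_id, ".cov.tsv")))
  }))
  files <- c(files, .write_tsv(sheet, .path(config, "meth_samples.tsv")))

  g <- genome$genes
  gm_out <- data.table::data.table(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand, tss = g$tss,
    tts = g$tts,
    exon_starts = vapply(g$exons, function(e)
      paste(e$start, collapse = ","), character(1)),
    exon_ends = vapply(g$exons, function(e)
      paste(e$end, collapse = ","), character(1)))
  files <- c(files, .write_tsv(gm_out, .path(config, "gene_models.tsv")))

  cgi_path <- .path(config, "cgi.bed")
  write_bed(genome$cgi, cgi_path)
  files <- c(files, cgi_path)

  cts <- data.table::data.table(gene_id = rownames(expr$counts))
  for (s in colnames(expr$counts)) cts[[s]] <- expr$counts[, s]
  files <- c(files, .write_tsv(cts, .path(config, "counts.tsv")))
  files <- c(files, .write_tsv(
    data.table::data.table(gene_id = names(expr$length_kb),
                           length_kb = expr$length_kb),
    .path(config, "gene_lengths.tsv")))
  files <- c(files, .write_tsv(
    data.table::data.table(sample_id = names(expr$groups),
                           group = expr$groups,
                           total_reads = expr$total_reads[names(expr$groups)]),
    .path(config, "expr_samples.tsv")))
  files <- c(files, .write_tsv(truth_table(genome),
                               .path(config, "truth.tsv")))
  files
}

.read_matrix_tsv <- function(config) {
  p <- .require_inputs(config, c("filtered_matrix.tsv", "meth_samples.tsv"))
  d <- utils::read.table(p[1], sep = "\t", header = TRUE,
                         check.names = FALSE)
  sheet <- utils::read.table(p[2], sep = "\t", header = TRUE)
  ids <- as.character(sheet$sample_id)
  lv <- as.matrix(d[, ids, drop = FALSE])
  structure(list(sites = data.table::data.table(chrom = d$chrom,
                                                pos = d$pos),
                 levels = lv, depth = NULL,
                 groups = stats::setNames(as.character(sheet$group), ids),
                 params = list()),
            class = "cpg_matrix")
}

.stage_methylome <- function(config) {
  p <- .require_inputs(config, "meth_samples.tsv")
  sheet <- utils::read.table(p, sep = "\t", header = TRUE)
  sheet$path <- ifelse(file.exists(as.character(sheet$path)),
                       as.character(sheet$path),
                       file.path(config$out_dir, sheet$path))
  samples <- lapply(seq_len(nrow(sheet)), function(i) {
    read_coverage_file(as.character(sheet$path[i]),
                       as.character(sheet$sample_id[i]),
                       as.character(sheet$group[i]))
  })
  mat <- filter_sites(samples, min_depth = config$min_depth,
                      min_samples_per_group = config$min_samples)
  regions <- merge_regions(mat, merge_gap = config$merge_gap)

  out <- data.table::data.table(chrom = mat$sites$chrom, pos = mat$sites$pos)
  for (s in colnames(mat$levels)) out[[s]] <- mat$levels[, s]
  files <- .write_tsv(out, .path(config, "filtered_matrix.tsv"))
  files <- c(files, .write_tsv(regions$regions, .path(config, "regions.tsv")))
  files <- c(files, .write_tsv(
    data.table::data.table(site_region = regions$site_region),
    .path(config, "site_regions.tsv")))

  cgi <- if (file.exists(.path(config, "cgi.bed")))
    read_bed(.path(config, "cgi.bed")) else NULL
  h <- methylation_histograms(mat, regions, cgi_track = cgi)
  files <- c(files, .write_tsv(h$levels, .path(config, "meth_histograms.tsv")))
  files <- c(files, .write_tsv(h$difference,
                               .path(config, "meth_diff_histograms.tsv")))
  files
}

.stage_dmr <- function(config) {
  .require_inputs(config, c("gene_models.tsv", "site_regions.tsv"))
  mat <- .read_matrix_tsv(config)
  genes <- read_gene_models(.path(config, "gene_models.tsv"))
  sr <- utils::read.table(.path(config, "site_regions.tsv"), sep = "\t",
                          header = TRUE)
  reg <- utils::read.table(.path(config, "regions.tsv"), sep = "\t",
                           header = TRUE)
  regions <- structure(list(regions = data.table::as.data.table(reg),
                            site_region = sr$site_region,
                            merge_gap = config$merge_gap),
                       class = "merged_regions")
  prom <- promoter_interval(genes)
  body <- gene_body_interval(genes)
  dmr_p <- call_dmrs(mat, prom, regions, min_delta = config$min_delta,
                     alpha = config$alpha,
                     min_sig_cpgs = config$min_sig_cpgs)
  dmr_b <- call_dmrs(mat, body, regions, min_delta = config$min_delta,
                     alpha = config$alpha,
                     min_sig_cpgs = config$min_sig_cpgs)
  c(.write_tsv(dmr_p, .path(config, "dmr_promoters.tsv")),
    .write_tsv(dmr_b, .path(config, "dmr_gene_bodies.tsv")))
}

.read_expression <- function(config) {
  p <- .require_inputs(config, c("counts.tsv", "gene_lengths.tsv",
                                 "expr_samples.tsv"))
  cts <- utils::read.table(p[1], sep = "\t", header = TRUE,
                           check.names = FALSE)
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts$gene_id
  len <- utils::read.table(p[2], sep = "\t", header = TRUE)
  sheet <- utils::read.table(p[3], sep = "\t", header = TRUE)
  expression_table(counts,
                   stats::setNames(len$length_kb, len$gene_id),
                   stats::setNames(sheet$total_reads,
                                   as.character(sheet$sample_id)),
                   stats::setNames(as.character(sheet$group),
                                   as.character(sheet$sample_id)),
                   floor = config$rpkm_floor)
}

.stage_expression <- function(config) {
  tbl <- .read_expression(config)
  de <- call_de(tbl, p_threshold = config$de_p, fold = config$fold)
  .write_tsv(de, .path(config, "de_genes.tsv"))
}

.stage_integrate <- function(config) {
  .require_inputs(config, c("de_genes.tsv", "dmr_promoters.tsv",
                            "dmr_gene_bodies.tsv", "gene_models.tsv",
                            "cgi.bed"))
  mat <- .read_matrix_tsv(config)
  tbl <- .read_expression(config)
  de <- data.table::as.data.table(
    utils::read.table(.path(config, "de_genes.tsv"), sep = "\t",
                      header = TRUE))
  dmr_p <- data.table::as.data.table(
    utils::read.table(.path(config, "dmr_promoters.tsv"), sep = "\t",
                      header = TRUE))
  dmr_b <- data.table::as.data.table(
    utils::read.table(.path(config, "dmr_gene_bodies.tsv"), sep = "\t",
                      header = TRUE))
  genes <- read_gene_models(.path(config, "gene_models.tsv"))
  cgi <- read_bed(.path(config, "cgi.bed"))

  retained <- tbl$genes[tbl$genes$retained]
  files <- character(0)

  curves <- list()
  for (grp in c("first", "third")) {
    expr <- stats::setNames(
      if (grp == "first") retained$avg_first else retained$avg_third,
      retained$gene_id)
    bins <- bin_genes_by_expression(expr,
                                    n_bins = min(config$n_bins,
                                                 length(expr)))
    for (kind in c("promoter", "gene_body")) {
      feats <- if (kind == "promoter") promoter_interval(genes)
               else gene_body_interval(genes)
      feats$cgi <- cgi_flag(feats, cgi)
      asg <- assign_to_feature(mat, feats)
      gm <- .site_group_means(mat)[[grp]]
      fm <- vapply(asg$sites, function(si)
        if (length(si)) mean(gm[si], na.rm = TRUE) else NA_real_,
        numeric(1))
      for (ctx in c("CGI", "non_CGI")) {
        sel <- feats$cgi == ctx
        v <- stats::setNames(fm[sel], feats$gene_id[sel])
        v <- v[!is.na(v)]
        curves[[length(curves) + 1L]] <-
          bin_methylation_curve(bins, v, context = paste(kind, ctx, sep = "_"),
                                group = grp)
      }
    }
  }
  files <- c(files, .write_tsv(data.table::rbindlist(curves),
                               .path(config, "bin_curves.tsv")))

  conc_p <- concordance_table(dmr_p, de, "promoter")
  conc_b <- concordance_table(dmr_b, de, "gene_body")
  files <- c(files, .write_tsv(conc_p, .path(config, "concordance_promoters.tsv")))
  files <- c(files, .write_tsv(conc_b, .path(config, "concordance_gene_bodies.tsv")))

  tests <- list()
  for (nm in c("promoter", "gene_body")) {
    tb <- if (nm == "promoter") conc_p else conc_b
    if (nrow(tb) > 0) {
      tst <- concordance_test(tb)
      tests[[length(tests) + 1L]] <- data.table::data.table(
        analysis = paste0("concordance_", nm), n = nrow(tb),
        n_anti = sum(tb$concordance == "anti"), p_value = tst$p_value)
    }
  }
  tests_dt <- if (length(tests)) data.table::rbindlist(tests) else
    data.table::data.table(analysis = character(0), n = integer(0),
                           n_anti = integer(0), p_value = numeric(0))
  files <- c(files, .write_tsv(tests_dt, .path(config, "concordance_tests.tsv")))
  files
}
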