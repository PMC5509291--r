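# Synthetic RRBS + RNA-seq data with known planted structure.
#
# Noise model: each CpG carries a true methylation level drawn from a
# context-specific beta distribution (CpG-island CpGs from a low-mode beta,
# non-island CpGs from a high-mode beta, reproducing the canonical bimodal
# RRBS methylation profile); per-sample reads are binomial draws at a
# negative-binomial sequencing depth. Expression counts are negative-binomial
# around planted group means. Planted group effects (hypermethylated
# features, fold-changed genes, and doubly-affected genes with a configured
# anti-concordance fraction) are recorded in a truth table.

#' Simulation configuration
#'
#' Defaults mirror the study design this pipeline targets: 6 first- vs 5
#' third-trimester methylomes, 5 vs 4 expression samples, RRBS-like depth
#' around 30x, bimodal CGI/non-CGI methylation, planted hypermethylation of
#' +20 percentage points and 4-fold expression changes of which 77% are
#' down-regulated.
#'
#' @param seed Integer seed; the entire simulation is reproducible from it.
#' @param n_genes Number of genes.
#' @param n_chroms Number of autosomes to lay genes on.
#' @param n_meth_samples Integer vector c(first, third) methylome samples.
#' @param n_expr_samples Integer vector c(first, third) expression samples.
#' @param cgi_fraction Fraction of promoters overlapping a CpG island.
#' @param depth_mean,depth_size Negative-binomial read-depth parameters
#'   (mean and size/dispersion).
#' @param beta_cgi,beta_noncgi Beta(a, b) parameters of the true methylation
#'   level in CGI and non-CGI context.
#' @param frac_hyper_promoters,frac_hyper_bodies Fractions of genes given a
#'   planted promoter / gene-body hypermethylation.
#' @param meth_delta Planted methylation shift in percentage points (third
#'   minus first).
#' @param frac_de Fraction of genes given a planted expression fold change.
#' @param fold Planted fold change magnitude.
#' @param frac_down Fraction of planted DE genes that are down-regulated.
#' @param n_concordant Number of genes planted with BOTH a promoter
#'   hypermethylation and an expression change.
#' @param anti_fraction Fraction of the concordant genes whose expression
#'   change opposes the methylation change (anti-correlated).
#' @param nb_size Negative-binomial size for expression counts.
#' @param total_reads Mean total aligned reads per expression sample.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 300, n_chroms = 4,
                       n_meth_samples = c(first = 6, third = 5),
                       n_expr_samples = c(first = 5, third = 4),
                       cgi_fraction = 0.5, depth_mean = 30, depth_size = 5,
                       beta_cgi = c(1.5, 10), beta_noncgi = c(10, 1.5),
                       frac_hyper_promoters = 0.1, frac_hyper_bodies = 0.1,
                       meth_delta = 20, frac_de = 0.15, fold = 4,
                       frac_down = 0.77, n_concordant = 0,
                       anti_fraction = 0.75, nb_size = 20,
                       total_reads = 2e6) {
  fr <- c(cgi_fraction, frac_hyper_promoters, frac_hyper_bodies, frac_de,
          frac_down, anti_fraction)
  if (any(fr < 0 | fr > 1)) stop("sim_config: fractions must lie in [0, 1]")
  if (meth_delta < 0 || meth_delta > 100)
    stop("sim_config: meth_delta must lie in [0, 100]")
  if (n_concordant > n_genes)
    stop("sim_config: n_concordant exceeds n_genes")
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_chroms = n_chroms, n_meth_samples = n_meth_samples,
                 n_expr_samples = n_expr_samples,
                 cgi_fraction = cgi_fraction, depth_mean = depth_mean,
                 depth_size = depth_size, beta_cgi = beta_cgi,
                 beta_noncgi = beta_noncgi,
                 frac_hyper_promoters = frac_hyper_promoters,
                 frac_hyper_bodies = frac_hyper_bodies,
                 meth_delta = meth_delta, frac_de = frac_de, fold = fold,
                 frac_down = frac_down, n_concordant = n_concordant,
                 anti_fraction = anti_fraction, nb_size = nb_size,
                 total_reads = total_reads),
            class = "sim_config")
}

#' Simulate a genome: gene models, CGI track, CpG positions, planted truth
#'
#' Genes are laid non-overlapping along `n_chroms` autosomes with
#' strand-aware TSS/TTS and 2-4 exons. CGI promoters carry a CpG island
#' around the TSS with densely spaced CpGs; non-CGI promoters and gene
#' bodies carry sparser CpGs whose spacing straddles the 500-bp merge gap, so
#' multi-CpG merged regions and singleton regions both occur; a few
#' intergenic CpGs guarantee singletons. Planted effects (which genes get a
#' hypermethylated promoter/body, which are differentially expressed, and the
#' doubly-affected concordant set) are drawn here and recorded in the truth
#' table.
#'
#' @param config A `sim_config`.
#' @return List with `genes` (a `gene_models` table), `cgi` (data.table
#'   chrom, start, end), `cpgs` (data.table chrom, pos), `truth` (see
#'   [truth_table()]) and `config`.
#' @export
simulate_genome <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  chrom <- paste0("chr", rep_len(seq_len(cfg$n_chroms), n))
  gene_id <- sprintf("G%04d", seq_len(n))

  genes <- vector("list", n)
  cgi <- vector("list", n)
  cpgs <- vector("list", n)
  cursor <- stats::setNames(rep(5000L, cfg$n_chroms),
                            paste0("chr", seq_len(cfg$n_chroms)))
  is_cgi_prom <- rep(FALSE, n)
  is_cgi_prom[sample.int(n, round(cfg$cgi_fraction * n))] <- TRUE

  for (i in seq_len(n)) {
    ch <- chrom[i]
    glen <- sample(4000:12000, 1)
    gstart <- cursor[ch]
    gend <- gstart + glen
    cursor[ch] <- gend + sample(3000:8000, 1)
    strand <- sample(c("+", "-"), 1)
    tss <- if (strand == "+") gstart else gend
    tts <- if (strand == "+") gend else gstart

    # exons tile part of [gstart, gend]
    k <- sample(2:4, 1)
    cuts <- sort(sample(seq(gstart + 200L, gend - 200L, by = 50L),
                        2L * k))
    ex <- data.frame(start = cuts[seq(1, 2 * k, by = 2)],
                     end = cuts[seq(2, 2 * k, by = 2)])

    # promoter span in genomic coordinates
    pstart <- if (strand == "+") tss - 1000L else tss - 500L
    pend <- if (strand == "+") tss + 500L else tss + 1000L
    pstart <- max(1L, pstart)

    if (is_cgi_prom[i]) {
      ci <- c(max(pstart, tss - 300L), min(pend, tss + 300L))
      cgi[[i]] <- data.table::data.table(chrom = ch, start = ci[1],
                                         end = ci[2])
      prom_sp <- sample(40:120, 40, replace = TRUE)
    } else {
      prom_sp <- sample(80:200, 40, replace = TRUE)
    }
    ppos <- pstart + cumsum(prom_sp)
    ppos <- ppos[ppos <= pend]

    body_sp <- sample(100:700, 60, replace = TRUE)
    bstart <- min(gstart, gend) + 1100L
    bpos <- bstart + cumsum(body_sp)
    bpos <- bpos[bpos <= gend]

    igpos <- gend + sample(1000:2500, sample(1:2, 1))

    cpgs[[i]] <- data.table::data.table(chrom = ch,
                                        pos = as.integer(sort(unique(
                                          c(ppos, bpos, igpos)))))
    genes[[i]] <- list(gene_id = gene_id[i], chrom = ch, strand = strand,
                       tss = tss, tts = tts, exons = ex)
  }

  gm <- gene_models(gene_id = vapply(genes, `[[`, character(1), "gene_id"),
                    chrom = vapply(genes, `[[`, character(1), "chrom"),
                    strand = vapply(genes, `[[`, character(1), "strand"),
                    tss = vapply(genes, function(g) g$tss, numeric(1)),
                    tts = vapply(genes, function(g) g$tts, numeric(1)),
                    exons = lapply(genes, `[[`, "exons"))
  cgi_dt <- data.table::rbindlist(cgi[!vapply(cgi, is.null, logical(1))])
  cpg_dt <- data.table::rbindlist(cpgs)
  ord <- .chrom_order(cpg_dt$chrom)
  cpg_dt <- cpg_dt[order(match(chrom, ord), pos)]

  # planted truth ------------------------------------------------------
  truth <- data.table::data.table(gene_id = gene_id,
                                  cgi_promoter = is_cgi_prom,
                                  promoter_delta = 0, body_delta = 0,
                                  log2fc = 0, planted_class = "null")
  pool <- seq_len(n)
  conc <- integer(0)
  if (cfg$n_concordant > 0) {
    conc <- sample(pool, cfg$n_concordant)
    pool <- setdiff(pool, conc)
    n_anti <- round(cfg$anti_fraction * cfg$n_concordant)
    anti <- sample(conc, n_anti)
    truth$promoter_delta[conc] <- cfg$meth_delta
    truth$log2fc[conc] <- ifelse(seq_len(n)[conc] %in% anti,
                                 -log2(cfg$fold), log2(cfg$fold))
    truth$planted_class[conc] <- ifelse(seq_len(n)[conc] %in% anti,
                                        "concordant_anti",
                                        "concordant_positive")
  }
  n_hp <- round(cfg$frac_hyper_promoters * n)
  if (n_hp > 0 && length(pool) >= n_hp) {
    hp <- sample(pool, n_hp)
    pool <- setdiff(pool, hp)
    truth$promoter_delta[hp] <- cfg$meth_delta
    truth$planted_class[hp] <- "dmr_promoter"
  }
  n_hb <- round(cfg$frac_hyper_bodies * n)
  if (n_hb > 0 && length(pool) >= n_hb) {
    hb <- sample(pool, n_hb)
    pool <- setdiff(pool, hb)
    truth$body_delta[hb] <- cfg$meth_delta
    truth$planted_class[hb] <- "dmr_body"
  }
  n_de <- round(cfg$frac_de * n)
  if (n_de > 0 && length(pool) >= n_de) {
    de <- sample(pool, n_de)
    down <- de[seq_len(round(cfg$frac_down * n_de))]
    truth$log2fc[de] <- log2(cfg$fold)
    truth$log2fc[down] <- -log2(cfg$fold)
    truth$planted_class[de] <- "de"
  }

  list(genes = gm, cgi = cgi_dt, cpgs = cpg_dt, truth = truth, config = cfg)
}

#' Simulate per-sample methylation call sets
#'
#' Draws each CpG's true methylation level from its context beta
#' distribution; CpGs inside a planted promoter or gene body get the
#' configured shift added for third-trimester samples (the baseline of
#' planted sites is drawn uniformly on \[10, 60\]% so the shifted level stays
#' within range). Read depth is negative-binomial per site and sample,
#' methylated reads binomial.
#'
#' @param config A `sim_config`.
#' @param genome Result of [simulate_genome()].
#' @return List of `methyl_calls`, one per sample.
#' @export
simulate_methylome <- function(config, genome) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  cp <- genome$cpgs
  ns <- nrow(cp)
  in_cgi <- .in_intervals(cp$chrom, cp$pos, cp$pos, genome$cgi)
  base <- numeric(ns)
  base[in_cgi] <- stats::rbeta(sum(in_cgi), cfg$beta_cgi[1], cfg$beta_cgi[2])
  base[!in_cgi] <- stats::rbeta(sum(!in_cgi), cfg$beta_noncgi[1],
                                cfg$beta_noncgi[2])

  shift <- rep(0, ns)
  planted <- genome$truth[genome$truth$promoter_delta != 0 |
                            genome$truth$body_delta != 0]
  if (nrow(planted) > 0) {
    g <- genome$genes[match(planted$gene_id, genome$genes$gene_id)]
    pr <- promoter_interval(g)
    bd <- gene_body_interval(g)
    pr_sel <- planted$promoter_delta != 0
    bd_sel <- planted$body_delta[match(bd$gene_id, planted$gene_id)] != 0
    feat <- rbind(pr[pr_sel, .(chrom, start, end)],
                  bd[bd_sel, .(chrom, start, end)])
    hit <- .in_intervals(cp$chrom, cp$pos, cp$pos, feat)
    shift[hit] <- cfg$meth_delta / 100
    # keep the shifted level in range: planted sites start from a mid-low base
    base[hit] <- stats::runif(sum(hit), 0.10, 0.60)
  }

  lev1 <- base
  lev3 <- pmin(0.995, pmax(0.005, base + shift))

  ids <- c(sprintf("first_%d", seq_len(cfg$n_meth_samples[["first"]])),
           sprintf("third_%d", seq_len(cfg$n_meth_samples[["third"]])))
  grp <- rep(c("first", "third"), cfg$n_meth_samples)
  lapply(seq_along(ids), function(j) {
    depth <- stats::rnbinom(ns, size = cfg$depth_size, mu = cfg$depth_mean)
    lv <- if (grp[j] == "first") lev1 else lev3
    n_meth <- stats::rbinom(ns, depth, lv)
    methyl_calls(data.table::data.table(chrom = cp$chrom, pos = cp$pos,
                                        n_meth = n_meth,
                                        n_unmeth = depth - n_meth),
                 sample_id = ids[j], group = grp[j])
  })
}

#' Simulate an RNA-seq count table
#'
#' Gene lengths come from the exon models; baseline expression is
#' log-normal; planted DE genes (including the concordant set) have their
#' third-trimester mean multiplied by the planted fold change, and their
#' baseline is drawn high enough to clear the low-expression filter. Counts
#' are negative-binomial around RPKM-implied means.
#'
#' @param config A `sim_config`.
#' @param genome Result of [simulate_genome()].
#' @return List with `counts` (genes x samples integer matrix), `length_kb`
#'   (named), `total_reads` (named), `groups` (named sample -> group).
#' @export
simulate_counts <- function(config, genome) {
  cfg <- config
  set.seed(cfg$seed + 2L)
  g <- genome$genes
  n <- nrow(g)
  length_kb <- vapply(g$exons, function(e) {
    max(0.2, sum(e$end - e$start + 1) / 1000)
  }, numeric(1))
  names(length_kb) <- g$gene_id

  base <- stats::rlnorm(n, meanlog = log(5), sdlog = 1.5)
  planted <- genome$truth$log2fc != 0
  base[planted] <- stats::rlnorm(sum(planted), meanlog = log(20), sdlog = 0.5)
  mu1 <- base
  mu3 <- base * 2^genome$truth$log2fc

  ids <- c(sprintf("efirst_%d", seq_len(cfg$n_expr_samples[["first"]])),
           sprintf("ethird_%d", seq_len(cfg$n_expr_samples[["third"]])))
  grp <- stats::setNames(rep(c("first", "third"), cfg$n_expr_samples), ids)
  totals <- stats::setNames(round(cfg$total_reads *
                                    stats::runif(length(ids), 0.85, 1.15)),
                            ids)
  counts <- sapply(seq_along(ids), function(j) {
    mu_rpkm <- if (grp[j] == "first") mu1 else mu3
    mu_count <- mu_rpkm * length_kb * totals[j] / 1e6
    stats::rnbinom(n, size = cfg$nb_size, mu = mu_count)
  })
  dimnames(counts) <- list(g$gene_id, ids)
  list(counts = counts, length_kb = length_kb, total_reads = totals,
       groups = grp)
}

#' Planted-effect truth table
#'
#' @param genome Result of [simulate_genome()].
#' @return data.table gene_id, cgi_promoter, promoter_delta (pp), body_delta
#'   (pp), log2fc, planted_class ("null", "dmr_promoter", "dmr_body", "de",
#'   "concordant_anti", "concordant_positive").
#' @export
truth_table <- function(genome) {
  data.table::copy(genome$truth)
}
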