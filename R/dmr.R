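# Regional differential-methylation calling.
#
# A feature (promoter or gene body) is differentially methylated when its
# third-minus-first group-mean difference is at least `min_delta` percentage
# points in magnitude AND it contains at least `min_sig_cpgs` CpGs whose
# per-CpG rank-test p-values survive Benjamini-Hochberg adjustment at
# `alpha`. Gene bodies additionally require every merged fragment containing
# a significant CpG to change in the same direction.

#' Per-CpG rank-test p-values within a feature
#'
#' One exact two-sided Mann-Whitney p-value per assigned CpG, computed on the
#' per-sample methylation percents; missing values are dropped per CpG, and a
#' CpG with fewer than 2 observations in either group gets p = 1.
#'
#' @param mat A `cpg_matrix`.
#' @param site_idx Integer site indices of the feature's CpGs.
#' @return Numeric vector of raw p-values, one per site index.
#' @export
test_cpgs_in_feature <- function(mat, site_idx) {
  gf <- mat$groups == "first"
  vapply(site_idx, function(i) {
    x <- mat$levels[i, gf]; y <- mat$levels[i, !gf]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(1)
    exact_mann_whitney(x, y)$p_value
  }, numeric(1))
}

.feature_delta <- function(mat, site_idx) {
  gm <- .site_group_means(mat)
  m1 <- mean(gm$first[site_idx], na.rm = TRUE)
  m3 <- mean(gm$third[site_idx], na.rm = TRUE)
  c(mean_first = m1, mean_third = m3, delta = m3 - m1)
}

.empty_dmr <- function() {
  list(n_cpgs = 0L, n_sig_cpgs = 0L, mean_first = NA_real_,
       mean_third = NA_real_, delta = NA_real_, direction = NA_character_,
       significant = FALSE, testable = FALSE,
       fragment_directions = character(0))
}

# shared calling core; `require_same_direction` distinguishes gene bodies
.call_feature_dmr <- function(mat, site_idx, regions = NULL, min_delta = 10,
                              alpha = 0.05, min_sig_cpgs = 2,
                              adjust_within = c("feature", "fragment"),
                              require_same_direction = FALSE) {
  adjust_within <- match.arg(adjust_within)
  n <- length(site_idx)
  if (n == 0L) return(.empty_dmr())
  p <- test_cpgs_in_feature(mat, site_idx)
  if (adjust_within == "fragment") {
    if (is.null(regions))
      stop("fragment-wise adjustment requires merged regions")
    frag <- regions$site_region[site_idx]
    padj <- numeric(n)
    for (f in unique(frag)) {
      k <- frag == f
      padj[k] <- benjamini_hochberg(p[k])
    }
  } else {
    frag <- if (is.null(regions)) rep(1L, n) else regions$site_region[site_idx]
    padj <- benjamini_hochberg(p)
  }
  d <- .feature_delta(mat, site_idx)
  n_sig <- sum(padj < alpha)

  gm <- .site_group_means(mat)
  sig_frags <- unique(frag[padj < alpha])
  frag_dir <- vapply(sig_frags, function(f) {
    k <- site_idx[frag == f]
    fd <- mean(gm$third[k], na.rm = TRUE) - mean(gm$first[k], na.rm = TRUE)
    if (is.na(fd)) NA_character_ else if (fd > 0) "hyper" else "hypo"
  }, character(1))
  same_dir <- !require_same_direction || length(frag_dir) == 0L ||
    length(unique(frag_dir[!is.na(frag_dir)])) <= 1L
  testable <- n >= min_sig_cpgs
  list(n_cpgs = n, n_sig_cpgs = n_sig,
       mean_first = unname(d["mean_first"]),
       mean_third = unname(d["mean_third"]), delta = unname(d["delta"]),
       direction = if (is.na(d["delta"])) NA_character_ else
         if (d["delta"] > 0) "hyper" else "hypo",
       significant = testable && abs(d["delta"]) >= min_delta &&
         n_sig >= min_sig_cpgs && same_dir,
       testable = testable,
       fragment_directions = frag_dir)
}

#' Call one differentially methylated promoter
#'
#' BH adjustment is applied within the promoter's own CpG family by default;
#' pass `adjust_within = "fragment"` (with `regions`) to adjust within merged
#' fragments instead.
#'
#' @param mat A `cpg_matrix`.
#' @param site_idx Site indices of the promoter's CpGs.
#' @param min_delta Minimum |group-mean difference| in percentage points.
#' @param alpha FDR threshold for per-CpG significance.
#' @param min_sig_cpgs Minimum number of FDR-significant CpGs.
#' @param adjust_within BH family: "feature" (default) or "fragment".
#' @param regions `merged_regions`, needed for fragment-wise adjustment.
#' @return List with n_cpgs, n_sig_cpgs, mean_first, mean_third, delta,
#'   direction ("hyper"/"hypo"), significant, testable.
#' @export
call_promoter_dmr <- function(mat, site_idx, min_delta = 10, alpha = 0.05,
                              min_sig_cpgs = 2,
                              adjust_within = c("feature", "fragment"),
                              regions = NULL) {
  .call_feature_dmr(mat, site_idx, regions, min_delta, alpha, min_sig_cpgs,
                    match.arg(adjust_within), require_same_direction = FALSE)
}

#' Call one differentially methylated gene body
#'
#' As [call_promoter_dmr()], with BH adjustment applied within each merged
#' fragment's CpG family by default (the regional unit of the analysis), and
#' the extra requirement that every fragment containing at least one
#' FDR-significant CpG changes in the same direction.
#'
#' @param mat A `cpg_matrix`.
#' @param site_idx Site indices of the body's CpGs.
#' @param regions A `merged_regions` over `mat` (fragments).
#' @param min_delta,alpha,min_sig_cpgs As in [call_promoter_dmr()].
#' @param adjust_within BH family: "fragment" (default) or "feature".
#' @return List as in [call_promoter_dmr()] plus `fragment_directions`
#'   (directions of the fragments containing significant CpGs).
#' @export
call_gene_body_dmr <- function(mat, site_idx, regions, min_delta = 10,
                               alpha = 0.05, min_sig_cpgs = 2,
                               adjust_within = c("fragment", "feature")) {
  .call_feature_dmr(mat, site_idx, regions, min_delta, alpha, min_sig_cpgs,
                    match.arg(adjust_within), require_same_direction = TRUE)
}

#' Call DMRs over a set of features
#'
#' Driver applying [call_promoter_dmr()] or [call_gene_body_dmr()] to every
#' feature interval.
#'
#' @param mat A `cpg_matrix`.
#' @param features data.table of intervals (gene_id, feature, chrom, start,
#'   end); `feature` must be all "promoter" or all "gene_body".
#' @param regions `merged_regions` over `mat`; required for gene bodies.
#' @param min_delta,alpha,min_sig_cpgs Calling parameters.
#' @param adjust_within BH family; defaults to "feature" for promoters and
#'   "fragment" for gene bodies.
#' @return data.table: gene_id, feature, chrom, start, end, n_cpgs,
#'   n_sig_cpgs, mean_first, mean_third, delta, direction, significant,
#'   testable.
#' @export
call_dmrs <- function(mat, features, regions = NULL, min_delta = 10,
                      alpha = 0.05, min_sig_cpgs = 2, adjust_within = NULL) {
  kind <- unique(features$feature)
  if (length(kind) != 1L)
    stop("call_dmrs: features must be of a single kind")
  if (kind == "gene_body" && is.null(regions))
    stop("call_dmrs: gene bodies require merged regions (fragments)")
  if (is.null(adjust_within))
    adjust_within <- if (kind == "gene_body") "fragment" else "feature"
  assign <- assign_to_feature(mat, features, regions)
  rows <- lapply(seq_len(nrow(features)), function(i) {
    r <- .call_feature_dmr(mat, assign$sites[[i]], regions, min_delta, alpha,
                           min_sig_cpgs, adjust_within,
                           require_same_direction = kind == "gene_body")
    data.table::data.table(
      gene_id = features$gene_id[i], feature = kind,
      chrom = features$chrom[i], start = features$start[i],
      end = features$end[i], n_cpgs = r$n_cpgs, n_sig_cpgs = r$n_sig_cpgs,
      mean_first = r$mean_first, mean_third = r$mean_third, delta = r$delta,
      direction = r$direction, significant = r$significant,
      testable = r$testable)
  })
  data.table::rbindlist(rows)
}

#' Summarize DMR calls
#'
#' Counts significant features, their hyper/hypo split, and a gene-level
#' rollup where a gene is significant when any of its features is; a gene's
#' direction is taken from its significant feature with the largest |delta|.
#'
#' @param dmrs data.table from [call_dmrs()].
#' @return List with `n_features`, `n_significant`, `n_hyper`, `n_hypo`,
#'   `pct_hyper`, and gene-level `n_genes_significant`, `n_genes_hyper`,
#'   `pct_genes_hyper` (percentages omitted when nothing is significant).
#' @export
summarize_dmrs <- function(dmrs) {
  sig <- dmrs[dmrs$significant]
  n <- nrow(sig)
  out <- list(n_features = nrow(dmrs), n_significant = n,
              n_hyper = sum(sig$direction == "hyper"),
              n_hypo = sum(sig$direction == "hypo"))
  if (n > 0L) {
    out$pct_hyper <- 100 * out$n_hyper / n
    gl <- sig[order(-abs(sig$delta))][!duplicated(gene_id)]
    out$n_genes_significant <- nrow(gl)
    out$n_genes_hyper <- sum(gl$direction == "hyper")
    out$pct_genes_hyper <- 100 * out$n_genes_hyper / nrow(gl)
  }
  out
}
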