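# Methylation-expression integration: expression-ranked bin curves,
# DMR x DE sign concordance with exact binomial tests, baseline-expression
# comparison of concordance classes, and dual-luciferase normalization.

#' Partition genes into equal-size bins of increasing expression
#'
#' Genes are sorted ascending by expression (ties broken by gene id for
#' determinism) and rank r (0-based) goes to bin `floor(r * n_bins / n) + 1`,
#' so bin sizes differ by at most one gene and bin index increases with
#' expression.
#'
#' @param expr Named numeric vector of group-average RPKM (names = gene ids).
#' @param n_bins Number of bins (default 50); must not exceed the number of
#'   genes.
#' @return data.table gene_id, expr, bin (1..n_bins).
#' @export
bin_genes_by_expression <- function(expr, n_bins = 50) {
  n <- length(expr)
  if (n_bins > n)
    stop("bin_genes_by_expression: more bins than genes")
  ord <- order(expr, names(expr))
  r <- seq_len(n) - 1L
  data.table::data.table(gene_id = names(expr)[ord], expr = unname(expr[ord]),
                         bin = as.integer((r * n_bins) %/% n) + 1L)
}

#' Per-bin mean methylation curve
#'
#' Averages a per-gene feature methylation value within each expression bin;
#' genes without a covered feature in the given context are excluded from
#' their bin's mean (not imputed), and bins with no covered gene yield NA.
#'
#' @param bins data.table from [bin_genes_by_expression()].
#' @param feature_meth Named numeric vector: per-gene mean methylation
#'   percent of the feature in the chosen context (NA / absent = no covered
#'   feature).
#' @param context Label stored with the curve (e.g. "promoter_CGI").
#' @param group Trimester group label stored with the curve.
#' @return data.table context, group, bin, n_genes, mean_expr, mean_meth.
#' @export
bin_methylation_curve <- function(bins, feature_meth, context = "all",
                                  group = "first") {
  b <- data.table::copy(bins)
  b[, mean_meth := unname(feature_meth[gene_id])]
  out <- b[, .(n_genes = sum(!is.na(mean_meth)),
               mean_expr = mean(expr),
               mean_meth = if (all(is.na(mean_meth))) NA_real_ else
                 mean(mean_meth, na.rm = TRUE)),
           by = bin]
  out[, `:=`(context = context, group = group)]
  data.table::setcolorder(out, c("context", "group", "bin", "n_genes",
                                 "mean_expr", "mean_meth"))
  out[order(bin)]
}

#' Sign-concordance table of doubly-significant genes
#'
#' For genes significant in BOTH the differential-methylation and the
#' differential-expression analyses, pairs the feature's methylation change
#' (third minus first, percentage points) with the expression log2 ratio and
#' classifies the pair as "anti" (opposite signs) or "positive" (same sign).
#' A gene with several significant features of the kind uses the one with the
#' largest |delta|. Records with either component exactly zero are excluded.
#'
#' @param dmrs data.table from [call_dmrs()].
#' @param de data.table from [call_de()].
#' @param feature "promoter" or "gene_body" (defaults to the kind in `dmrs`).
#' @return data.table gene_id, feature, meth_delta, expr_log2, concordance.
#' @export
concordance_table <- function(dmrs, de, feature = NULL) {
  if (is.null(feature)) feature <- unique(dmrs$feature)[1]
  sig_m <- dmrs[dmrs$significant & dmrs$feature == feature]
  sig_m <- sig_m[order(-abs(sig_m$delta))][!duplicated(gene_id)]
  sig_e <- de[de$significant]
  m <- merge(sig_m[, .(gene_id, meth_delta = delta)],
             sig_e[, .(gene_id, expr_log2 = log2_ratio)], by = "gene_id")
  m <- m[meth_delta != 0 & expr_log2 != 0]
  m[, feature := feature]
  m[, concordance := ifelse(sign(meth_delta) != sign(expr_log2),
                            "anti", "positive")]
  data.table::setcolorder(m, c("gene_id", "feature", "meth_delta",
                               "expr_log2", "concordance"))
  m[order(gene_id)]
}

#' Classify printed (methylation change, expression log2) pairs
#'
#' Convenience for concordance classification of a plain table of pairs.
#'
#' @param meth_delta,expr_log2 Numeric vectors.
#' @return Character vector "anti"/"positive" (NA where a component is zero).
#' @export
classify_concordance <- function(meth_delta, expr_log2) {
  ifelse(meth_delta == 0 | expr_log2 == 0, NA_character_,
         ifelse(sign(meth_delta) != sign(expr_log2), "anti", "positive"))
}

#' Exact binomial test of the anti-correlated fraction
#'
#' Tests whether anti-correlated genes outnumber positively correlated ones
#' beyond chance: exact two-sided binomial test of k = number of
#' anti-correlated records against n = all records at p0 = 0.5.
#'
#' @param records data.table from [concordance_table()].
#' @return A `gm_test` (statistic = n_anti).
#' @export
concordance_test <- function(records) {
  if (nrow(records) == 0L) stop("concordance_test: no records")
  exact_binomial_two_sided(sum(records$concordance == "anti"),
                           nrow(records), 0.5)
}

#' Compare baseline expression between concordance classes
#'
#' Two-sided Mann-Whitney comparison of (log-scale) first-trimester average
#' RPKM between the anti-correlated and positively correlated classes, with
#' per-class medians and quartiles.
#'
#' @param records data.table from [concordance_table()].
#' @param expr_first Named numeric vector of first-trimester average RPKM.
#' @param log_scale Compare on log2 scale (default; the rank test itself is
#'   scale-invariant, the summaries are not).
#' @return List with `test` (a `gm_test`) and `summary` (data.table class, n,
#'   median, q1, q3 on the reported scale).
#' @export
compare_baseline_expression <- function(records, expr_first,
                                        log_scale = TRUE) {
  v <- unname(expr_first[records$gene_id])
  if (log_scale) v <- log2(v)
  a <- v[records$concordance == "anti"]
  p <- v[records$concordance == "positive"]
  if (length(a) < 2 || length(p) < 2)
    stop("compare_baseline_expression: need >= 2 genes per class")
  tst <- exact_mann_whitney(a, p)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  qa <- qs(a); qp <- qs(p)
  list(test = tst,
       summary = data.table::data.table(
         class = c("anti", "positive"), n = c(length(a), length(p)),
         q1 = c(qa[1], qp[1]), median = c(qa[2], qp[2]),
         q3 = c(qa[3], qp[3])))
}

#' Normalize dual-luciferase reporter activity
#'
#' Firefly activity is divided by Renilla activity to normalize for
#' transfection efficiency, then baselined by subtracting the empty-vector
#' firefly:Renilla ratio.
#'
#' @param firefly,renilla Construct activities (renilla > 0).
#' @param firefly_empty,renilla_empty Empty-vector activities
#'   (renilla_empty > 0).
#' @return Normalized activity (firefly/renilla -
#'   firefly_empty/renilla_empty).
#' @export
normalize_luciferase <- function(firefly, renilla, firefly_empty,
                                 renilla_empty) {
  if (any(renilla <= 0) || any(renilla_empty <= 0))
    stop("normalize_luciferase: Renilla activity must be positive")
  firefly / renilla - firefly_empty / renilla_empty
}
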