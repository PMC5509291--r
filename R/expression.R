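# RPKM-based expression quantification and differential expression between
# trimester groups.

#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = gene reads / (total aligned reads x transcript length in kb) x 1e6.
#' Vectorized over all arguments.
#'
#' @param n_gene_reads Aligned reads for the gene(s) (>= 0).
#' @param n_total_reads Total aligned reads of the sample (> 0).
#' @param length_kb Transcript length in kilobases (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1e6, 1)  # 10
#' @export
rpkm <- function(n_gene_reads, n_total_reads, length_kb) {
  if (any(n_total_reads <= 0)) stop("rpkm: total reads must be positive")
  if (any(length_kb <= 0)) stop("rpkm: transcript length must be positive")
  n_gene_reads / (n_total_reads * length_kb) * 1e6
}

#' Floor a group-average RPKM
#'
#' Group averages below the floor are raised to it, so fold changes against
#' lowly expressed genes stay bounded and division by zero is impossible.
#'
#' @param avg Group-average RPKM (>= 0).
#' @param floor Floor value (default 0.5).
#' @return max(avg, floor), elementwise.
#' @export
floor_group_average <- function(avg, floor = 0.5) {
  if (any(avg < 0)) stop("floor_group_average: negative average")
  pmax(avg, floor)
}

#' Build a per-gene expression table from counts
#'
#' Computes per-sample RPKM and raw/floored group-average RPKM.
#'
#' @param counts Integer matrix, genes x samples, with rownames (gene ids) and
#'   colnames (sample ids).
#' @param length_kb Named numeric vector of transcript lengths in kb.
#' @param total_reads Named numeric vector of per-sample total aligned reads;
#'   by default the column sums of `counts`.
#' @param groups Named character vector mapping sample id to
#'   "first"/"third".
#' @param floor RPKM floor applied to group averages.
#' @return An `expression_table`: list with `rpkm` (matrix), `genes`
#'   (data.table gene_id, length_kb, avg_first_raw, avg_third_raw, avg_first,
#'   avg_third, retained), `groups`, `floor`.
#' @export
expression_table <- function(counts, length_kb, total_reads = colSums(counts),
                             groups, floor = 0.5) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  groups <- vapply(groups, .norm_group, character(1))
  if (!all(colnames(counts) %in% names(groups)))
    stop("expression_table: every sample needs a group")
  groups <- groups[colnames(counts)]
  length_kb <- length_kb[rownames(counts)]
  total_reads <- total_reads[colnames(counts)]
  rk <- sweep(counts, 2, total_reads, "/") / length_kb * 1e6
  gf <- groups == "first"
  a1 <- rowMeans(rk[, gf, drop = FALSE])
  a3 <- rowMeans(rk[, !gf, drop = FALSE])
  genes <- data.table::data.table(
    gene_id = rownames(counts), length_kb = as.numeric(length_kb),
    avg_first_raw = a1, avg_third_raw = a3,
    avg_first = floor_group_average(a1, floor),
    avg_third = floor_group_average(a3, floor),
    retained = a1 >= floor | a3 >= floor)
  structure(list(rpkm = rk, genes = genes, groups = groups, floor = floor),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples, %d retained (floor %.2g)\n",
              nrow(x$genes), length(x$groups), sum(x$genes$retained), x$floor))
  invisible(x)
}

#' Filter genes with low expression in both groups
#'
#' A gene is retained iff its raw (pre-floor) group-average RPKM reaches the
#' floor in at least one group.
#'
#' @param tbl An `expression_table`.
#' @return Character vector of retained gene ids.
#' @export
filter_low_expression <- function(tbl) {
  tbl$genes$gene_id[tbl$genes$retained]
}

#' Call differential expression between trimester groups
#'
#' A retained gene is significant when (1) the exact two-sided Mann-Whitney U
#' test on its per-sample RPKM gives p < `p_threshold`, and (2) the ratio of
#' floored group averages (third / first) is >= `fold` or <= 1/`fold`.
#'
#' @param tbl An `expression_table`.
#' @param p_threshold Rank-test p-value cutoff (strict).
#' @param fold Fold-change cutoff (inclusive on both sides).
#' @return data.table with gene_id, avg_first, avg_third (floored),
#'   log2_ratio, p_value, significant, direction ("up"/"down").
#' @export
call_de <- function(tbl, p_threshold = 0.05, fold = 2) {
  g <- tbl$genes[tbl$genes$retained]
  gf <- tbl$groups == "first"
  p <- vapply(g$gene_id, function(id) {
    v <- tbl$rpkm[id, ]
    exact_mann_whitney(v[gf], v[!gf])$p_value
  }, numeric(1))
  ratio <- g$avg_third / g$avg_first
  res <- data.table::data.table(
    gene_id = g$gene_id, avg_first = g$avg_first, avg_third = g$avg_third,
    log2_ratio = log2(ratio), p_value = unname(p),
    significant = p < p_threshold & (ratio >= fold | ratio <= 1 / fold),
    direction = ifelse(ratio > 1, "up", "down"))
  res
}

#' Summarize a differential-expression call set
#'
#' @param de data.table from [call_de()].
#' @param binwidth Bin width of the log2 fold-change histogram over the
#'   significant genes.
#' @return List with `n_significant`, `n_up`, `n_down`, `pct_up`, `pct_down`
#'   and `histogram` (data.table bin_low, bin_high, count); percentages are
#'   omitted when nothing is significant.
#' @export
summarize_de <- function(de, binwidth = 0.25) {
  sig <- de[de$significant]
  n <- nrow(sig)
  if (n == 0L)
    return(list(n_significant = 0L, n_up = 0L, n_down = 0L,
                histogram = data.table::data.table(bin_low = numeric(0),
                                                   bin_high = numeric(0),
                                                   count = integer(0))))
  n_up <- sum(sig$direction == "up")
  lim <- max(abs(sig$log2_ratio))
  breaks <- seq(-ceiling(lim / binwidth) * binwidth,
                ceiling(lim / binwidth) * binwidth, by = binwidth)
  list(n_significant = n, n_up = n_up, n_down = n - n_up,
       pct_up = 100 * n_up / n, pct_down = 100 * (n - n_up) / n,
       histogram = .hist_counts(sig$log2_ratio, breaks))
}

#' Overlay imprinting status on significant genes
#'
#' Joins the differentially expressed genes with an imprinting lookup and
#' returns the significant imprinted genes sorted by log2 ratio ascending.
#'
#' @param de data.table from [call_de()].
#' @param lookup data.frame with gene_id and imprinting_status
#'   ("maternal"/"paternal"/"unknown").
#' @return data.table gene_id, avg_first, avg_third, log2_ratio, direction,
#'   imprinting_status.
#' @export
imprinted_overlay <- function(de, lookup) {
  if (is.null(lookup) || nrow(lookup) == 0L)
    return(data.table::data.table(gene_id = character(0),
                                  avg_first = numeric(0),
                                  avg_third = numeric(0),
                                  log2_ratio = numeric(0),
                                  direction = character(0),
                                  imprinting_status = character(0)))
  sig <- de[de$significant]
  m <- merge(sig, data.table::as.data.table(lookup), by = "gene_id")
  m <- m[order(m$log2_ratio)]
  m[, .(gene_id, avg_first, avg_third, log2_ratio, direction,
        imprinting_status)]
}
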