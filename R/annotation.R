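# Strand-aware gene-model annotation: core promoters, gene bodies,
# exon/intron partitions, CpG-island context, and CpG/region assignment.
#
# All intervals are 1-based closed; BED input (0-based half-open) is
# converted on read. Upstream/downstream are taken in the direction of
# transcription on both strands.

#' Construct a gene-model table
#'
#' @param gene_id,chrom,strand,tss,tts Vectors describing one gene per
#'   element; `strand` is "+" or "-"; `tss < tts` on "+", `tss > tts` on "-".
#' @param exons List of data.frames (start, end) per gene, or NULL for
#'   exon-less models.
#' @param imprinting_status Optional per-gene status
#'   ("maternal", "paternal", "unknown", "none").
#' @return A `gene_models` data.table with an `exons` list-column.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, tts, exons = NULL,
                        imprinting_status = NULL) {
  stopifnot(all(strand %in% c("+", "-")))
  bad <- (strand == "+" & tss >= tts) | (strand == "-" & tss <= tts)
  if (any(bad))
    stop(sprintf("gene_models: tss/tts inconsistent with strand for %s",
                 paste(gene_id[bad], collapse = ", ")))
  if (is.null(exons)) exons <- replicate(length(gene_id), NULL, simplify = FALSE)
  if (is.null(imprinting_status))
    imprinting_status <- rep("none", length(gene_id))
  g <- data.table::data.table(gene_id = as.character(gene_id),
                              chrom = as.character(chrom), strand = strand,
                              tss = as.integer(tss), tts = as.integer(tts),
                              exons = exons,
                              imprinting_status = imprinting_status)
  data.table::setattr(g, "class", c("gene_models", class(g)))
  g
}

#' Read gene models from a flat TSV or BED12 file
#'
#' The flat dialect has a header and columns gene_id, chrom, strand, tss,
#' tts, exon_starts, exon_ends (comma-separated 1-based inclusive
#' coordinates; empty for exon-less models). BED12 rows are converted from
#' 0-based half-open coordinates; the TSS is the strand-dependent 5' end.
#'
#' @param path File path.
#' @param format "tsv" or "bed12".
#' @return A `gene_models` table.
#' @export
read_gene_models <- function(path, format = c("tsv", "bed12")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
    exons <- Map(function(s, e) {
      if (is.na(s) || s == "") return(NULL)
      data.frame(start = as.integer(strsplit(s, ",")[[1]]),
                 end = as.integer(strsplit(e, ",")[[1]]))
    }, d$exon_starts, d$exon_ends)
    names(exons) <- NULL
    gene_models(d$gene_id, d$chrom, d$strand, as.integer(d$tss),
                as.integer(d$tts), exons)
  } else {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
    if (ncol(d) < 12) stop("read_gene_models: BED12 requires 12 columns")
    chromStart <- as.integer(d[[2]])
    chromEnd <- as.integer(d[[3]])
    strand <- d[[6]]
    start1 <- chromStart + 1L        # to 1-based inclusive
    end1 <- chromEnd
    tss <- ifelse(strand == "+", start1, end1)
    tts <- ifelse(strand == "+", end1, start1)
    sizes <- strsplit(d[[11]], ",")
    offs <- strsplit(d[[12]], ",")
    exons <- Map(function(s0, sz, of) {
      sz <- as.integer(sz[sz != ""]); of <- as.integer(of[of != ""])
      data.frame(start = s0 + of + 1L, end = s0 + of + sz)
    }, chromStart, sizes, offs)
    names(exons) <- NULL
    gene_models(d[[4]], d[[1]], strand, tss, tts, exons)
  }
}

#' Read a BED interval file (e.g. a CpG-island track)
#'
#' @param path BED file (0-based half-open); only the first three columns are
#'   used.
#' @return data.table with chrom, start, end in 1-based inclusive coordinates.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "")
  data.table::data.table(chrom = as.character(d[[1]]),
                         start = as.integer(d[[2]]) + 1L,
                         end = as.integer(d[[3]]))
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data.frame with chrom, start, end (1-based inclusive) and
#'   optionally a name column.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  out <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end)
  if (!is.null(intervals$gene_id)) out$name <- intervals$gene_id
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Core promoter intervals
#'
#' The core promoter spans `up` bp upstream to `down` bp downstream of the
#' TSS in the direction of transcription: `[tss - up, tss + down]` on "+",
#' `[tss - down, tss + up]` on "-". Intervals are clipped at position 1.
#'
#' @param genes A `gene_models` table.
#' @param up,down Extent upstream/downstream of the TSS in bp.
#' @return data.table of annotated intervals (gene_id, feature = "promoter",
#'   chrom, start, end, strand).
#' @export
promoter_interval <- function(genes, up = 1000, down = 500) {
  start <- ifelse(genes$strand == "+", genes$tss - up, genes$tss - down)
  end <- ifelse(genes$strand == "+", genes$tss + down, genes$tss + up)
  data.table::data.table(gene_id = genes$gene_id, feature = "promoter",
                         chrom = genes$chrom, start = pmax(1L, as.integer(start)),
                         end = as.integer(end), strand = genes$strand)
}

#' Gene-body intervals
#'
#' The gene body runs from `offset` bp downstream of the TSS to the
#' transcription termination site: `[tss + offset, tts]` on "+",
#' `[tts, tss - offset]` on "-". Genes shorter than `offset` have no body and
#' are omitted.
#'
#' @param genes A `gene_models` table.
#' @param offset Distance (bp) from the TSS at which the body starts.
#' @return data.table of annotated intervals (feature = "gene_body"); zero
#'   rows if no gene is long enough.
#' @export
gene_body_interval <- function(genes, offset = 1000) {
  start <- ifelse(genes$strand == "+", genes$tss + offset, genes$tts)
  end <- ifelse(genes$strand == "+", genes$tts, genes$tss - offset)
  keep <- start <= end
  data.table::data.table(gene_id = genes$gene_id[keep], feature = "gene_body",
                         chrom = genes$chrom[keep],
                         start = as.integer(start[keep]),
                         end = as.integer(end[keep]),
                         strand = genes$strand[keep])
}

#' Exon/intron partition of a gene body
#'
#' Clips the gene's exons to its body interval (dropping exon parts in the
#' first `offset` bp after the TSS) and returns exon and intron pieces that
#' exactly tile the body.
#'
#' @param genes A `gene_models` table (uses the `exons` list-column).
#' @param offset Body offset passed to [gene_body_interval()].
#' @return data.table of intervals with feature "exon" or "intron".
#' @export
exon_intron_partition <- function(genes, offset = 1000) {
  bodies <- gene_body_interval(genes, offset = offset)
  out <- vector("list", nrow(bodies))
  for (i in seq_len(nrow(bodies))) {
    gi <- match(bodies$gene_id[i], genes$gene_id)
    ex <- genes$exons[[gi]]
    b_start <- bodies$start[i]; b_end <- bodies$end[i]
    if (is.null(ex) || nrow(ex) == 0L) {
      out[[i]] <- data.table::data.table(gene_id = bodies$gene_id[i],
                                         feature = "intron",
                                         chrom = bodies$chrom[i],
                                         start = b_start, end = b_end)
      next
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop(sprintf("exon_intron_partition: overlapping exons in %s",
                   bodies$gene_id[i]))
    # clip to the body
    cs <- pmax(ex$start, b_start); ce <- pmin(ex$end, b_end)
    ok <- cs <= ce
    cs <- cs[ok]; ce <- ce[ok]
    pieces <- list()
    cursor <- b_start
    for (k in seq_along(cs)) {
      if (cs[k] > cursor)
        pieces[[length(pieces) + 1L]] <- c("intron", cursor, cs[k] - 1L)
      pieces[[length(pieces) + 1L]] <- c("exon", cs[k], ce[k])
      cursor <- ce[k] + 1L
    }
    if (cursor <= b_end)
      pieces[[length(pieces) + 1L]] <- c("intron", cursor, b_end)
    m <- do.call(rbind, pieces)
    out[[i]] <- data.table::data.table(gene_id = bodies$gene_id[i],
                                       feature = m[, 1],
                                       chrom = bodies$chrom[i],
                                       start = as.integer(m[, 2]),
                                       end = as.integer(m[, 3]))
  }
  data.table::rbindlist(out)
}

#' CpG-island context of intervals
#'
#' An interval is in CGI context iff it overlaps at least one CpG-island
#' interval by at least 1 bp.
#'
#' @param intervals data.frame with chrom, start, end (1-based inclusive).
#' @param cgi_track data.frame with chrom, start, end (1-based inclusive),
#'   e.g. from [read_bed()].
#' @return Character vector, "CGI" or "non_CGI" per interval.
#' @export
cgi_flag <- function(intervals, cgi_track) {
  ifelse(.in_intervals(intervals$chrom, intervals$start, intervals$end,
                       cgi_track),
         "CGI", "non_CGI")
}

#' Assign CpG sites and merged regions to feature intervals
#'
#' A CpG is assigned to a feature when its position lies within the feature
#' interval; a merged region is assigned when at least one of its member CpGs
#' does. A CpG or region may be assigned to features of several genes.
#'
#' @param mat A `cpg_matrix` (supplies the site list).
#' @param features data.table of intervals (gene_id, feature, chrom, start,
#'   end), e.g. from [promoter_interval()].
#' @param regions Optional `merged_regions` over the same matrix.
#' @return List with `sites`: integer list, per feature row the site indices
#'   falling inside it; and `regions` (when supplied): integer list, per
#'   feature row the region ids with >= 1 member CpG inside it.
#' @export
assign_to_feature <- function(mat, features, regions = NULL) {
  nf <- nrow(features)
  site_idx <- rep(list(integer(0)), nf)
  reg_idx <- if (is.null(regions)) NULL else rep(list(integer(0)), nf)
  if (nrow(mat$sites) > 0L && nf > 0L) {
    q <- GenomicRanges::GRanges(mat$sites$chrom,
                                IRanges::IRanges(mat$sites$pos,
                                                 mat$sites$pos))
    s <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start,
                                                 features$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh)) {
      site_idx_raw <- split(qh, sh)
      site_idx[as.integer(names(site_idx_raw))] <-
        lapply(site_idx_raw, function(v) sort(unique(v)))
      if (!is.null(regions)) {
        rr <- split(regions$site_region[qh], sh)
        reg_idx[as.integer(names(rr))] <-
          lapply(rr, function(v) sort(unique(v)))
      }
    }
  }
  list(sites = site_idx, regions = reg_idx)
}
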