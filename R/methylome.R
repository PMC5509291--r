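# Import, filtering and regionalization of per-CpG methylation calls.
#
# Coordinates are 1-based inclusive throughout; a CpG is identified by the
# position of its forward-strand C (inputs are assumed pre-collapsed across
# strands). Methylation levels are percentages in [0, 100].

.default_autosomes <- function() paste0("chr", 1:22)

.norm_group <- function(group) {
  g <- match.arg(tolower(group),
                 c("first", "third", "first_trimester", "third_trimester"))
  if (g %in% c("first", "first_trimester")) "first" else "third"
}

#' Read a per-sample methylation coverage file
#'
#' Reads tab-separated per-CpG bisulfite calls. Two dialects are
#' auto-detected by column count: the Bismark coverage dialect
#' (chrom, start, end, methylation percent, count methylated,
#' count unmethylated; the percent column is ignored and recomputed from the
#' counts) and a plain 4-column dialect (chrom, pos, n_meth, n_unmeth).
#'
#' @param path Path to a TSV file without header.
#' @param sample_id Sample label.
#' @param group Group label, `"first"` or `"third"` trimester
#'   (`"first_trimester"`/`"third_trimester"` accepted).
#' @return A `methyl_calls` object: list with `sample_id`, `group` and
#'   `calls`, a data.table with columns chrom, pos, n_meth, n_unmeth.
#' @export
read_coverage_file <- function(path, sample_id, group) {
  group <- .norm_group(group)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  nc <- ncol(raw)
  if (nc == 6L) {
    calls <- data.table::data.table(
      chrom = raw[[1]],
      pos = suppressWarnings(as.integer(raw[[2]])),
      n_meth = suppressWarnings(as.integer(raw[[5]])),
      n_unmeth = suppressWarnings(as.integer(raw[[6]])))
  } else if (nc == 4L) {
    calls <- data.table::data.table(
      chrom = raw[[1]],
      pos = suppressWarnings(as.integer(raw[[2]])),
      n_meth = suppressWarnings(as.integer(raw[[3]])),
      n_unmeth = suppressWarnings(as.integer(raw[[4]])))
  } else {
    stop(sprintf("read_coverage_file: %s has %d columns; expected 4 or 6",
                 path, nc))
  }
  bad <- which(is.na(calls$pos) | is.na(calls$n_meth) | is.na(calls$n_unmeth) |
                 calls$n_meth < 0 | calls$n_unmeth < 0)
  if (length(bad))
    stop(sprintf("read_coverage_file: malformed row at line %d of %s",
                 bad[1], path))
  dup <- duplicated(calls, by = c("chrom", "pos"))
  if (any(dup))
    stop(sprintf("read_coverage_file: duplicate position %s:%d in %s",
                 calls$chrom[which(dup)[1]], calls$pos[which(dup)[1]], path))
  methyl_calls(calls, sample_id = sample_id, group = group)
}

#' Construct a methylation call set
#'
#' @param calls data.frame with columns chrom, pos, n_meth, n_unmeth (at most
#'   one row per chrom/pos).
#' @param sample_id Sample label.
#' @param group `"first"` or `"third"`.
#' @return A `methyl_calls` object.
#' @export
methyl_calls <- function(calls, sample_id, group) {
  group <- .norm_group(group)
  calls <- data.table::as.data.table(calls)[, c("chrom", "pos", "n_meth",
                                                "n_unmeth"), with = FALSE]
  if (anyDuplicated(calls, by = c("chrom", "pos")))
    stop("methyl_calls: duplicate (chrom, pos)")
  if (any(calls$n_meth < 0 | calls$n_unmeth < 0))
    stop("methyl_calls: negative read counts")
  structure(list(sample_id = as.character(sample_id), group = group,
                 calls = calls), class = "methyl_calls")
}

# natural chromosome order: chr1..chr22, then chrX, chrY, then others
.chrom_order <- function(chroms) {
  u <- unique(chroms)
  num <- suppressWarnings(as.integer(sub("^chr", "", u)))
  sexrank <- match(sub("^chr", "", u), c("X", "Y", "M", "MT"))
  key <- ifelse(!is.na(num), num,
                ifelse(!is.na(sexrank), 1000 + sexrank, 2000))
  u[order(key, u)]
}

#' Filter CpG sites by depth, per-group coverage and autosome status
#'
#' Retains sites with sequencing depth at least `min_depth` in at least
#' `min_samples_per_group` samples of each group; per-sample methylation
#' levels (percent) are stored only where that sample's depth passes
#' `min_depth`, otherwise they are missing. Sex-chromosome sites are dropped
#' when `autosomes_only` is set.
#'
#' @param samples List of `methyl_calls` objects (at least one per group).
#' @param min_depth Minimum per-sample read depth for a usable observation.
#' @param min_samples_per_group Minimum number of passing samples required in
#'   each group for a site to be retained.
#' @param autosomes_only Drop sites not on an autosome.
#' @param autosomes Character vector naming the autosomes of the assembly.
#' @return A `cpg_matrix` object: list with `sites` (data.table chrom, pos in
#'   genomic order), `levels` (sites x samples percent matrix, NA = missing),
#'   `depth` (same shape), `groups` (named character vector sample -> group).
#' @export
filter_sites <- function(samples, min_depth = 10, min_samples_per_group = 3,
                         autosomes_only = TRUE,
                         autosomes = .default_autosomes()) {
  stopifnot(length(samples) >= 2L)
  groups <- vapply(samples, function(s) s$group, character(1))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("filter_sites: duplicate sample ids")
  names(groups) <- ids
  if (!all(c("first", "third") %in% groups))
    stop("filter_sites: need at least one sample in each group")

  tabs <- lapply(seq_along(samples), function(i) {
    dt <- data.table::copy(samples[[i]]$calls)
    dt[, `:=`(sample = ids[i], depth = n_meth + n_unmeth)]
    dt
  })
  all_calls <- data.table::rbindlist(tabs)
  if (autosomes_only) all_calls <- all_calls[chrom %in% autosomes]
  all_calls <- all_calls[depth >= min_depth]
  if (nrow(all_calls) == 0L)
    return(.empty_cpg_matrix(ids, groups))

  all_calls[, level := 100 * n_meth / depth]
  all_calls[, grp := groups[sample]]
  cov <- all_calls[, .(n_first = sum(grp == "first"),
                       n_third = sum(grp == "third")),
                   by = .(chrom, pos)]
  keep <- cov[n_first >= min_samples_per_group &
                n_third >= min_samples_per_group, .(chrom, pos)]
  if (nrow(keep) == 0L)
    return(.empty_cpg_matrix(ids, groups))

  ord <- .chrom_order(keep$chrom)
  keep <- keep[order(match(chrom, ord), pos)]
  keep[, site := .I]
  data.table::setkey(keep, chrom, pos)

  sub <- keep[all_calls, nomatch = NULL, on = c("chrom", "pos")]
  lv <- matrix(NA_real_, nrow = nrow(keep), ncol = length(ids),
               dimnames = list(NULL, ids))
  dp <- matrix(NA_real_, nrow = nrow(keep), ncol = length(ids),
               dimnames = list(NULL, ids))
  j <- match(sub$sample, ids)
  lv[cbind(sub$site, j)] <- sub$level
  dp[cbind(sub$site, j)] <- sub$depth

  structure(list(sites = keep[, .(chrom, pos)], levels = lv, depth = dp,
                 groups = groups,
                 params = list(min_depth = min_depth,
                               min_samples_per_group = min_samples_per_group)),
            class = "cpg_matrix")
}

.empty_cpg_matrix <- function(ids, groups) {
  structure(list(sites = data.table::data.table(chrom = character(0),
                                                pos = integer(0)),
                 levels = matrix(numeric(0), 0, length(ids),
                                 dimnames = list(NULL, ids)),
                 depth = matrix(numeric(0), 0, length(ids),
                                dimnames = list(NULL, ids)),
                 groups = groups, params = list()),
            class = "cpg_matrix")
}

#' @export
print.cpg_matrix <- function(x, ...) {
  cat(sprintf("cpg_matrix: %d sites x %d samples (%d first, %d third)\n",
              nrow(x$sites), length(x$groups), sum(x$groups == "first"),
              sum(x$groups == "third")))
  invisible(x)
}

# per-site per-group mean levels (NA-aware); returns list(first=, third=)
.site_group_means <- function(mat) {
  gf <- mat$groups == "first"
  list(first = rowMeans(mat$levels[, gf, drop = FALSE], na.rm = TRUE),
       third = rowMeans(mat$levels[, !gf, drop = FALSE], na.rm = TRUE))
}

#' Group-mean methylation of one site
#'
#' Arithmetic mean of the available (non-missing) per-sample levels of one
#' group at one retained site; `NA` when no observation is available.
#'
#' @param mat A `cpg_matrix`.
#' @param site Site index (row of `mat$sites`).
#' @param group `"first"` or `"third"`.
#' @return Mean methylation percent, or NA.
#' @export
site_group_mean <- function(mat, site, group) {
  group <- .norm_group(group)
  v <- mat$levels[site, mat$groups == group]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Merge retained CpGs into regions by gap
#'
#' Scans sites in genomic order and starts a new region whenever the distance
#' to the previous CpG is at least `merge_gap` or the chromosome changes, so
#' consecutive CpGs inside a region are strictly less than `merge_gap` apart.
#' The per-group mean of a region is the unweighted mean over member CpGs of
#' the per-CpG group means.
#'
#' @param mat A non-empty `cpg_matrix`.
#' @param merge_gap Gap (bp) at which CpGs are no longer merged; gaps strictly
#'   below this merge.
#' @return A `merged_regions` object: list with `regions` (data.table chrom,
#'   start, end, n_cpgs, mean_first, mean_third, delta) and `site_region`
#'   (integer region id per site of `mat`).
#' @export
merge_regions <- function(mat, merge_gap = 500) {
  s <- mat$sites
  if (nrow(s) == 0L) stop("merge_regions: empty matrix")
  new_chrom <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)])
  gap <- c(Inf, diff(s$pos))
  region_id <- cumsum(new_chrom | gap >= merge_gap)

  gm <- .site_group_means(mat)
  dt <- data.table::data.table(region = region_id, chrom = s$chrom,
                               pos = s$pos, m1 = gm$first, m3 = gm$third)
  regions <- dt[, .(chrom = chrom[1], start = min(pos), end = max(pos),
                    n_cpgs = .N, mean_first = mean(m1, na.rm = TRUE),
                    mean_third = mean(m3, na.rm = TRUE)),
                by = region]
  regions[, delta := mean_third - mean_first]
  regions[, region := NULL]
  structure(list(regions = regions, site_region = region_id,
                 merge_gap = merge_gap), class = "merged_regions")
}

#' @export
print.merged_regions <- function(x, ...) {
  cat(sprintf("merged_regions: %d regions (gap < %d bp), %d member CpGs\n",
              nrow(x$regions), x$merge_gap, length(x$site_region)))
  invisible(x)
}

.hist_counts <- function(v, breaks) {
  v <- v[!is.na(v)]
  # left-closed bins [low, high); the last bin also includes its upper edge
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= length(breaks) - 1]
  data.table::data.table(bin_low = breaks[-length(breaks)],
                         bin_high = breaks[-1],
                         count = tabulate(idx, nbins = length(breaks) - 1))
}

#' Histograms of group-mean methylation and group differences
#'
#' Builds per-group histograms of mean methylation for single CpGs and for
#' merged regions, optionally stratified by CpG-island context, plus the
#' histogram of the third-minus-first difference per site and per region.
#'
#' @param mat A `cpg_matrix`.
#' @param regions A `merged_regions` object from [merge_regions()].
#' @param cgi_track Optional CpG-island track, a data.frame with chrom,
#'   start, end (1-based inclusive); when supplied, histograms are split into
#'   CGI and non-CGI strata (a CpG by position, a region by >= 1 bp overlap).
#' @param binwidth Bin width in percentage points (default 5).
#' @return List with `levels` (data.table unit, context, group, bin_low,
#'   bin_high, count) and `difference` (data.table unit, bin_low, bin_high,
#'   count) histograms.
#' @export
methylation_histograms <- function(mat, regions, cgi_track = NULL,
                                   binwidth = 5) {
  gm <- .site_group_means(mat)
  reg <- regions$regions
  breaks <- seq(0, 100, by = binwidth)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  dbreaks <- seq(-100, 100, by = binwidth)

  if (is.null(cgi_track)) {
    site_ctx <- rep("all", nrow(mat$sites))
    reg_ctx <- rep("all", nrow(reg))
  } else {
    site_ctx <- ifelse(.in_intervals(mat$sites$chrom, mat$sites$pos,
                                     mat$sites$pos, cgi_track),
                       "CGI", "non_CGI")
    reg_ctx <- ifelse(.in_intervals(reg$chrom, reg$start, reg$end, cgi_track),
                      "CGI", "non_CGI")
  }

  lev <- data.table::rbindlist(lapply(unique(site_ctx), function(ctx) {
    i <- site_ctx == ctx
    data.table::rbindlist(lapply(c("first", "third"), function(g) {
      h <- .hist_counts(gm[[g]][i], breaks)
      h[, `:=`(unit = "cpg", context = ctx, group = g)]
    }))
  }))
  rgm <- list(first = reg$mean_first, third = reg$mean_third)
  lev_r <- data.table::rbindlist(lapply(unique(reg_ctx), function(ctx) {
    i <- reg_ctx == ctx
    data.table::rbindlist(lapply(c("first", "third"), function(g) {
      h <- .hist_counts(rgm[[g]][i], breaks)
      h[, `:=`(unit = "region", context = ctx, group = g)]
    }))
  }))
  levels_hist <- data.table::rbindlist(list(lev, lev_r))
  data.table::setcolorder(levels_hist,
                          c("unit", "context", "group", "bin_low", "bin_high",
                            "count"))

  d_site <- .hist_counts(gm$third - gm$first, dbreaks)[, unit := "cpg"]
  d_reg <- .hist_counts(reg$delta, dbreaks)[, unit := "region"]
  difference <- data.table::rbindlist(list(d_site, d_reg))
  data.table::setcolorder(difference, c("unit", "bin_low", "bin_high",
                                        "count"))
  list(levels = levels_hist, difference = difference)
}

#' Per-sample mean methylation over common sites with a group comparison
#'
#' Restricts to sites observed (depth passing the filter) in every sample,
#' computes each sample's mean methylation over those common sites, and
#' compares the two groups with the exact two-sided Mann-Whitney U test.
#'
#' @param mat A `cpg_matrix`.
#' @return List with `sample_means` (named numeric), `n_common_sites`, and
#'   `test` (a `gm_test`).
#' @export
sample_mean_methylation <- function(mat) {
  if (sum(mat$groups == "first") < 2 || sum(mat$groups == "third") < 2)
    stop("sample_mean_methylation: need at least 2 samples per group")
  common <- stats::complete.cases(mat$levels)
  if (!any(common)) stop("sample_mean_methylation: no common sites")
  m <- colMeans(mat$levels[common, , drop = FALSE])
  tst <- exact_mann_whitney(m[mat$groups == "first"],
                            m[mat$groups == "third"])
  list(sample_means = m, n_common_sites = sum(common), test = tst)
}

# TRUE where interval (chrom, start, end) overlaps any track interval by >=1bp
.in_intervals <- function(chrom, start, end, track) {
  if (is.null(track) || nrow(track) == 0L) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  s <- GenomicRanges::GRanges(track$chrom,
                              IRanges::IRanges(track$start, track$end))
  # disjoint chromosome sets are a legitimate all-FALSE case, not a warning
  suppressWarnings(IRanges::overlapsAny(q, s))
}
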