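test_that("coverage files are parsed in both dialects with levels recomputed from counts", {
  f6 <- tempfile()
  writeLines(c("chr1\t100\t100\t70.0\t7\t3",
               "chr1\t200\t200\t0.0\t0\t0"), f6)
  s <- read_coverage_file(f6, "s1", "first")
  expect_equal(s$calls$n_meth, c(7L, 0L))
  expect_equal(s$calls$n_unmeth, c(3L, 0L))
  expect_equal(100 * s$calls$n_meth[1] /
                 (s$calls$n_meth[1] + s$calls$n_unmeth[1]), 70)
  # depth-0 call retained, level undefined
  expect_equal(s$calls$n_meth[2] + s$calls$n_unmeth[2], 0L)

  f4 <- tempfile()
  writeLines("chr2\t500\t4\t6", f4)
  s4 <- read_coverage_file(f4, "s2", "third_trimester")
  expect_equal(s4$group, "third")
  expect_equal(s4$calls$pos, 500L)

  fdup <- tempfile()
  writeLines(c("chr1\t100\t100\t70.0\t7\t3",
               "chr1\t100\t100\t50.0\t5\t5"), fdup)
  expect_error(read_coverage_file(fdup, "s", "first"), "duplicate")

  fbad <- tempfile()
  writeLines(c("chr1\t100\t100\t70.0\t7\t3",
               "chr1\tx\ty\tz\tq\tw"), fbad)
  expect_error(read_coverage_file(fbad, "s", "first"), "line 2")
})

make_samples <- function(depths, chrom = "chr1", pos = 100L) {
  # depths: named list group -> vector of depths, one sample per entry
  out <- list(); k <- 0
  for (g in names(depths)) for (d in depths[[g]]) {
    k <- k + 1
    out[[k]] <- methyl_calls(
      data.frame(chrom = chrom, pos = pos, n_meth = round(d / 2),
                 n_unmeth = d - round(d / 2)),
      sample_id = paste0("s", k), group = g)
  }
  out
}

test_that("site filtering applies depth, per-group coverage, and autosome rules at their boundaries", {
  # depth exactly 10 in exactly 3 samples of each group -> retained
  s <- make_samples(list(first = c(10, 10, 10, 5, 5, 5),
                         third = c(10, 10, 10, 5, 5)))
  m <- filter_sites(s, min_depth = 10, min_samples_per_group = 3)
  expect_equal(nrow(m$sites), 1L)
  # levels stored only where depth passes
  expect_equal(sum(!is.na(m$levels)), 6L)

  # depth 9 everywhere -> dropped
  s9 <- make_samples(list(first = rep(9, 6), third = rep(9, 5)))
  expect_equal(nrow(filter_sites(s9)$sites), 0L)

  # chrX dropped when autosomes_only
  sx <- make_samples(list(first = rep(30, 6), third = rep(30, 5)),
                     chrom = "chrX")
  expect_equal(nrow(filter_sites(sx)$sites), 0L)
  expect_equal(nrow(filter_sites(sx, autosomes_only = FALSE)$sites), 1L)
})

test_that("raising filter thresholds never increases the retained site count", {
  set.seed(5)
  cfg <- sim_config(seed = 5, n_genes = 20)
  genome <- simulate_genome(cfg)
  samples <- simulate_methylome(cfg, genome)
  n_prev <- Inf
  for (md in c(5, 10, 20, 30)) {
    n <- nrow(filter_sites(samples, min_depth = md)$sites)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (ms in 1:5) {
    n <- nrow(filter_sites(samples, min_samples_per_group = ms)$sites)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("region merging follows the strict sub-500bp gap rule", {
  m <- toy_matrix(matrix(50, 2, 3), matrix(50, 2, 3), pos = c(100L, 549L))
  r <- merge_regions(m)
  expect_equal(nrow(r$regions), 1L)
  expect_equal(r$regions$n_cpgs, 2L)

  m2 <- toy_matrix(matrix(50, 2, 3), matrix(50, 2, 3), pos = c(100L, 600L))
  expect_equal(nrow(merge_regions(m2)$regions), 2L)

  m3 <- toy_matrix(matrix(50, 4, 3), matrix(50, 4, 3),
                   pos = c(100L, 400L, 1000L, 1200L))
  r3 <- merge_regions(m3)
  expect_equal(nrow(r3$regions), 2L)
  expect_equal(r3$regions$start, c(100L, 1000L))
  expect_equal(r3$regions$end, c(400L, 1200L))
  expect_equal(r3$site_region, c(1L, 1L, 2L, 2L))
})

test_that("region merging partitions sites, never spans chromosomes, and matches the brute-force oracle", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    chrom <- sort(sample(paste0("chr", 1:3), n, replace = TRUE))
    pos <- unlist(tapply(seq_len(n), chrom, function(ix)
      sort(sample(1:20000, length(ix)))), use.names = FALSE)
    m <- toy_matrix(matrix(50, n, 3), matrix(50, n, 3), pos = pos,
                    chrom = chrom)
    r <- merge_regions(m)
    # partition: every site in exactly one region, totals add up
    expect_equal(sum(r$regions$n_cpgs), n)
    expect_equal(length(r$site_region), n)
    # no region spans chromosomes; same-chrom regions separated by >= gap
    by_reg <- split(seq_len(n), r$site_region)
    for (ix in by_reg) expect_equal(length(unique(chrom[ix])), 1L)
    # oracle equivalence (same grouping up to labels)
    orc <- oracle_merge(chrom, pos)
    expect_equal(length(unique(orc)), nrow(r$regions))
    expect_true(all(tapply(orc, r$site_region,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("re-merging the CpGs of a region reproduces that region (idempotence)", {
  set.seed(21)
  n <- 60
  pos <- sort(sample(1:30000, n))
  m <- toy_matrix(matrix(runif(n * 3, 0, 100), n, 3),
                  matrix(runif(n * 3, 0, 100), n, 3), pos = pos)
  r <- merge_regions(m)
  for (reg in unique(r$site_region)) {
    ix <- which(r$site_region == reg)
    sub <- toy_matrix(m$levels[ix, 1:3, drop = FALSE],
                      m$levels[ix, 4:6, drop = FALSE], pos = pos[ix])
    r2 <- merge_regions(sub)
    expect_equal(nrow(r2$regions), 1L)
    expect_equal(r2$regions$start, r$regions$start[reg])
    expect_equal(r2$regions$end, r$regions$end[reg])
    expect_equal(r2$regions$delta, r$regions$delta[reg])
  }
})

test_that("site and region group means ignore missing values and stay in [0, 100]", {
  m <- toy_matrix(cbind(c(70, 0), c(80, 0), c(NA, 0)),
                  cbind(c(100, 50), c(NA, 50), c(NA, 50)))
  expect_equal(site_group_mean(m, 1, "first"), 75)
  expect_equal(site_group_mean(m, 2, "first"), 0)
  expect_equal(site_group_mean(m, 1, "third"), 100)
  m2 <- toy_matrix(cbind(c(NA, 10)), cbind(c(NA, 20)))
  expect_true(is.na(site_group_mean(m2, 1, "first")))

  set.seed(2)
  n <- 40
  mm <- toy_matrix(matrix(runif(n * 4, 0, 100), n, 4),
                   matrix(runif(n * 3, 0, 100), n, 3),
                   pos = sort(sample(1:5000, n)))
  r <- merge_regions(mm)
  expect_true(all(r$regions$mean_first >= 0 & r$regions$mean_first <= 100))
  expect_true(all(r$regions$mean_third >= 0 & r$regions$mean_third <= 100))
  # unweighted mean over member CpGs of per-CpG group means
  gm1 <- rowMeans(mm$levels[, 1:4])
  expect_equal(r$regions$mean_first,
               as.numeric(tapply(gm1, r$site_region, mean)),
               ignore_attr = TRUE)
})

test_that("methylation histograms bin group means and group differences as expected", {
  m <- toy_matrix(matrix(0, 3, 3), matrix(0, 3, 3))
  r <- merge_regions(m)
  h <- methylation_histograms(m, r)
  first_bin <- h$levels[h$levels$bin_low == 0 & h$levels$unit == "cpg", ]
  expect_true(all(first_bin$count == 3))
  expect_equal(sum(h$levels$count[h$levels$unit == "cpg"]), 6)  # 2 groups
  d0 <- h$difference[h$difference$unit == "cpg" & h$difference$bin_low == 0, ]
  expect_equal(d0$count, 3L)

  # one site 40 vs 60 -> difference entry at +20
  m2 <- toy_matrix(matrix(40, 1, 3), matrix(60, 1, 3))
  h2 <- methylation_histograms(m2, merge_regions(m2))
  d <- h2$difference[h2$difference$unit == "cpg"]
  expect_equal(d$count[d$bin_low == 20], 1L)
  expect_equal(sum(d$count), 1L)
})

test_that("a planted +10pp shift shows up as a +10 mode in the difference histogram", {
  set.seed(31)
  n <- 4000
  base <- runif(n, 20, 70)
  first <- sapply(1:6, function(i) 100 * rbinom(n, 50, base / 100) / 50)
  third <- sapply(1:5, function(i) 100 * rbinom(n, 50, (base + 10) / 100) / 50)
  m <- toy_matrix(first, third, pos = seq_len(n) * 1000L)
  h <- methylation_histograms(m, merge_regions(m))
  d <- h$difference[h$difference$unit == "cpg"]
  # +10 sits exactly on a bin edge, so the modal bin must touch it
  mode_bin <- d$bin_low[which.max(d$count)]
  expect_true(mode_bin %in% c(5, 10))
  gm <- list(first = rowMeans(first), third = rowMeans(third))
  expect_equal(mean(gm$third - gm$first), 10, tolerance = 0.05)
})

test_that("per-sample mean methylation uses common sites and an exact rank test", {
  first <- cbind(rep(1, 3), rep(2, 3), rep(3, 3))
  third <- cbind(rep(4, 3), rep(5, 3), rep(6, 3))
  m <- toy_matrix(first, third)
  r <- sample_mean_methylation(m)
  expect_equal(unname(r$sample_means), 1:6)
  expect_equal(r$test$p_value, 0.1)
  expect_equal(r$n_common_sites, 3L)

  # identical means everywhere -> p = 1
  m2 <- toy_matrix(matrix(50, 4, 3), matrix(50, 4, 3))
  expect_equal(sample_mean_methylation(m2)$test$p_value, 1)

  # sites missing in any sample are excluded from the common set
  lv <- matrix(50, 4, 6); lv[1, 2] <- NA
  m3 <- toy_matrix(lv[, 1:3], lv[, 4:6])
  expect_equal(sample_mean_methylation(m3)$n_common_sites, 3L)

  expect_error(sample_mean_methylation(toy_matrix(matrix(1, 2, 1),
                                                  matrix(2, 2, 3))),
               "2 samples")
})

test_that("planted global hypermethylation is detected by the sample-level rank test", {
  set.seed(77)
  n <- 500
  base <- runif(n, 20, 60)
  first <- sapply(1:6, function(i) 100 * rbinom(n, 40, base / 100) / 40)
  third <- sapply(1:5, function(i) 100 * rbinom(n, 40, (base + 15) / 100) / 40)
  m <- toy_matrix(first, third, pos = seq_len(n) * 1000L)
  expect_lte(sample_mean_methylation(m)$test$p_value, 0.05)
})
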