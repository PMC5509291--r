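toy_genes <- function(strand = "+", tss = 10000L, tts = 20000L,
                      exons = NULL, gene_id = "g1", chrom = "chr1") {
  gene_models(gene_id, chrom, strand, tss, tts,
              exons = if (is.null(exons)) NULL else list(exons))
}

test_that("core promoters are strand-aware and clipped at position 1", {
  expect_equal(unlist(promoter_interval(toy_genes("+"))[, .(start, end)]),
               c(start = 9000L, end = 10500L))
  expect_equal(unlist(promoter_interval(toy_genes("-", tss = 10000L,
                                                  tts = 2000L))[, .(start, end)]),
               c(start = 9500L, end = 11000L))
  p <- promoter_interval(toy_genes("+", tss = 400L, tts = 5000L))
  expect_equal(c(p$start, p$end), c(1L, 900L))
})

test_that("gene bodies start 1kb into the gene and vanish for short genes", {
  b <- gene_body_interval(toy_genes("+"))
  expect_equal(c(b$start, b$end), c(11000L, 20000L))
  expect_equal(nrow(gene_body_interval(toy_genes("+", tss = 10000L,
                                                 tts = 10500L))), 0L)
  bm <- gene_body_interval(toy_genes("-", tss = 20000L, tts = 10000L))
  expect_equal(c(bm$start, bm$end), c(10000L, 19000L))
})

test_that("exon/intron partition tiles the gene body exactly", {
  g <- toy_genes("+", exons = data.frame(start = c(11000, 15000),
                                         end = c(12000, 16000)))
  p <- exon_intron_partition(g)
  expect_equal(p$feature, c("exon", "intron", "exon", "intron"))
  expect_equal(p$start, c(11000L, 12001L, 15000L, 16001L))
  expect_equal(p$end, c(12000L, 14999L, 16000L, 20000L))

  # single exon covering the body -> no introns
  g2 <- toy_genes("+", exons = data.frame(start = 11000, end = 20000))
  expect_equal(exon_intron_partition(g2)$feature, "exon")

  # exon entirely within the first 1 kb is clipped away
  g3 <- toy_genes("+", exons = data.frame(start = 10100, end = 10900))
  p3 <- exon_intron_partition(g3)
  expect_equal(p3$feature, "intron")
  expect_equal(c(p3$start, p3$end), c(11000L, 20000L))

  g4 <- toy_genes("+", exons = data.frame(start = c(11000, 11500),
                                          end = c(12000, 12500)))
  expect_error(exon_intron_partition(g4), "overlapping")
})

test_that("exon/intron partitions of random gene models tile bodies with no gap or overlap", {
  set.seed(13)
  genome <- simulate_genome(sim_config(seed = 13, n_genes = 40))
  parts <- exon_intron_partition(genome$genes)
  bodies <- gene_body_interval(genome$genes)
  for (i in seq_len(nrow(bodies))) {
    p <- parts[parts$gene_id == bodies$gene_id[i]][order(start)]
    expect_equal(p$start[1], bodies$start[i])
    expect_equal(p$end[nrow(p)], bodies$end[i])
    if (nrow(p) > 1) expect_equal(p$start[-1], p$end[-nrow(p)] + 1L)
    expect_equal(sum(p$end - p$start + 1), bodies$end[i] - bodies$start[i] + 1)
  }
})

test_that("promoter and body intervals mirror under coordinate reflection with strand flip", {
  set.seed(17)
  L <- 1000000L
  g <- simulate_genome(sim_config(seed = 17, n_genes = 25))$genes
  flipped <- gene_models(g$gene_id, g$chrom,
                         ifelse(g$strand == "+", "-", "+"),
                         L - g$tss + 1L, L - g$tts + 1L)
  for (pair in list(list(promoter_interval(g), promoter_interval(flipped)),
                    list(gene_body_interval(g),
                         gene_body_interval(flipped)))) {
    a <- pair[[1]]; b <- pair[[2]]
    b <- b[match(a$gene_id, b$gene_id)]
    expect_equal(b$start, L - a$end + 1L)
    expect_equal(b$end, L - a$start + 1L)
  }
})

test_that("CGI context requires at least 1 bp of overlap", {
  prom <- data.frame(chrom = "chr1", start = 9000, end = 10500)
  expect_equal(cgi_flag(prom, data.frame(chrom = "chr1", start = 10400,
                                         end = 11000)), "CGI")
  expect_equal(cgi_flag(prom, data.frame(chrom = "chr1", start = 10501,
                                         end = 11000)), "non_CGI")
  expect_equal(cgi_flag(prom, data.frame(chrom = character(0),
                                         start = integer(0),
                                         end = integer(0))), "non_CGI")
  expect_equal(cgi_flag(prom, data.frame(chrom = "chr2", start = 9000,
                                         end = 10500)), "non_CGI")
})

test_that("CpGs and regions are assigned to features by the member-CpG rule", {
  m <- toy_matrix(matrix(50, 3, 3), matrix(50, 3, 3),
                  pos = c(8000L, 9500L, 9800L))
  r <- merge_regions(m)  # 8000 | {9500, 9800}
  feats <- data.table::data.table(gene_id = "g1", feature = "promoter",
                                  chrom = "chr1", start = 9000L, end = 10500L)
  a <- assign_to_feature(m, feats, r)
  expect_equal(a$sites[[1]], c(2L, 3L))
  expect_equal(a$regions[[1]], 2L)

  # region straddling the boundary with one member inside is assigned
  m2 <- toy_matrix(matrix(50, 3, 3), matrix(50, 3, 3),
                   pos = c(8900L, 9100L, 9300L))
  r2 <- merge_regions(m2)
  expect_equal(nrow(r2$regions), 1L)
  a2 <- assign_to_feature(m2, feats, r2)
  expect_equal(a2$regions[[1]], 1L)

  # region entirely outside is not assigned
  m3 <- toy_matrix(matrix(50, 1, 3), matrix(50, 1, 3), pos = 8000L)
  a3 <- assign_to_feature(m3, feats, merge_regions(m3))
  expect_equal(length(a3$sites[[1]]), 0L)
  expect_equal(length(a3$regions[[1]]), 0L)
})

test_that("feature assignment matches the brute-force all-pairs oracle on random instances", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    chrom <- sample(paste0("chr", 1:3), n, replace = TRUE)
    o <- order(chrom, runif(n))
    sites <- data.table::data.table(chrom = chrom[o],
                                    pos = unlist(tapply(
                                      seq_len(n), chrom[o], function(ix)
                                        sort(sample(1:50000, length(ix)))),
                                      use.names = FALSE))
    m <- toy_matrix(matrix(50, n, 3), matrix(50, n, 3), pos = sites$pos,
                    chrom = sites$chrom)
    nf <- sample(20:100, 1)
    fs <- sample(1:45000, nf)
    feats <- data.table::data.table(
      gene_id = paste0("g", seq_len(nf)), feature = "promoter",
      chrom = sample(paste0("chr", 1:3), nf, replace = TRUE),
      start = fs, end = fs + sample(100:5000, nf, replace = TRUE))
    got <- assign_to_feature(m, feats)$sites
    want <- oracle_assign(m$sites, feats)
    for (k in seq_len(nf)) expect_equal(got[[k]], want[[k]])
  }
})

test_that("gene models and BED round-trip through their file formats", {
  g <- gene_models(c("a", "b"), c("chr1", "chr2"), c("+", "-"),
                   c(1000L, 9000L), c(5000L, 3000L),
                   exons = list(data.frame(start = c(1200, 2500),
                                           end = c(1500, 3000)), NULL))
  tf <- tempfile()
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                    tss = g$tss, tts = g$tts,
                    exon_starts = c("1200,2500", ""),
                    exon_ends = c("1500,3000", ""))
  write.table(out, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- read_gene_models(tf)
  expect_equal(g2$tss, g$tss)
  expect_equal(g2$exons[[1]]$end, c(1500L, 3000L))
  expect_null(g2$exons[[2]])

  bed <- tempfile()
  writeLines("chr1\t999\t1500\tcgi1", bed)
  b <- read_bed(bed)
  expect_equal(c(b$start, b$end), c(1000L, 1500L))
  bed2 <- tempfile()
  write_bed(b, bed2)
  expect_equal(readLines(bed2), "chr1\t999\t1500")

  bed12 <- tempfile()
  writeLines("chr1\t999\t5000\tgeneA\t0\t-\t999\t5000\t0\t2\t200,300\t0,3701",
             bed12)
  g3 <- read_gene_models(bed12, format = "bed12")
  expect_equal(g3$tss, 5000L)
  expect_equal(g3$tts, 1000L)
  expect_equal(g3$exons[[1]]$start, c(1000L, 4701L))
  expect_equal(g3$exons[[1]]$end, c(1199L, 5000L))
})
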