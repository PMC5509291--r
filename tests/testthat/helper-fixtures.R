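# Shared builders and independent brute-force oracles.

# Build a cpg_matrix directly from per-group level matrices (percent, rows =
# sites). Positions default to 1000, 2000, ... on one chromosome.
toy_matrix <- function(first, third, pos = NULL, chrom = NULL) {
  first <- as.matrix(first); third <- as.matrix(third)
  stopifnot(nrow(first) == nrow(third))
  n <- nrow(first)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", n)
  ids <- c(paste0("f", seq_len(ncol(first))), paste0("t", seq_len(ncol(third))))
  lv <- cbind(first, third)
  colnames(lv) <- ids
  structure(list(
    sites = data.table::data.table(chrom = chrom, pos = as.integer(pos)),
    levels = lv, depth = NULL,
    groups = stats::setNames(rep(c("first", "third"),
                                 c(ncol(first), ncol(third))), ids),
    params = list()), class = "cpg_matrix")
}

# flip the group labels of a cpg_matrix
swap_groups <- function(mat) {
  mat$groups <- ifelse(mat$groups == "first", "third", "first")
  mat
}

# write a coverage file in the 6-column dialect
write_cov6 <- function(df, path = tempfile(fileext = ".cov")) {
  out <- data.frame(df$chrom, df$pos, df$pos,
                    ifelse(df$n_meth + df$n_unmeth > 0,
                           100 * df$n_meth / (df$n_meth + df$n_unmeth), 0),
                    df$n_meth, df$n_unmeth)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# independent permutation-exact two-sided Mann-Whitney oracle: enumerates
# group assignments with a recursive subset walk (no rank formula; U counted
# pair by pair) and doubles the smaller inclusive tail.
oracle_mwu <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(ix) u_stat(pool[ix], pool[-ix]))
  u_obs <- u_stat(x, y)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# closed-form doubled-tail binomial oracle via explicit density sums
oracle_binom <- function(k, n) {
  lo <- sum(stats::dbinom(0:k, n, 0.5))
  hi <- sum(stats::dbinom(k:n, n, 0.5))
  min(1, 2 * min(lo, hi))
}

# brute-force O(n^2) single-linkage clustering of positions at gap < thr
oracle_merge <- function(chrom, pos, thr = 500) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && chrom[i] == chrom[j] && abs(pos[i] - pos[j]) < thr) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots[order(chrom, pos)]))
}

# simple all-pairs overlap oracle: site index lists per feature row
oracle_assign <- function(sites, features) {
  lapply(seq_len(nrow(features)), function(i) {
    which(sites$chrom == features$chrom[i] &
            sites$pos >= features$start[i] & sites$pos <= features$end[i])
  })
}
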