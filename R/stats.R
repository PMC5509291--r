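# Exact small-sample statistics used throughout the pipeline.
#
# With 6 vs 5 (methylation) and 5 vs 4 (expression) samples, asymptotic rank
# tests are unreliable and methylation percents are heavily tied, so the
# Mann-Whitney test is computed permutation-exactly (enumeration of all group
# assignments of the observed values) whenever that is feasible.

# cache of combination index matrices, keyed by "n,k"
.combn_cache <- new.env(parent = emptyenv())

.combn_idx <- function(n, k) {
  key <- paste(n, k, sep = ",")
  m <- .combn_cache[[key]]
  if (is.null(m)) {
    m <- utils::combn(n, k)
    .combn_cache[[key]] <- m
  }
  m
}

#' Exact two-sided Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic with mid-ranks for ties and a
#' two-sided p-value. When the number of group assignments
#' \code{choose(n1 + n2, n1)} is at most \code{exact_limit}, the p-value is
#' permutation-exact: every assignment of the observed (possibly tied) values
#' into groups of sizes n1 and n2 is enumerated and the smaller one-sided tail
#' probability is doubled (capped at 1). Beyond the limit, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric vectors of observations for the two groups (non-empty).
#' @param exact_limit Maximum number of enumerated assignments for the exact
#'   path. The default keeps all designs up to roughly 12 vs 12 exact and in
#'   particular the 6-vs-5 and 5-vs-4 designs always exact.
#' @return A list of class \code{gm_test} with elements \code{statistic} (U
#'   for the first sample), \code{p_value}, \code{method} ("exact" or
#'   "normal_approx") and \code{n1}, \code{n2}.
#' @examples
#' exact_mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
exact_mann_whitney <- function(x, y, exact_limit = 200000) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("exact_mann_whitney: both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))                     # mid-ranks under ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (choose(n, n1) <= exact_limit) {
    idx <- .combn_idx(n, n1)
    # rank sum of every possible assignment of n1 of the pooled values
    rs <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rs - n1 * (n1 + 1) / 2
    eps <- 1e-8
    p_lo <- mean(u_all <= u_obs + eps)
    p_hi <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(statistic = u_obs, p_value = p, method = method,
                 n1 = n1, n2 = n2), class = "gm_test")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (a validating front-end to
#' \code{stats::p.adjust(method = "BH")}): with the m p-values sorted
#' ascending, the i-th adjusted value is \code{min_{j >= i} p_(j) * m / j},
#' capped at 1, returned in the original order.
#'
#' @param p Numeric vector of raw p-values, all in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
benjamini_hochberg <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("benjamini_hochberg: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Exact two-sided binomial test
#'
#' For a symmetric null (\code{p0 = 0.5}) the two-sided p-value is the doubled
#' smaller tail, \code{min(1, 2 * min(P(X <= k), P(X >= k)))} under
#' Binomial(n, p0); for \code{p0 != 0.5} the minimum-likelihood two-sided
#' definition (as in \code{stats::binom.test}) is used. At p0 = 0.5 the two
#' definitions coincide.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param p0 Null success probability.
#' @return A list of class \code{gm_test} with \code{statistic} (k),
#'   \code{p_value}, \code{method} = "exact" and \code{n}.
#' @examples
#' exact_binomial_two_sided(19, 25)$p_value  # ~0.0147
#' @export
exact_binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("exact_binomial_two_sided: n must be positive")
  if (k < 0 || k > n) stop("exact_binomial_two_sided: k must be in [0, n]")
  if (p0 == 0.5) {
    p <- min(1, 2 * min(stats::pbinom(k, n, p0),
                        1 - stats::pbinom(k - 1, n, p0)))
  } else {
    d <- stats::dbinom(k, n, p0)
    p <- sum(stats::dbinom(0:n, n, p0)[stats::dbinom(0:n, n, p0) <= d * (1 + 1e-7)])
    p <- min(1, p)
  }
  structure(list(statistic = k, p_value = p, method = "exact", n = n),
            class = "gm_test")
}

#' @export
print.gm_test <- function(x, ...) {
  cat(sprintf("statistic = %g, p = %.4g (%s", x$statistic, x$p_value, x$method))
  if (!is.null(x$n1)) cat(sprintf(", n1 = %d, n2 = %d", x$n1, x$n2))
  if (!is.null(x$n)) cat(sprintf(", n = %d", x$n))
  cat(")\n")
  invisible(x)
}
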