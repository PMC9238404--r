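# Shared statistical primitives: Bray-Curtis dissimilarity, BH adjustment,
# Wilson score intervals, Spearman tests, and the Dunn post hoc test.

#' Bray-Curtis dissimilarity matrix
#'
#' For relative-abundance rows x and y, BC(x, y) = 1 - sum(min(x_i, y_i)),
#' the standard Bray-Curtis dissimilarity on normalized compositions.
#'
#' @param a an `abundance_table` or a numeric matrix with samples in rows.
#' @return Symmetric dissimilarity matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
bray_curtis <- function(a) {
  m <- if (inherits(a, "abundance_table")) a$values else as.matrix(a)
  if (nrow(m) < 2) stop("need at least 2 samples")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - sum(pmin(m[i, ], m[j, ]))
    }
  }
  d
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values in the input order; NA entries are preserved
#' and ignored in the adjustment.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param rate observed proportion in \[0, 1\].
#' @param n number of trials (>= 1).
#' @param level confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(lo, hi)` with bounds in \[0, 1\].
#' @export
wilson_interval <- function(rate, n, level = 0.95) {
  if (any(n < 1)) stop("n must be >= 1")
  stopifnot(level > 0, level < 1, all(rate >= 0), all(rate <= 1))
  z <- stats::qnorm(1 - (1 - level) / 2)
  z2 <- z^2
  centre <- (rate + z2 / (2 * n)) / (1 + z2 / n)
  half <- z * sqrt(rate * (1 - rate) / n + z2 / (4 * n^2)) / (1 + z2 / n)
  lo <- pmax(0, centre - half)
  hi <- pmin(1, centre + half)
  if (length(rate) == 1L) c(lo = lo, hi = hi) else cbind(lo = lo, hi = hi)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes the tie-corrected Spearman rho (Pearson correlation of average
#' ranks) and a two-sided p-value from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom. Returns
#' NA rho when fewer than 3 observations remain or either vector is constant.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `rho`, `p`, and `n`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Kruskal-Wallis omnibus test with Dunn post hoc comparisons
#'
#' Runs the Kruskal-Wallis rank-sum test across groups, followed by pairwise
#' Dunn z-tests on the joint ranks with a tie correction, adjusted by
#' Benjamini-Hochberg within the pairwise family.
#'
#' @param x numeric response vector.
#' @param g grouping factor (or vector coercible to one).
#' @return List with `kruskal` (htest) and `pairs`, a data.frame with one row
#'   per group pair: `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups")
  kw <- stats::kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  lev <- levels(g)
  combs <- utils::combn(lev, 2)
  zs <- ps <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    zs[k] <- (mean_r[[i]] - mean_r[[j]]) / se
    ps[k] <- 2 * stats::pnorm(-abs(zs[k]))
  }
  data.frame(group1 = combs[1, ], group2 = combs[2, ],
             z = zs, p = ps, p_adj = bh_adjust(ps),
             stringsAsFactors = FALSE) -> pairs
  list(kruskal = kw, pairs = pairs)
}
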