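# Statistical primitives shared by all pipeline stages. Each is a thin,
# validated interface over the corresponding classical test; conventions
# (two-sided p, midranks, conditional-MLE odds ratio) are fixed here so
# downstream modules never call the underlying tests directly.

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' is the two-sided asymptotic (Kolmogorov distribution) approximation,
#' appropriate for the large samples this pipeline compares.
#'
#' @param x,y Numeric vectors, each with at least one value.
#' @return List with `statistic` (D in `[0, 1]`) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L)
    stop("ks_two_sample: both samples must be non-empty")
  # ties only affect the p approximation; D itself is well defined
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA with `k - 1` and `N - k` degrees
#' of freedom. When the within-group sum of squares is exactly zero while
#' group means differ, F is infinite; the result is returned with
#' `p_value = 0` and `degenerate = TRUE` rather than NaN.
#'
#' @param groups List of numeric vectors, each with at least two values.
#' @return List with `statistic` (F), `p_value`, `df` (length-2),
#'   `degenerate` flag.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L)
    stop("anova_oneway: need at least two groups")
  if (any(lengths(groups) < 2L))
    stop("anova_oneway: every group needs at least two values")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    stop("anova_oneway: all values identical, no variance to partition")
  k <- length(groups)
  n <- length(values)
  gm <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  ss_between <- sum(lengths(groups) * (gm - mean(values))^2)
  df <- c(k - 1L, n - k)
  if (ss_within == 0) {
    return(list(statistic = Inf, p_value = 0, df = df, degenerate = TRUE))
  }
  f <- (ss_between / df[1]) / (ss_within / df[2])
  list(statistic = f,
       p_value = stats::pf(f, df[1], df[2], lower.tail = FALSE),
       df = df, degenerate = FALSE)
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' U counts the pairs `(i, j)` with `x_i > y_j`, ties counted as 1/2
#' (midrank convention), so `U = 0` when every x lies below every y. The
#' p-value is the two-sided normal approximation with tie-corrected
#' variance and no continuity correction.
#'
#' @param x,y Numeric vectors, each with at least one value.
#' @return List with `statistic` (U for the first sample) and `p_value`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L)
    stop("mann_whitney: both samples must be non-empty")
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' The odds-ratio estimate is the conditional maximum-likelihood estimate
#' given the table margins (the `fisher.test` convention); the simple
#' cross-product `ad/bc` is also reported. The two-sided p-value sums the
#' hypergeometric probabilities of all tables, with the observed margins,
#' at most as probable as the observed one.
#'
#' @param a,b,c,d Cell counts. Rows are the two strata (e.g. ordered /
#'   disordered), columns the two outcomes (e.g. neighbor yes / no), so
#'   the table is `rbind(c(a, b), c(c, d))`.
#' @return List with `odds_ratio` (conditional MLE; 0 or `Inf` at the
#'   boundary), `sample_odds_ratio` (`ad/bc`), `p_value` and `conf_int`
#'   (95% interval for the odds ratio).
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("fisher_exact: cells must be nonnegative integers")
  if (sum(cells) == 0) stop("fisher_exact: empty table")
  tab <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("fisher_exact: zero margin, odds ratio undefined")
  res <- stats::fisher.test(tab)
  sample_or <- (a * d) / (b * c)  # Inf/NaN at empty cells, by design
  list(odds_ratio = .fisher_cmle(a, b, c, d),
       sample_odds_ratio = sample_or,
       p_value = res$p.value,
       conf_int = unname(res$conf.int))
}

# Conditional MLE of the odds ratio given both table margins: the root of
# the noncentral-hypergeometric score equation E[A | psi] = a, solved to
# high precision (fisher.test solves the same equation but with a loose
# root tolerance).
.fisher_cmle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0L, k - n2):min(k, m)
  if (a == min(xs)) return(0)
  if (a == max(xs)) return(Inf)
  lw0 <- lchoose(m, xs) + lchoose(n2, k - xs)
  cond_mean <- function(lpsi) {
    lw <- lw0 + xs * lpsi
    w <- exp(lw - max(lw))
    sum(xs * w) / sum(w) - a
  }
  exp(stats::uniroot(cond_mean, c(-40, 40), tol = 1e-12)$root)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values; order-preserving, each `q >= p`, monotone
#' after sorting by p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
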