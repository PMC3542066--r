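# Independent brute-force oracles used to verify the statistical
# primitives. These deliberately share no code with the package
# implementations.

# KS D: scan |ECDF_x - ECDF_y| at every point of the pooled sample.
ks_oracle_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# Mann-Whitney U for x: count pairs with x > y, ties as 1/2.
mw_oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# One-way ANOVA F from the explicit sum-of-squares decomposition.
anova_oracle_f <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups); n <- length(all)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Fisher's exact test by exhaustive hypergeometric enumeration over all
# tables with the observed margins: two-sided p by probability-mass
# ordering (with R's relative-error guard), odds ratio by maximizing the
# noncentral hypergeometric conditional likelihood.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(k, m)
  px <- dhyper(xs, m, n2, k)
  pobs <- dhyper(a, m, n2, k)
  p <- sum(px[px <= pobs * (1 + 1e-7)])
  logsumexp <- function(w) { mx <- max(w); mx + log(sum(exp(w - mx))) }
  loglik <- function(lpsi) {
    base <- lchoose(m, xs) + lchoose(n2, k - xs) + xs * lpsi
    lchoose(m, a) + lchoose(n2, k - a) + a * lpsi - logsumexp(base)
  }
  or <- if (a == min(xs)) 0
        else if (a == max(xs)) Inf
        else exp(stats::optimize(loglik, c(-25, 25), maximum = TRUE,
                                 tol = 1e-10)$maximum)
  list(odds_ratio = or, p_value = p)
}

# Benjamini-Hochberg step-up adjusted values, straight from the formula.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# Small random site table for parser and filter tests.
random_site_table <- function(n = 10, protein = "P1", start = 10, gap = 9) {
  pos <- start + gap * seq_len(n)
  tab <- data.frame(protein_id = protein, position = as.integer(pos),
                    residue = sample(c("S", "T", "Y"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  for (rc in c("ratio_g1", "ratio_g1s", "ratio_es",
               "ratio_ls", "ratio_g2", "ratio_m"))
    tab[[rc]] <- round(runif(n, 0.2, 3), 4)
  tab
}
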