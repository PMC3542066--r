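# Sequence-window statistics around phospho-sites: +/-6 flanking windows,
# the two-sample logo comparison of low- versus high-variability sites,
# composition profiling against a background set, and the enrichment of
# proximal (multi-)phosphorylation in disordered regions.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Extract the flanking window of a phospho-site
#'
#' Returns the `2*halfwidth + 1` residues centred on the site; offsets
#' beyond the protein termini are `NA` (missing) and are excluded from
#' all per-position statistics downstream.
#'
#' @param sequence Protein sequence (character scalar).
#' @param position 1-based position of the phospho-residue; must be
#'   S, T or Y.
#' @param halfwidth Window half-width (default 6, a 13-residue window).
#' @return Character vector of length `2*halfwidth + 1`, named by offset
#'   (`"-6"` .. `"6"`), `NA` where the window runs off the sequence.
#' @export
extract_flank <- function(sequence, position, halfwidth = 6L) {
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop("extract_flank: position ", position, " outside sequence (1..",
         n, ")")
  centre <- substring(sequence, position, position)
  if (!centre %in% c("S", "T", "Y"))
    stop("extract_flank: residue at position ", position, " is '",
         centre, "', not S/T/Y")
  offs <- seq(-halfwidth, halfwidth)
  pos <- position + offs
  out <- rep(NA_character_, length(offs))
  inside <- pos >= 1L & pos <= n
  out[inside] <- substring(sequence, pos[inside], pos[inside])
  names(out) <- as.character(offs)
  out
}

#' Flanking windows for every site of a table
#'
#' @param sites Site table.
#' @param seqs Named character vector of protein sequences.
#' @param halfwidth Window half-width.
#' @return Character matrix, one row per site, `2*halfwidth + 1` columns
#'   named by offset.
#' @export
flank_windows <- function(sites, seqs, halfwidth = 6L) {
  validate_sites_against_sequences(sites, seqs)
  t(mapply(function(p, pos) extract_flank(seqs[[p]], pos, halfwidth),
           sites$protein_id, sites$position))
}

# Welch t-test on two binary indicator vectors given counts; falls back
# to a pooled two-proportion z-test when both group variances vanish.
.indicator_test <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  s1 <- n1 * p1 * (1 - p1) / (n1 - 1)  # sample variance of the indicator
  s2 <- n2 * p2 * (1 - p2) / (n2 - 1)
  if (s1 == 0 && s2 == 0) {
    if (p1 == p2) return(1)
    pp <- (k1 + k2) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    return(2 * stats::pnorm(-abs(z)))
  }
  se2 <- s1 / n1 + s2 / n2
  tval <- (p1 - p2) / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(tval), df)
}

#' Two-sample logo statistics
#'
#' For every flank offset (excluding the centre) and every amino acid,
#' compares the frequency of that residue between the low-variability
#' (positive) and high-variability (negative) window sets with a Welch
#' two-sample t-test on the 0/1 indicator vectors; when both indicator
#' vectors are constant the test degenerates and a pooled two-proportion
#' z-test is used instead. `delta_freq = f_low - f_high`; positions with
#' `p < alpha` are flagged ENRICHED (positive delta, i.e. more frequent
#' around low-variability sites) or DEPLETED.
#'
#' @param low_windows,high_windows Character matrices from
#'   [flank_windows()] for the two site sets (at least two rows each).
#' @param alpha Significance level (uncorrected by default).
#' @param correction `"none"` or `"bonferroni"` across the
#'   (offset, amino-acid) cells.
#' @return `data.frame` with `offset`, `aa`, `f_low`, `f_high`,
#'   `delta_freq`, `p_value`, `flag`.
#' @export
two_sample_logo <- function(low_windows, high_windows, alpha = 0.05,
                            correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (nrow(low_windows) < 2L || nrow(high_windows) < 2L)
    stop("two_sample_logo: each set needs at least two windows")
  stopifnot(identical(colnames(low_windows), colnames(high_windows)))
  offs <- colnames(low_windows)
  offs <- offs[offs != "0"]
  grid <- expand.grid(offset = as.integer(offs), aa = AA20,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  f_low <- f_high <- p <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    col <- as.character(grid$offset[i])
    lo <- low_windows[, col]; hi <- high_windows[, col]
    lo <- lo[!is.na(lo)]; hi <- hi[!is.na(hi)]
    n1 <- length(lo); n2 <- length(hi)
    if (n1 < 2L || n2 < 2L) { f_low[i] <- f_high[i] <- NA; p[i] <- NA; next }
    k1 <- sum(lo == grid$aa[i]); k2 <- sum(hi == grid$aa[i])
    f_low[i] <- k1 / n1; f_high[i] <- k2 / n2
    p[i] <- .indicator_test(k1, n1, k2, n2)
  }
  if (correction == "bonferroni")
    p <- pmin(1, p * sum(!is.na(p)))
  delta <- f_low - f_high
  flag <- rep("NONE", nrow(grid))
  sig <- !is.na(p) & p < alpha
  flag[sig & delta > 0] <- "ENRICHED"
  flag[sig & delta < 0] <- "DEPLETED"
  data.frame(grid, f_low = f_low, f_high = f_high, delta_freq = delta,
             p_value = p, flag = flag, stringsAsFactors = FALSE)
}

#' Composition profile of a window set against a background
#'
#' For every amino acid, the fractional frequency difference
#' `(P - Q) / Q` between the pooled flank residues of the query windows
#' (P) and the background windows (Q), with a percentile bootstrap
#' confidence interval obtained by resampling windows (rows) of both
#' sets. An amino acid absent from the background has an undefined
#' profile value and is returned as `NA` with `defined = FALSE`.
#'
#' @param windows,background_windows Character matrices from
#'   [flank_windows()].
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level of the percentile interval.
#' @param include_centre Include the offset-0 column (default FALSE).
#' @return `data.frame` with `aa`, `p_freq`, `q_freq`, `rel_diff`,
#'   `ci_lo`, `ci_hi`, `defined`, `significant` (CI excludes 0).
#' @export
composition_profile <- function(windows, background_windows,
                                n_boot = 1000L, conf = 0.95,
                                include_centre = FALSE) {
  if (nrow(windows) < 1L || nrow(background_windows) < 1L)
    stop("composition_profile: both sets must be non-empty")
  keep <- function(m) {
    cols <- colnames(m)
    if (!include_centre) m <- m[, cols != "0", drop = FALSE]
    m
  }
  w <- keep(windows); b <- keep(background_windows)
  freq <- function(m, rows) {
    x <- as.vector(m[rows, , drop = FALSE])
    x <- x[!is.na(x)]
    tab <- table(factor(x, levels = AA20))
    as.numeric(tab) / max(1L, length(x))
  }
  p_freq <- freq(w, seq_len(nrow(w)))
  q_freq <- freq(b, seq_len(nrow(b)))
  defined <- q_freq > 0
  rel <- ifelse(defined, (p_freq - q_freq) / q_freq, NA_real_)
  boot <- matrix(NA_real_, n_boot, length(AA20))
  for (r in seq_len(n_boot)) {
    pw <- freq(w, sample.int(nrow(w), replace = TRUE))
    qw <- freq(b, sample.int(nrow(b), replace = TRUE))
    boot[r, ] <- ifelse(qw > 0, (pw - qw) / qw, NA_real_)
  }
  a <- (1 - conf) / 2
  ci <- apply(boot, 2, function(col)
    if (all(is.na(col))) c(NA_real_, NA_real_)
    else stats::quantile(col, c(a, 1 - a), na.rm = TRUE, names = FALSE))
  data.frame(aa = AA20, p_freq = p_freq, q_freq = q_freq, rel_diff = rel,
             ci_lo = ci[1, ], ci_hi = ci[2, ], defined = defined,
             significant = defined & !is.na(ci[1, ]) &
               (ci[1, ] > 0 | ci[2, ] < 0),
             stringsAsFactors = FALSE)
}

#' Flag sites having a neighboring phospho-site
#'
#' A neighbor is another phospho-site of the same protein within
#' `w` residues of the central site (|position difference| <= w).
#'
#' @param sites Site table whose rows are flagged.
#' @param w Neighbor distance cut-off (the study used 1..5).
#' @param pool Optional site table providing the set of phospho-sites
#'   neighbors are drawn from (defaults to `sites` itself); a site is
#'   never its own neighbor.
#' @return Logical vector along the rows of `sites`.
#' @export
find_neighbors <- function(sites, w, pool = NULL) {
  if (!is.numeric(w) || length(w) != 1L || w < 1)
    stop("find_neighbors: w must be a positive integer")
  if (is.null(pool)) pool <- sites
  out <- logical(nrow(sites))
  pool_by_prot <- split(pool$position, pool$protein_id)
  for (pid in unique(sites$protein_id)) {
    i <- which(sites$protein_id == pid)
    ppos <- pool_by_prot[[pid]]
    if (is.null(ppos)) next
    out[i] <- vapply(sites$position[i], function(p) {
      d <- abs(ppos - p)
      any(d <= w & d > 0)
    }, logical(1))
  }
  out
}

#' Enrichment of multi-phospho-sites in disordered regions
#'
#' Builds, for each distance cut-off, the 2x2 table of ordered /
#' disordered sites with and without a neighboring phospho-site, and
#' tests enrichment with Fisher's exact test. When a table cell is empty
#' the conditional-MLE odds ratio is reported at its boundary value
#' (0 or `Inf`) as an upper/lower-bound marker.
#'
#' @param classified Site table with a `category2` column.
#' @param w Vector of distance cut-offs (default 1:5).
#' @param pool Optional neighbor pool passed to [find_neighbors()]
#'   (e.g. all detected sites rather than the filtered analysis set).
#' @return `data.frame` with one row per `w`: the four cells
#'   (`dis_nb`, `dis_no`, `ord_nb`, `ord_no`), `odds_ratio`,
#'   `sample_odds_ratio`, `p_value`, `ci_lo`, `ci_hi`. The odds ratio is
#'   oriented so values > 1 mean neighbors are enriched among
#'   disordered sites.
#' @export
neighbor_enrichment <- function(classified, w = 1:5, pool = NULL) {
  c2 <- as.character(classified$category2)
  if (!all(CATEGORY2_LEVELS %in% c2))
    stop("neighbor_enrichment: both ordered and disordered sites required")
  res <- lapply(w, function(wi) {
    nb <- find_neighbors(classified, wi, pool = pool)
    dis <- c2 == "DISORDERED"
    a <- sum(dis & nb);  b <- sum(dis & !nb)
    c_ <- sum(!dis & nb); d <- sum(!dis & !nb)
    ft <- fisher_exact(a, b, c_, d)
    data.frame(w = wi, dis_nb = a, dis_no = b, ord_nb = c_, ord_no = d,
               odds_ratio = ft$odds_ratio,
               sample_odds_ratio = ft$sample_odds_ratio,
               p_value = ft$p_value,
               ci_lo = ft$conf_int[1], ci_hi = ft$conf_int[2])
  })
  do.call(rbind, res)
}
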