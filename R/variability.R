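# Per-site phosphorylation variability: the standard deviation of the six
# cell-cycle-phase ratios, plus the completeness filters that define the
# analysis set and the low/high split used by the sequence-logo stage.

#' Phosphorylation variability of one site
#'
#' Standard deviation of the phase ratios over the non-missing time
#' points. The sample (n-1) denominator is the default, matching the
#' convention of standard statistical tooling; a population (n)
#' denominator is available for sensitivity analysis.
#'
#' @param ratios Numeric vector of phase ratios (typically length 6),
#'   `NA` for missing phases; at least two non-missing values required.
#' @param population Use the population (n) denominator instead of n-1.
#' @param log2_transform Compute the SD on `log2(ratios)` instead of the
#'   raw ratios (off by default; zeros become `-Inf` and are rejected).
#' @return Nonnegative scalar.
#' @export
compute_variability <- function(ratios, population = FALSE,
                                log2_transform = FALSE) {
  r <- ratios[!is.na(ratios)]
  if (length(r) < 2L)
    stop("compute_variability: need at least two non-missing ratios")
  if (log2_transform) {
    if (any(r <= 0))
      stop("compute_variability: log2 transform requires positive ratios")
    r <- log2(r)
  }
  s <- stats::sd(r)
  if (population) s <- s * sqrt((length(r) - 1) / length(r))
  s
}

#' Add a variability column to a site table
#'
#' @param sites Site table with the six ratio columns.
#' @inheritParams compute_variability
#' @return `sites` with a numeric `variability` column (`NA` where fewer
#'   than two ratios are available).
#' @export
add_variability <- function(sites, population = FALSE,
                            log2_transform = FALSE) {
  rm_ <- as.matrix(sites[RATIO_COLS])
  k <- rowSums(!is.na(rm_))
  v <- rep(NA_real_, nrow(sites))
  ok <- which(k >= 2L)
  v[ok] <- apply(rm_[ok, , drop = FALSE], 1, compute_variability,
                 population = population, log2_transform = log2_transform)
  sites$variability <- v
  sites
}

#' Filter sites by time-point completeness
#'
#' The primary analysis set keeps only sites quantified in all six
#' phases (`min_timepoints = 6`). Robustness subsets use either at least
#' `k` ("at_least", the default) or exactly `k` ("exactly") non-missing
#' ratios; variability is then computed over the available points.
#'
#' @param sites Site table.
#' @param min_timepoints Integer in 2..6.
#' @param mode `"at_least"` or `"exactly"`.
#' @return The filtered site table.
#' @export
filter_complete <- function(sites, min_timepoints = 6L,
                            mode = c("at_least", "exactly")) {
  mode <- match.arg(mode)
  if (!is.numeric(min_timepoints) || length(min_timepoints) != 1L ||
      min_timepoints < 2 || min_timepoints > 6)
    stop("filter_complete: min_timepoints must lie in 2..6")
  k <- rowSums(!is.na(as.matrix(sites[RATIO_COLS])))
  keep <- if (mode == "at_least") k >= min_timepoints else k == min_timepoints
  sites[keep, , drop = FALSE]
}

#' Split sites into low- and high-variability sets
#'
#' The threshold is the empirical `q`-quantile (type-7 linear
#' interpolation) of the variability values; sites at or below the
#' threshold go to the low set, sites above it to the high set, so ties
#' at the threshold fall low.
#'
#' @param sites Site table with a `variability` column (see
#'   [add_variability()]), or a bare numeric vector.
#' @param q Quantile in (0, 1); default 0.5 (median split).
#' @return List with `low`, `high` (same type as the input) and
#'   `threshold`.
#' @export
split_by_variability <- function(sites, q = 0.5) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("split_by_variability: q must lie strictly in (0, 1)")
  v <- if (is.data.frame(sites)) sites$variability else sites
  if (is.null(v)) stop("split_by_variability: no variability column")
  ok <- !is.na(v)
  if (sum(ok) < 2L)
    stop("split_by_variability: need at least two sites with variability")
  if (length(unique(v[ok])) == 1L)
    stop("split_by_variability: all variabilities identical, no split possible")
  thr <- unname(stats::quantile(v[ok], probs = q, type = 7))
  lo <- ok & v <= thr
  hi <- ok & v > thr
  if (is.data.frame(sites)) {
    list(low = sites[lo, , drop = FALSE],
         high = sites[hi, , drop = FALSE], threshold = thr)
  } else {
    list(low = v[lo], high = v[hi], threshold = thr)
  }
}
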