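# Kinase recognition motifs over the +/-6 site window and the rank-based
# two-dimensional annotation enrichment locating each motif's substrate
# set in (phosphorylation variability, disorder) space.

#' Parse a kinase motif pattern
#'
#' Grammar: tokens separated by `-`, read left to right; exactly one
#' token is the phospho-accepting centre, marked by a `p` prefix (e.g.
#' `pS`, `pS/pT`). Tokens before the centre occupy offsets -1, -2, ...
#' outwards; tokens after it +1, +2, ... A token is a single residue
#' letter, `X` (any residue), a `/`-separated alternative list, or a
#' bracketed set like `[ST]`. Example: `R-X-X-pS/pT` puts R at -3, any
#' residue at -2 and -1, and accepts S or T at the centre.
#'
#' @param name Motif name.
#' @param pattern Pattern string.
#' @return Object of class `motif_definition`: list with `name`,
#'   `offsets` (integer vector) and `allowed` (list of character vectors
#'   of permitted residues, parallel to `offsets`; offset 0 is the
#'   centre).
#' @export
parse_motif <- function(name, pattern) {
  tokens <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (!length(tokens) || any(!nzchar(tokens)))
    stop("motif '", name, "': empty token in pattern '", pattern, "'")
  is_centre <- vapply(tokens, function(tk)
    any(startsWith(strsplit(tk, "/", fixed = TRUE)[[1]], "p")),
    logical(1))
  if (sum(is_centre) != 1L)
    stop("motif '", name, "': pattern must contain exactly one ",
         "phospho-accepting centre token (p-prefixed), found ",
         sum(is_centre))
  ci <- which(is_centre)
  offsets <- seq_along(tokens) - ci
  if (any(abs(offsets) > 6L))
    stop("motif '", name, "': offsets must lie within -6..+6")
  parse_token <- function(tk, centre) {
    alts <- strsplit(tk, "/", fixed = TRUE)[[1]]
    res <- character(0)
    for (a in alts) {
      if (centre) {
        if (!startsWith(a, "p"))
          stop("motif '", name, "': centre alternatives must all be ",
               "p-prefixed in token '", tk, "'")
        a <- substring(a, 2)
      }
      if (a == "X") { res <- c(res, AA20); next }
      if (grepl("^\\[[A-Z]+\\]$", a)) {
        res <- c(res, strsplit(gsub("\\[|\\]", "", a), "")[[1]]); next
      }
      if (!grepl("^[A-Z]$", a))
        stop("motif '", name, "': cannot parse token '", tk, "'")
      res <- c(res, a)
    }
    res <- unique(res)
    if (any(!res %in% AA20))
      stop("motif '", name, "': unknown residue letter in token '",
           tk, "'")
    res
  }
  allowed <- mapply(parse_token, tokens, is_centre, SIMPLIFY = FALSE)
  names(allowed) <- NULL
  centre_set <- allowed[[ci]]
  if (any(!centre_set %in% c("S", "T", "Y")))
    stop("motif '", name, "': centre residues must be S, T or Y")
  structure(list(name = name, pattern = pattern,
                 offsets = offsets, allowed = allowed),
            class = "motif_definition")
}

#' Read a motif definition file
#'
#' One motif per line: `NAME<TAB>PATTERN` (see [parse_motif()] for the
#' pattern grammar); `#` lines and blank lines are skipped.
#'
#' @param path Path to the motif TSV.
#' @return Named list of `motif_definition` objects.
#' @export
read_motifs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no motif definitions in '", path, "'")
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed motif line (need NAME<TAB>PATTERN): '", ln, "'")
    if (parts[1] %in% names(out))
      stop("duplicate motif name '", parts[1], "' in '", path, "'")
    out[[parts[1]]] <- parse_motif(parts[1], parts[2])
  }
  out
}

#' Match a motif against a flanking window
#'
#' TRUE iff every token's offset slot is inside the protein (non-missing)
#' and holds a permitted residue.
#'
#' @param window Character vector from [extract_flank()] (names are
#'   offsets).
#' @param motif A `motif_definition`.
#' @return Logical scalar.
#' @export
match_motif <- function(window, motif) {
  slots <- window[as.character(motif$offsets)]
  if (any(is.na(slots))) return(FALSE)
  all(mapply(function(res, ok) res %in% ok, slots, motif$allowed))
}

#' Motif membership matrix for a window set
#'
#' @param windows Character matrix from [flank_windows()].
#' @param motifs Named list of `motif_definition`s.
#' @return Logical matrix, one row per window, one column per motif.
#' @export
match_motifs <- function(windows, motifs) {
  out <- vapply(motifs, function(m)
    apply(windows, 1, match_motif, motif = m),
    logical(nrow(windows)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(windows))
  colnames(out) <- names(motifs)
  out
}

# Midranks of x (average rank for ties).
.midrank <- function(x) rank(x, ties.method = "average")

#' Two-dimensional rank-based annotation enrichment
#'
#' Places every motif's member sites in a two-dimensional score space.
#' For each dimension, with midranks `R` over all `n` sites and `m`
#' members, the score is `s = 2 * (mean member rank - (n+1)/2) / (n - m)`
#' which lies in `[-1, 1]`: +1 when members occupy the top ranks of that
#' dimension, -1 the bottom. Joint significance uses a Hotelling-type
#' statistic on the mean-rank vector: under the null the members are a
#' simple random sample (without replacement) of the n ranks, so the
#' exact covariance of the mean-rank pair is the empirical midrank
#' covariance scaled by `(n - m) / (m (n - 1))`; the quadratic form is
#' referred to a chi-square with 2 degrees of freedom. P-values are
#' corrected across motifs with Benjamini-Hochberg.
#'
#' @param x Numeric vector (e.g. variability per site).
#' @param y Numeric vector (e.g. disorder probability or 0/1 call; ties
#'   are handled by midranks).
#' @param membership Logical matrix (sites x motifs) or a single logical
#'   vector; motifs with 0 or n members are skipped with a warning.
#' @param fdr FDR threshold for the `significant` flag (default 0.01).
#' @return `data.frame` with `motif`, `m`, `s_var`, `s_dis`, `p_value`,
#'   `q_value`, `significant`.
#' @export
enrichment_2d <- function(x, y, membership, fdr = 0.01) {
  if (is.vector(membership)) membership <- cbind(motif = membership)
  n <- length(x)
  stopifnot(length(y) == n, nrow(membership) == n)
  if (n < 10L) stop("enrichment_2d: need at least 10 sites")
  rx <- .midrank(x); ry <- .midrank(y)
  centre <- (n + 1) / 2
  # population (divide-by-n) covariance matrix of the midrank pairs
  sig_pop <- stats::cov(cbind(rx, ry)) * (n - 1) / n
  res <- lapply(colnames(membership), function(nm) {
    mem <- membership[, nm]
    m <- sum(mem)
    if (m == 0L || m == n) {
      warning("motif '", nm, "' has ", m,
              " members; skipped (needs 1 <= m < n)")
      return(NULL)
    }
    u <- c(mean(rx[mem]) - centre, mean(ry[mem]) - centre)
    s <- 2 * u / (n - m)
    sig <- sig_pop * (n - m) / (m * (n - 1))
    tstat <- tryCatch(drop(t(u) %*% solve(sig, u)),
                      error = function(e) NA_real_)
    if (is.na(tstat)) {  # x,y ranks collinear: fall back to 1-df on x
      v <- sig_pop[1, 1] * (n - m) / (m * (n - 1))
      tstat <- u[1]^2 / v
      p <- stats::pchisq(tstat, df = 1, lower.tail = FALSE)
    } else {
      p <- stats::pchisq(tstat, df = 2, lower.tail = FALSE)
    }
    data.frame(motif = nm, m = m, s_var = s[1], s_dis = s[2],
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) stop("enrichment_2d: no testable motif")
  res$q_value <- bh_fdr(res$p_value)
  res$significant <- res$q_value < fdr
  res
}

#' Remove sites matching any of a set of motifs
#'
#' Used as a robustness check: e.g. drop all sites matching
#' proline-directed motifs and re-run the category comparison to see
#' whether the variability/disorder contrast persists.
#'
#' @param sites Site table.
#' @param seqs Named character vector of sequences.
#' @param motifs Named list of `motif_definition`s.
#' @return The site table without matching sites (a warning is issued if
#'   nothing survives).
#' @export
exclude_motif_sites <- function(sites, seqs, motifs) {
  if (!length(motifs) || !nrow(sites)) return(sites)
  win <- flank_windows(sites, seqs)
  mm <- match_motifs(win, motifs)
  hit <- rowSums(mm) > 0
  out <- sites[!hit, , drop = FALSE]
  if (!nrow(out))
    warning("exclude_motif_sites: every site matched a motif; ",
            "empty table returned")
  out
}
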