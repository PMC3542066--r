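#' @importFrom stats sd median quantile rnorm runif rgeom rbinom
#' @importFrom utils read.delim write.table head
NULL

# Canonical column order of a site table; ratio columns follow the six
# cell-cycle phases G1, G1/S, early S, late S, G2, M.
SITE_TABLE_COLS <- c("protein_id", "position", "residue",
                     "ratio_g1", "ratio_g1s", "ratio_es",
                     "ratio_ls", "ratio_g2", "ratio_m")

RATIO_COLS <- SITE_TABLE_COLS[4:9]

#' Read a phospho-site quantification table
#'
#' Reads a tab-separated site table with one row per phospho-site:
#' protein accession, 1-based residue position, modified residue (S/T/Y)
#' and six normalized phosphorylation ratios, one per cell-cycle phase
#' (G1, G1/S, early S, late S, G2, M). Missing ratios may be encoded as
#' an empty cell or `NA`; they are preserved as `NA`, never as zero.
#'
#' @param path Path to a TSV file with a header row using the column names
#'   `protein_id`, `position`, `residue`, `ratio_g1`, `ratio_g1s`,
#'   `ratio_es`, `ratio_ls`, `ratio_g2`, `ratio_m`.
#' @return A `data.frame` with those nine columns, positions integer,
#'   ratios numeric with `NA` for missing values.
#' @export
read_site_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = c("", "NA"),
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(SITE_TABLE_COLS, names(raw))
  if (length(missing_cols))
    stop("site table '", path, "' is missing columns: ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[SITE_TABLE_COLS]
  n <- nrow(raw)
  lines <- seq_len(n) + 1L  # header is line 1

  pos <- suppressWarnings(as.numeric(raw$position))
  bad <- which(is.na(pos) | pos != floor(pos) | pos < 1)
  if (length(bad))
    stop("malformed position at line ", lines[bad[1]],
         " of '", path, "': '", raw$position[bad[1]], "'")

  res <- toupper(raw$residue)
  bad <- which(is.na(res) | !res %in% c("S", "T", "Y"))
  if (length(bad))
    stop("unknown residue at line ", lines[bad[1]],
         " of '", path, "': '", raw$residue[bad[1]],
         "' (expected S, T or Y)")

  out <- data.frame(protein_id = raw$protein_id,
                    position = as.integer(pos),
                    residue = res,
                    stringsAsFactors = FALSE)
  for (rc in RATIO_COLS) {
    v <- suppressWarnings(as.numeric(raw[[rc]]))
    bad <- which(!is.na(raw[[rc]]) & is.na(v))
    if (length(bad))
      stop("malformed ", rc, " at line ", lines[bad[1]],
           " of '", path, "': '", raw[[rc]][bad[1]], "'")
    if (any(v < 0, na.rm = TRUE))
      stop("negative ", rc, " at line ",
           lines[which(v < 0)[1]], " of '", path, "'")
    out[[rc]] <- v
  }

  key <- paste(out$protein_id, out$position)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (protein, position) entry in '", path, "': ", d)
  }
  out
}

#' Write a phospho-site table
#'
#' Writes a site table as TSV in the fixed canonical column order, missing
#' ratios as `NA`, ratio values at 6 significant digits. Extra (derived)
#' columns such as `variability` or `category3` are appended after the
#' canonical nine when present.
#'
#' @param sites A site table `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  stopifnot(all(SITE_TABLE_COLS %in% names(sites)))
  extra <- setdiff(names(sites), SITE_TABLE_COLS)
  out <- sites[c(SITE_TABLE_COLS, extra)]
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- signif(out[[nm]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector, one element per record; the name is the
#'   first whitespace-delimited token of the header line.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in '", path, "'")
  acc <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(acc))
    stop("duplicate accession in '", path, "': ",
         acc[duplicated(acc)][1])
  seqs <- as.character(set)
  names(seqs) <- acc
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for accession ",
         acc[nchar(seqs) == 0L][1], " in '", path, "'")
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a PsiPred .ss2 secondary-structure prediction
#'
#' Parses PsiPred VFORMAT output: comment/blank lines followed by one row
#' per residue with columns index, residue, state (`H`, `E` or `C`) and
#' three state probabilities. The probabilities are parsed and checked to
#' sum to ~1 per residue (a warning is issued otherwise) but only the
#' state string is returned.
#'
#' @param path Path to a `.ss2` file.
#' @return Character scalar over `{H,E,C}`, one letter per residue, with
#'   the parsed residue string in attribute `"residues"`.
#' @export
read_psipred_ss2 <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no residue rows in .ss2 file '", path, "' (empty profile)")
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed .ss2 row in '", path, "': '",
         lines[which(nf < 3L)[1]], "'")
  idx <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 1L)))
  if (anyNA(idx) || !identical(idx, seq_along(idx)))
    stop("non-contiguous residue indices in .ss2 file '", path, "'")
  state <- toupper(vapply(fields, `[`, character(1), 3L))
  bad <- which(!state %in% c("H", "E", "C"))
  if (length(bad))
    stop("unknown secondary-structure state '", state[bad[1]],
         "' in '", path, "'")
  if (all(nf >= 6L)) {
    probs <- t(vapply(fields, function(f)
      suppressWarnings(as.numeric(f[4:6])), numeric(3)))
    s <- rowSums(probs)
    if (any(is.na(s)) || any(s < 0.9 | s > 1.1))
      warning("state probabilities in '", path,
              "' do not sum to ~1 for some residues")
  }
  ss <- paste(state, collapse = "")
  attr(ss, "residues") <- paste(vapply(fields, `[`, character(1), 2L),
                                collapse = "")
  ss
}

#' Read a DISOPRED .diso disorder prediction
#'
#' Parses DISOPRED output: comment/blank lines followed by one row per
#' residue with columns index, residue, mark (`*` disordered, `.` ordered)
#' and, when present, a confidence/probability value.
#'
#' @param path Path to a `.diso` file.
#' @param sequence Optional protein sequence; when given, the profile
#'   length is checked against it.
#' @return List with `disorder` (logical vector) and `prob` (numeric
#'   vector, or `NULL` when the file carries no confidence column).
#' @export
read_disopred <- function(path, sequence = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no residue rows in .diso file '", path, "'")
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3L))
    stop("malformed .diso row in '", path, "'")
  idx <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 1L)))
  if (anyNA(idx) || !identical(idx, seq_along(idx)))
    stop("non-contiguous residue indices in .diso file '", path, "'")
  mark <- vapply(fields, `[`, character(1), 3L)
  bad <- which(!mark %in% c("*", "."))
  if (length(bad))
    stop("unknown disorder mark '", mark[bad[1]], "' in '", path, "'")
  disorder <- mark == "*"
  prob <- NULL
  if (all(lengths(fields) >= 4L)) {
    prob <- suppressWarnings(
      as.numeric(vapply(fields, `[`, character(1), 4L)))
    if (anyNA(prob)) prob <- NULL
  }
  if (!is.null(sequence) && nchar(sequence) != length(disorder))
    stop("disorder profile length (", length(disorder),
         ") does not match sequence length (", nchar(sequence),
         ") for '", path, "'")
  list(disorder = disorder, prob = prob)
}

#' Read a rate4site per-residue evolutionary-rate file
#'
#' Parses rate4site `res` output: `#`-comment lines followed by rows of at
#' least position, residue and score. Lower scores mean stronger
#' conservation (slower evolutionary rate); negative scores are valid.
#'
#' @param path Path to a rate4site output file.
#' @return Numeric score vector, one per residue, with the residue string
#'   in attribute `"residues"`.
#' @export
read_rate4site <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no residue rows in rate4site file '", path, "'")
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3L))
    stop("malformed rate4site row in '", path, "'")
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 1L)))
  if (anyNA(pos) || !identical(pos, seq_along(pos)))
    stop("missing or non-contiguous positions in rate4site file '",
         path, "'")
  score <- suppressWarnings(
    as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(score))
    stop("non-numeric score in rate4site file '", path, "' at position ",
         pos[which(is.na(score))[1]])
  if (any(!is.finite(score)))
    stop("non-finite score in rate4site file '", path, "'")
  attr(score, "residues") <- paste(vapply(fields, `[`, character(1), 2L),
                                   collapse = "")
  score
}

#' Build a per-protein structure profile
#'
#' Combines a secondary-structure string and disorder vector into the
#' per-protein profile used downstream, cross-checking lengths.
#'
#' @param protein_id Accession.
#' @param ss Character scalar over `{H,E,C}`.
#' @param disorder Logical vector, same length as `ss`.
#' @param prob Optional numeric disorder probabilities in `[0, 1]`.
#' @return List of class `structure_profile`.
#' @export
structure_profile <- function(protein_id, ss, disorder, prob = NULL) {
  ss <- as.character(ss)
  n <- nchar(ss)
  if (length(disorder) != n)
    stop("structure profile for ", protein_id, ": ss length ", n,
         " != disorder length ", length(disorder))
  if (!grepl("^[HEC]*$", ss))
    stop("structure profile for ", protein_id,
         ": ss states must be H, E or C")
  if (!is.null(prob)) {
    if (length(prob) != n)
      stop("structure profile for ", protein_id,
           ": probability length mismatch")
    if (any(prob < 0 | prob > 1, na.rm = TRUE))
      stop("structure profile for ", protein_id,
           ": probabilities outside [0, 1]")
  }
  structure(list(protein_id = protein_id, ss = ss,
                 disorder = disorder, prob = prob),
            class = "structure_profile")
}

#' Check a site table against protein sequences
#'
#' Verifies that every site's position lies inside its protein and that
#' the annotated residue matches the sequence at that position.
#'
#' @param sites Site table.
#' @param seqs Named character vector of sequences.
#' @return `sites`, invisibly, when all checks pass.
#' @export
validate_sites_against_sequences <- function(sites, seqs) {
  missing <- setdiff(unique(sites$protein_id), names(seqs))
  if (length(missing))
    stop("no sequence for protein(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  len <- nchar(seqs[sites$protein_id])
  bad <- which(sites$position > len)
  if (length(bad))
    stop("site position ", sites$position[bad[1]], " beyond sequence end of ",
         sites$protein_id[bad[1]], " (length ", len[bad[1]], ")")
  at <- substring(seqs[sites$protein_id], sites$position, sites$position)
  bad <- which(at != sites$residue)
  if (length(bad))
    stop("residue mismatch at ", sites$protein_id[bad[1]], ":",
         sites$position[bad[1]], " (table says ", sites$residue[bad[1]],
         ", sequence has ", at[bad[1]], ")")
  invisible(sites)
}
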