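# Conservation of phospho-sites versus control S/T/Y residues, stratified
# by structural background (ordered / disordered). Controls are all
# serine, threonine and tyrosine residues of the phospho-proteins that
# were not observed phosphorylated; evolutionary-rate scores (lower =
# more conserved) come from pre-computed rate4site tracks.

CONS_STRATA <- c("PHOSPHO_ORDERED", "CONTROL_ORDERED",
                 "PHOSPHO_DISORDERED", "CONTROL_DISORDERED")

#' Enumerate phospho and control S/T/Y residues of one protein
#'
#' @param protein_id Accession.
#' @param sequence Protein sequence.
#' @param phospho_positions Integer vector of phosphorylated positions
#'   (each must be an S, T or Y of the sequence).
#' @param disorder Logical per-residue disorder vector (same length as
#'   the sequence).
#' @param scores Optional numeric per-residue conservation scores.
#' @return `data.frame` with `protein_id`, `position`, `residue`,
#'   `phospho`, `background` (ORDERED/DISORDERED) and `score` (`NA`
#'   when no track is supplied).
#' @export
define_control_sites <- function(protein_id, sequence, phospho_positions,
                                 disorder, scores = NULL) {
  n <- nchar(sequence)
  if (length(disorder) != n)
    stop("define_control_sites: disorder length != sequence length for ",
         protein_id)
  if (!is.null(scores) && length(scores) != n)
    stop("define_control_sites: score length != sequence length for ",
         protein_id)
  res <- strsplit(sequence, "")[[1]]
  sty <- which(res %in% c("S", "T", "Y"))
  bad <- setdiff(phospho_positions, sty)
  if (length(bad))
    stop("define_control_sites: phospho position ", bad[1], " of ",
         protein_id, " is not an S/T/Y residue")
  if (!length(sty))
    return(data.frame(protein_id = character(), position = integer(),
                      residue = character(), phospho = logical(),
                      background = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(protein_id = protein_id, position = sty,
             residue = res[sty],
             phospho = sty %in% phospho_positions,
             background = ifelse(disorder[sty], "DISORDERED", "ORDERED"),
             score = if (is.null(scores)) NA_real_ else scores[sty],
             stringsAsFactors = FALSE)
}

#' Build conservation records for a whole dataset
#'
#' @param sites Site table (defines the phospho positions per protein).
#' @param seqs Named character vector of sequences.
#' @param profiles Named list of [structure_profile()]s.
#' @param tracks Named list of numeric conservation-score vectors (as
#'   from [read_rate4site()]), one per protein; proteins without a track
#'   are dropped with a warning.
#' @return Row-bound `data.frame` of [define_control_sites()] records.
#' @export
build_conservation_records <- function(sites, seqs, profiles, tracks) {
  pids <- intersect(names(seqs), names(profiles))
  no_track <- setdiff(pids, names(tracks))
  if (length(no_track))
    warning(length(no_track), " protein(s) have no conservation track; ",
            "dropped")
  pids <- intersect(pids, names(tracks))
  out <- lapply(pids, function(pid)
    define_control_sites(pid, seqs[[pid]],
                         sites$position[sites$protein_id == pid],
                         profiles[[pid]]$disorder, tracks[[pid]]))
  do.call(rbind, out)
}

#' Compare conservation of phospho-sites and controls by background
#'
#' Reports per-stratum counts and mean scores for the four strata
#' (phospho/control x ordered/disordered) and Mann-Whitney-Wilcoxon
#' tests for the three contrasts: phospho vs control within ordered
#' regions, phospho vs control within disordered regions, and phospho
#' ordered vs phospho disordered.
#'
#' @param records `data.frame` from [build_conservation_records()] with
#'   non-missing `score` values; every stratum needs at least two
#'   records.
#' @return List with `strata` (data.frame of stratum, n, mean) and
#'   `tests` (data.frame of contrast, U, p_value).
#' @export
compare_conservation <- function(records) {
  records <- records[!is.na(records$score), , drop = FALSE]
  stratum <- paste0(ifelse(records$phospho, "PHOSPHO_", "CONTROL_"),
                    records$background)
  for (s in CONS_STRATA) {
    k <- sum(stratum == s)
    if (k < 2L)
      stop("compare_conservation: stratum ", s, " has ", k,
           " record(s); need at least 2")
  }
  sc <- split(records$score, factor(stratum, levels = CONS_STRATA))
  strata <- data.frame(stratum = CONS_STRATA,
                       n = lengths(sc),
                       mean = vapply(sc, mean, numeric(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  contrasts <- list(
    phospho_vs_control_ordered =
      c("PHOSPHO_ORDERED", "CONTROL_ORDERED"),
    phospho_vs_control_disordered =
      c("PHOSPHO_DISORDERED", "CONTROL_DISORDERED"),
    phospho_ordered_vs_disordered =
      c("PHOSPHO_ORDERED", "PHOSPHO_DISORDERED"))
  tests <- do.call(rbind, lapply(names(contrasts), function(nm) {
    pair <- contrasts[[nm]]
    mw <- mann_whitney(sc[[pair[1]]], sc[[pair[2]]])
    data.frame(contrast = nm, U = mw$statistic, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  }))
  list(strata = strata, tests = tests)
}
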