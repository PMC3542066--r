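# Merge secondary-structure (H/E/C) and disorder predictions into the
# site categories used throughout: regular (helix/sheet in an ordered
# region), irregular (coil in an ordered region) and disordered (coil in
# a disordered region). Disorder dominates on the rare helix/sheet
# residues flagged disordered; such conflicts are counted and warned.

CATEGORY3_LEVELS <- c("REGULAR", "IRREGULAR", "DISORDERED")
CATEGORY2_LEVELS <- c("ORDERED", "DISORDERED")

#' Structural category of residues
#'
#' @param ss_state Character vector of secondary-structure states
#'   (`H`, `E` or `C`), one per residue of interest.
#' @param disordered Logical vector of the same length.
#' @param warn Emit a warning when helix/sheet residues are flagged
#'   disordered (they are classed DISORDERED: disorder dominates).
#' @return Factor with levels REGULAR, IRREGULAR, DISORDERED.
#' @export
assign_category <- function(ss_state, disordered, warn = TRUE) {
  stopifnot(length(ss_state) == length(disordered))
  if (any(!ss_state %in% c("H", "E", "C")))
    stop("assign_category: states must be H, E or C")
  out <- ifelse(disordered, "DISORDERED",
                ifelse(ss_state == "C", "IRREGULAR", "REGULAR"))
  n_conflict <- sum(disordered & ss_state != "C")
  if (warn && n_conflict > 0)
    warning(n_conflict, " helix/sheet residue(s) flagged disordered; ",
            "classed DISORDERED (disorder dominates)")
  factor(out, levels = CATEGORY3_LEVELS)
}

#' Two-level category from the three-level one
#'
#' @param category3 Factor or character of REGULAR/IRREGULAR/DISORDERED.
#' @return Factor with levels ORDERED, DISORDERED.
#' @export
category2_from_category3 <- function(category3) {
  factor(ifelse(as.character(category3) == "DISORDERED",
                "DISORDERED", "ORDERED"),
         levels = CATEGORY2_LEVELS)
}

#' Classify the sites of a table by structural context
#'
#' Reads each site's secondary-structure state and disorder flag at
#' exactly the modified position (no window vote) and appends the
#' category columns, the raw state/flag, and the disorder probability
#' when the profile carries one.
#'
#' @param sites Site table.
#' @param profiles Named list of [structure_profile()] objects, one per
#'   protein accession in `sites`.
#' @return `sites` with columns `ss_state`, `disordered`,
#'   `disorder_prob`, `category3`, `category2` appended.
#' @export
classify_sites <- function(sites, profiles) {
  missing <- setdiff(unique(sites$protein_id), names(profiles))
  if (length(missing))
    stop("no structure profile for protein(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  n <- nrow(sites)
  ss_state <- character(n)
  disordered <- logical(n)
  dprob <- rep(NA_real_, n)
  for (pid in unique(sites$protein_id)) {
    prof <- profiles[[pid]]
    i <- which(sites$protein_id == pid)
    pos <- sites$position[i]
    if (any(pos > nchar(prof$ss)))
      stop("site position beyond structure profile of ", pid)
    ss_state[i] <- substring(prof$ss, pos, pos)
    disordered[i] <- prof$disorder[pos]
    if (!is.null(prof$prob)) dprob[i] <- prof$prob[pos]
  }
  sites$ss_state <- ss_state
  sites$disordered <- disordered
  sites$disorder_prob <- dprob
  sites$category3 <- assign_category(ss_state, disordered)
  sites$category2 <- category2_from_category3(sites$category3)
  sites
}

#' Extract maximal coil segments from a structure profile
#'
#' Maximal runs of `C`-state residues, split wherever the disorder flag
#' changes, labelled ORDERED_COIL or DISORDERED_REGION. Ordered coils
#' correspond to turns and short loops and are typically much shorter
#' than disordered regions.
#'
#' @param profile A [structure_profile()] object.
#' @return `data.frame` with columns `protein_id`, `start`, `end`,
#'   `kind`, `length` (1-based inclusive coordinates).
#' @export
extract_coil_segments <- function(profile) {
  ss <- strsplit(profile$ss, "")[[1]]
  n <- length(ss)
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), kind = character(),
                      length = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  is_coil <- ss == "C"
  # run id changes when coil-ness or the disorder flag changes
  key <- paste(is_coil, profile$disorder)
  run_id <- cumsum(c(TRUE, key[-1] != key[-n]))
  starts <- which(!duplicated(run_id))
  ends <- c(starts[-1] - 1L, n)
  keep <- is_coil[starts]
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(protein_id = profile$protein_id,
             start = starts, end = ends,
             kind = ifelse(profile$disorder[starts],
                           "DISORDERED_REGION", "ORDERED_COIL"),
             length = ends - starts + 1L,
             stringsAsFactors = FALSE)
}

#' Compare phosphorylation variability across structural categories
#'
#' Per-category counts and medians, a two-sample Kolmogorov-Smirnov test
#' on the two-level ordered/disordered split, and a one-way ANOVA across
#' the three-level categories.
#'
#' @param classified Site table with `variability`, `category2` and
#'   `category3` columns (see [add_variability()], [classify_sites()]).
#' @return List with `by_category3` (data.frame of n, median),
#'   `by_category2`, `ks2` (ordered vs disordered), `anova3`.
#' @export
compare_category_variability <- function(classified) {
  v <- classified$variability
  ok <- !is.na(v)
  c3 <- as.character(classified$category3)[ok]
  c2 <- as.character(classified$category2)[ok]
  v <- v[ok]
  for (lev in CATEGORY3_LEVELS)
    if (!any(c3 == lev))
      stop("compare_category_variability: empty category ", lev)
  by3 <- data.frame(
    category = CATEGORY3_LEVELS,
    n = vapply(CATEGORY3_LEVELS, function(l) sum(c3 == l), integer(1)),
    median = vapply(CATEGORY3_LEVELS, function(l) stats::median(v[c3 == l]),
                    numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  by2 <- data.frame(
    category = CATEGORY2_LEVELS,
    n = vapply(CATEGORY2_LEVELS, function(l) sum(c2 == l), integer(1)),
    median = vapply(CATEGORY2_LEVELS, function(l) stats::median(v[c2 == l]),
                    numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  ks2 <- ks_two_sample(v[c2 == "ORDERED"], v[c2 == "DISORDERED"])
  anova3 <- anova_oneway(split(v, factor(c3, levels = CATEGORY3_LEVELS)))
  list(by_category3 = by3, by_category2 = by2, ks2 = ks2, anova3 = anova3)
}
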