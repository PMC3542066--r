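# Synthetic dataset generator. Emulates, jointly, every input the
# pipeline consumes: protein sequences, the six-phase phospho-ratio
# table, secondary-structure and disorder profiles, per-residue
# conservation tracks and a kinase-motif file. Defaults reproduce the
# study conditions: site-class proportions 145/353/4675, per-class
# median ratio SDs 1.65/1.83/2.22, a planted neighbor-clustering odds
# ratio of 1.9 at distance 4, and conservation stratum means
# (-0.38, -0.28, 0.14, 0.22).

# Run code with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 1,059 proteins, an analysis set
#' of ~5,173 complete sites in class proportions 145:353:4,675
#' (regular:irregular:disordered), class-median ratio SDs
#' 1.65/1.83/2.22, a planted disordered-vs-ordered neighbor-clustering
#' odds ratio of 1.9 at distance cut-off 4, a proline-directed motif
#' planted preferentially at disordered, variable sites, and
#' conservation stratum means (-0.38, -0.28, 0.14, 0.22).
#'
#' @param n_proteins Number of proteins.
#' @param mean_protein_length Mean protein length (residues).
#' @param n_sites Total phospho-sites generated (before completeness
#'   filtering); with the default `missing_rate` the complete analysis
#'   set is ~`n_sites * (1 - missing_rate)`.
#' @param class_props Site proportions for regular / irregular /
#'   disordered (must sum to 1).
#' @param median_sd Target per-class median of the per-site ratio SD.
#' @param sigma_log_sd Log-scale SD of the log-normal per-site sigma.
#' @param neighbor_or Planted odds ratio (disordered vs ordered) of
#'   having a neighboring phospho-site at `neighbor_w`.
#' @param neighbor_w Distance cut-off at which `neighbor_or` is planted.
#' @param ordered_pair_frac Fraction of ordered sites given a planted
#'   neighbor; the disordered fraction is derived from `neighbor_or`.
#' @param sty_probs Residue probabilities for S, T, Y at phospho-sites.
#' @param proline_excess_disorder Multiplier on the proline frequency
#'   inside disordered regions.
#' @param motif_pattern Planted motif (see [parse_motif()] grammar).
#' @param motif_base,motif_dis_coef,motif_var_coef Logistic coefficients
#'   of the planting probability: `plogis(base + dis_coef * disordered +
#'   var_coef * z)`, z the standardized log per-site sigma.
#' @param cons_means Conservation stratum means, in the order phospho
#'   ordered, control ordered, phospho disordered, control disordered
#'   (lower = more conserved).
#' @param cons_sd Within-stratum conservation-score SD.
#' @param missing_rate Fraction of sites given 1-4 missing ratios.
#' @param seed Mandatory RNG seed; outputs are deterministic given the
#'   config.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1059L,
                       mean_protein_length = 460L,
                       n_sites = 5748L,
                       class_props = c(regular = 145, irregular = 353,
                                       disordered = 4675) / 5173,
                       median_sd = c(regular = 1.65, irregular = 1.83,
                                     disordered = 2.22),
                       sigma_log_sd = 0.1,
                       neighbor_or = 1.9,
                       neighbor_w = 4L,
                       ordered_pair_frac = 0.2,
                       sty_probs = c(S = 0.84, T = 0.14, Y = 0.02),
                       proline_excess_disorder = 2,
                       motif_pattern = "pS/pT-P",
                       motif_base = -2.2,
                       motif_dis_coef = 1.1,
                       motif_var_coef = 0.7,
                       cons_means = c(phospho_ordered = -0.38,
                                      control_ordered = -0.28,
                                      phospho_disordered = 0.14,
                                      control_disordered = 0.22),
                       cons_sd = 0.6,
                       missing_rate = 0.1,
                       seed) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  if (abs(sum(class_props) - 1) > 1e-8)
    stop("sim_config: class proportions must sum to 1")
  if (any(class_props < 0) || any(median_sd <= 0) || neighbor_or <= 0)
    stop("sim_config: proportions and targets must be positive")
  if (ordered_pair_frac <= 0 || ordered_pair_frac >= 1)
    stop("sim_config: ordered_pair_frac must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("sim_config: missing_rate must lie in [0, 1)")
  if (is.null(names(cons_means)))
    names(cons_means) <- c("phospho_ordered", "control_ordered",
                           "phospho_disordered", "control_disordered")
  structure(as.list(environment()), class = "sim_config")
}

# ---- structure / sequence generation --------------------------------

# One protein's secondary structure + disorder. Ordered blocks contain
# H/E runs interleaved with short coils (turns); disordered blocks are
# all-coil. Returns list(ss, disorder).
.gen_structure <- function(len) {
  ss <- character(0); dis <- logical(0)
  disordered_block <- stats::runif(1) < 0.5
  while (length(ss) < len) {
    if (disordered_block) {
      bl <- 8L + stats::rgeom(1, 1 / 32)
      bl <- min(bl, len - length(ss))
      ss <- c(ss, rep("C", bl)); dis <- c(dis, rep(TRUE, bl))
    } else {
      bl <- 15L + stats::rgeom(1, 1 / 25)
      bl <- min(bl, len - length(ss))
      filled <- 0L
      while (filled < bl) {
        kind <- sample(c("H", "E", "C"), 1, prob = c(0.35, 0.20, 0.45))
        rl <- switch(kind,
                     H = 4L + stats::rgeom(1, 1 / 6),
                     E = 3L + stats::rgeom(1, 1 / 3),
                     C = 1L + stats::rgeom(1, 1 / 3))  # ordered coils short
        rl <- min(rl, bl - filled)
        ss <- c(ss, rep(kind, rl))
        filled <- filled + rl
      }
      dis <- c(dis, rep(FALSE, bl))
    }
    disordered_block <- !disordered_block
  }
  list(ss = ss, disorder = dis)
}

# Maximal runs of a logical vector; list(start, len).
.runs_of <- function(flag) {
  n <- length(flag)
  if (!n || !any(flag))
    return(list(start = integer(), len = integer()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], len = r$lengths[keep])
}

# ---- site placement --------------------------------------------------

# Greedy gap-respecting placement. `cands` is a list per protein of
# candidate position vectors for one class; returns (protein index,
# position) pairs, updating `occ` (environment holding per-protein
# occupied positions). Sites are kept >= `gap` residues from every
# previously placed site so the only phospho-neighbors are planted ones.
.place_singles <- function(k, cands, occ, gap = 11L, label) {
  placed_p <- integer(k); placed_pos <- integer(k)
  weights <- vapply(cands, length, integer(1))
  if (k > 0L && sum(weights) == 0)
    stop("simulate_dataset: no candidate residues for ", label, " sites")
  tries <- 0L; max_tries <- 60L * max(1L, k)
  batch <- integer(0); bi <- 0L
  i <- 1L
  while (i <= k) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("simulate_dataset: could not place ", label,
           " sites; config infeasible (proteins too short or too few ",
           "candidate residues)")
    if (bi >= length(batch)) {  # draw protein indices in bulk
      batch <- sample.int(length(cands), 2L * k + 32L,
                          replace = TRUE, prob = weights)
      bi <- 0L
    }
    bi <- bi + 1L
    pr <- batch[bi]
    cc <- cands[[pr]]
    if (!length(cc)) next
    pos <- cc[sample.int(length(cc), 1L)]
    o <- occ$pos[[pr]]
    if (length(o) && any(abs(o - pos) < gap)) next
    occ$pos[[pr]] <- c(o, pos)
    placed_p[i] <- pr; placed_pos[i] <- pos
    i <- i + 1L
  }
  data.frame(prot = placed_p, position = placed_pos)
}

# Place `k` pairs inside same-kind runs: both members get the same
# structural class. The pair distance d is drawn uniformly over 1..maxd
# FIRST and then a run long enough to hold it is sought, so the distance
# distribution is identical in ordered and disordered regions and the
# planted odds ratio is flat across where the cut-off exceeds d.
# Returns data.frame(prot, position, pair_id).
.place_pairs <- function(k, runs, occ, maxd = 4L, gap = 11L, label) {
  if (k == 0L)
    return(data.frame(prot = integer(), position = integer(),
                      pair_id = integer()))
  prot_v <- integer(2L * k); pos_v <- integer(2L * k)
  weights <- vapply(runs, function(r) sum(r$len >= 2L), numeric(1))
  tries <- 0L; max_tries <- 150L * k
  i <- 1L
  d <- sample.int(maxd, 1L)
  while (i <= k) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("simulate_dataset: could not place ", label,
           " site pairs; config infeasible (runs too short for the ",
           "clustering target)")
    pr <- sample.int(length(runs), 1L, prob = weights)
    rr <- runs[[pr]]
    ok <- which(rr$len >= d + 1L)
    if (!length(ok)) next
    ri <- ok[sample.int(length(ok), 1L)]
    a <- rr$start[ri] + sample.int(rr$len[ri] - d, 1L) - 1L
    b <- a + d
    o <- occ$pos[[pr]]
    if (length(o) && any(o > a - gap & o < b + gap)) next
    occ$pos[[pr]] <- c(o, a, b)
    prot_v[c(2L * i - 1L, 2L * i)] <- pr
    pos_v[c(2L * i - 1L, 2L * i)] <- c(a, b)
    i <- i + 1L
    d <- sample.int(maxd, 1L)
  }
  data.frame(prot = prot_v, position = pos_v,
             pair_id = rep(seq_len(k), each = 2L))
}

# ---- main generator --------------------------------------------------

#' Simulate a complete dataset
#'
#' Deterministic given the config seed. Sequences are i.i.d. over the 20
#' amino acids except for a configurable proline excess in disordered
#' stretches and the residues written at planted sites and motif
#' positions. Each site's six ratios are `1 + sigma * z` with `z` a
#' standardized noise 6-vector (unit sample SD), shifted up when needed
#' so ratios stay nonnegative -- a constant shift preserves the sample
#' SD, so the realized per-site variability equals the planted
#' `sigma_site` exactly and the class medians are controlled by the
#' log-normal sigma medians alone. Planted neighbor pairs are the only
#' phospho-sites closer than 11 residues, so the realized
#' neighbor-enrichment odds ratio at the target cut-off equals the
#' planted value up to binomial noise.
#'
#' @param config A [sim_config()].
#' @return List of class `phosvar_sim` with elements `sequences` (named
#'   character), `sites` (site table), `profiles` (named list of
#'   [structure_profile()]), `tracks` (named list of score vectors),
#'   `motifs` (named list of motif definitions; first entry is the
#'   planted one), `truth` (per-site data.frame: class3, sigma, paired,
#'   planted_motif) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .simulate_dataset_impl(config))
}

.simulate_dataset_impl <- function(cfg) {
  np <- cfg$n_proteins
  pids <- sprintf("SYN%04d", seq_len(np))

  lens <- pmax(120L, pmin(2500L,
    as.integer(round(stats::rnorm(np, cfg$mean_protein_length,
                                  cfg$mean_protein_length / 5)))))
  structs <- lapply(lens, .gen_structure)

  # per-class candidate positions; sites are never placed within 6
  # residues of a terminus so full +/-6 windows and +1 motif slots exist
  interior <- function(pos, len) pos[pos > 6L & pos <= len - 6L]
  cand_reg <- cand_irr <- cand_dis <- vector("list", np)
  runs_irr <- runs_dis <- vector("list", np)
  for (i in seq_len(np)) {
    st <- structs[[i]]
    ordered <- !st$disorder
    cand_reg[[i]] <- interior(which(st$ss %in% c("H", "E") & ordered),
                              lens[i])
    cand_irr[[i]] <- interior(which(st$ss == "C" & ordered), lens[i])
    cand_dis[[i]] <- interior(which(st$disorder), lens[i])
    ri <- .runs_of(st$ss == "C" & ordered)
    rd <- .runs_of(st$disorder)
    clip <- function(r, len) {
      # clip runs to the interior margin
      s <- pmax(r$start, 7L)
      e <- pmin(r$start + r$len - 1L, len - 6L)
      keep <- e >= s
      list(start = s[keep], len = (e - s + 1L)[keep])
    }
    runs_irr[[i]] <- clip(ri, lens[i])
    runs_dis[[i]] <- clip(rd, lens[i])
  }

  # site counts per class and planted pair counts
  n_sites <- cfg$n_sites
  n_cls <- round(cfg$class_props * n_sites)
  n_cls[3] <- n_sites - n_cls[1] - n_cls[2]
  n_ord <- n_cls[1] + n_cls[2]
  # The completeness filter removes a fraction `missing_rate` of sites at
  # random, so a planted pair fraction f yields a neighbor fraction f*s
  # (s = survival) in the analysis set. Calibrate the disordered fraction
  # so the analysis-set odds ratio equals the target.
  s_surv <- 1 - cfg$missing_rate
  p_o <- cfg$ordered_pair_frac
  odds_o_eff <- p_o * s_surv / (1 - p_o * s_surv)
  odds_d_eff <- cfg$neighbor_or * odds_o_eff
  p_d <- (odds_d_eff / (1 + odds_d_eff)) / s_surv
  if (p_d >= 1)
    stop("simulate_dataset: neighbor_or target infeasible at this ",
         "ordered_pair_frac and missing_rate")
  k_pairs_ord <- round(p_o * n_ord / 2)
  k_pairs_dis <- round(p_d * n_cls[3] / 2)
  if (2L * k_pairs_ord > n_cls[2])
    stop("simulate_dataset: clustering target needs more irregular ",
         "(ordered-coil) sites than the class proportions allow")

  occ <- new.env(parent = emptyenv())
  occ$pos <- rep(list(integer(0)), np)

  pr_ord <- .place_pairs(k_pairs_ord, runs_irr, occ,
                         maxd = cfg$neighbor_w, label = "ordered")
  pr_dis <- .place_pairs(k_pairs_dis, runs_dis, occ,
                         maxd = cfg$neighbor_w, label = "disordered")
  sg_reg <- .place_singles(n_cls[1], cand_reg, occ, label = "regular")
  sg_irr <- .place_singles(n_cls[2] - 2L * k_pairs_ord, cand_irr, occ,
                           label = "irregular")
  sg_dis <- .place_singles(n_cls[3] - 2L * k_pairs_dis, cand_dis, occ,
                           label = "disordered")

  mkdf <- function(df, class3, paired)
    data.frame(df[c("prot", "position")],
               class3 = rep(class3, nrow(df)),
               paired = rep(paired, nrow(df)))
  site <- rbind(
    mkdf(sg_reg, "REGULAR", FALSE),
    mkdf(sg_irr, "IRREGULAR", FALSE),
    mkdf(pr_ord, "IRREGULAR", TRUE),
    mkdf(sg_dis, "DISORDERED", FALSE),
    mkdf(pr_dis, "DISORDERED", TRUE))
  ns <- nrow(site)
  site <- site[sample.int(ns), , drop = FALSE]
  rownames(site) <- NULL

  # per-site sigma (log-normal around the class median) and ratios
  m_cls <- cfg$median_sd[c(REGULAR = 1, IRREGULAR = 2, DISORDERED = 3)[
    site$class3]]
  sigma <- unname(m_cls) * exp(stats::rnorm(ns, 0, cfg$sigma_log_sd))
  z <- matrix(stats::rnorm(6L * ns), ns, 6L)
  mu_z <- rowMeans(z)
  sd_z <- sqrt(rowSums((z - mu_z)^2) / 5)
  ratios <- 1 + sigma * ((z - mu_z) / sd_z)
  row_min <- do.call(pmin, as.data.frame(ratios))
  ratios <- ratios - pmin(row_min, 0)  # shift preserves the sample SD

  # missingness: a fixed fraction of sites loses 1-4 ratios
  n_incomplete <- round(cfg$missing_rate * ns)
  if (n_incomplete > 0) {
    inc <- sample.int(ns, n_incomplete)
    for (i in inc) {
      kna <- sample.int(4L, 1L)
      ratios[i, sample.int(6L, kna)] <- NA_real_
    }
  }

  # residues at sites; motif planting at +1
  residue <- sample(names(cfg$sty_probs), ns, replace = TRUE,
                    prob = cfg$sty_probs)
  zvar <- as.numeric(scale(log(sigma)))
  p_plant <- stats::plogis(cfg$motif_base +
                           cfg$motif_dis_coef * (site$class3 == "DISORDERED") +
                           cfg$motif_var_coef * zvar)
  plant <- stats::runif(ns) < p_plant & residue %in% c("S", "T")

  # sequences: background residues, proline excess in disorder, then
  # site residues and planted prolines written in
  base_p <- rep(1 / 20, 20)
  dis_p <- base_p
  dis_p[AA20 == "P"] <- dis_p[AA20 == "P"] * cfg$proline_excess_disorder
  dis_p <- dis_p / sum(dis_p)
  seqs <- character(np)
  seq_chars <- vector("list", np)
  for (i in seq_len(np)) {
    ch <- character(lens[i])
    d <- structs[[i]]$disorder
    ch[!d] <- sample(AA20, sum(!d), replace = TRUE, prob = base_p)
    ch[d] <- sample(AA20, sum(d), replace = TRUE, prob = dis_p)
    seq_chars[[i]] <- ch
  }
  site_pos_by_prot <- split(site$position, site$prot)
  for (i in seq_len(ns)) {
    seq_chars[[site$prot[i]]][site$position[i]] <- residue[i]
  }
  for (i in which(plant)) {
    pr <- site$prot[i]; pp <- site$position[i] + 1L
    others <- site_pos_by_prot[[as.character(pr)]]
    if (pp %in% others) { plant[i] <- FALSE; next }  # don't overwrite a site
    seq_chars[[pr]][pp] <- "P"
  }
  for (i in seq_len(np)) seqs[i] <- paste(seq_chars[[i]], collapse = "")
  names(seqs) <- pids

  # structure profiles with disorder probabilities
  profiles <- lapply(seq_len(np), function(i) {
    d <- structs[[i]]$disorder
    prob <- ifelse(d, stats::runif(lens[i], 0.65, 1),
                   stats::runif(lens[i], 0, 0.35))
    structure_profile(pids[i], paste(structs[[i]]$ss, collapse = ""),
                      d, prob)
  })
  names(profiles) <- pids

  # conservation tracks: stratum-mean shifts on S/T/Y residues
  mu <- cfg$cons_means
  tracks <- lapply(seq_len(np), function(i) {
    ch <- seq_chars[[i]]
    d <- structs[[i]]$disorder
    sc <- stats::rnorm(lens[i], 0, cfg$cons_sd)
    sty <- ch %in% c("S", "T", "Y")
    ph <- logical(lens[i])
    ph[site$position[site$prot == i]] <- TRUE
    sc[sty & ph & !d] <- sc[sty & ph & !d] + mu[["phospho_ordered"]]
    sc[sty & !ph & !d] <- sc[sty & !ph & !d] + mu[["control_ordered"]]
    sc[sty & ph & d] <- sc[sty & ph & d] + mu[["phospho_disordered"]]
    sc[sty & !ph & d] <- sc[sty & !ph & d] + mu[["control_disordered"]]
    sc
  })
  names(tracks) <- pids

  sites <- data.frame(protein_id = pids[site$prot],
                      position = site$position,
                      residue = residue,
                      stringsAsFactors = FALSE)
  sites[RATIO_COLS] <- as.data.frame(ratios)
  sites <- sites[order(sites$protein_id, sites$position), ]
  ord <- order(pids[site$prot], site$position)
  rownames(sites) <- NULL

  truth <- data.frame(protein_id = pids[site$prot],
                      position = site$position,
                      class3 = site$class3,
                      sigma = sigma,
                      paired = site$paired,
                      planted_motif = plant,
                      stringsAsFactors = FALSE)[ord, ]
  rownames(truth) <- NULL

  motifs <- list(
    ProDir = parse_motif("ProDir", cfg$motif_pattern),
    PKA = parse_motif("PKA", "R-R-X-pS/pT"),
    CK2 = parse_motif("CK2", "pS/pT-X-X-E"))

  structure(list(sequences = seqs, sites = sites, profiles = profiles,
                 tracks = tracks, motifs = motifs, truth = truth,
                 config = cfg),
            class = "phosvar_sim")
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Writes `seqs.fa`, `sites.tsv`, `motifs.tsv`, and per-protein
#' `ss2/<id>.ss2`, `diso/<id>.diso`, `rates/<id>.res` files.
#'
#' @param sim A `phosvar_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "phosvar_sim") || is.list(sim))
  for (sub in c("", "ss2", "diso", "rates"))
    dir.create(file.path(dir, sub), showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$sequences, file.path(dir, "seqs.fa"))
  write_site_table(sim$sites, file.path(dir, "sites.tsv"))
  mo <- vapply(sim$motifs, function(m) paste0(m$name, "\t", m$pattern),
               character(1))
  writeLines(c("# name<TAB>pattern", mo), file.path(dir, "motifs.tsv"))
  for (pid in names(sim$sequences)) {
    ch <- strsplit(sim$sequences[[pid]], "")[[1]]
    prof <- sim$profiles[[pid]]
    ss <- strsplit(prof$ss, "")[[1]]
    n <- length(ch)
    probs <- matrix(0.05, n, 3)
    probs[cbind(seq_len(n), match(ss, c("C", "H", "E")))] <- 0.9
    writeLines(c("# PSIPRED VFORMAT (synthetic)", "",
                 sprintf("%4d %s %s  %5.3f %5.3f %5.3f", seq_len(n), ch,
                         ss, probs[, 1], probs[, 2], probs[, 3])),
               file.path(dir, "ss2", paste0(pid, ".ss2")))
    writeLines(c("# DISOPRED (synthetic)",
                 sprintf("%5d %s %s %5.2f", seq_len(n), ch,
                         ifelse(prof$disorder, "*", "."),
                         if (is.null(prof$prob)) rep(0.5, n) else prof$prob)),
               file.path(dir, "diso", paste0(pid, ".diso")))
    writeLines(c("# rates (synthetic rate4site output)",
                 sprintf("%5d %s %9.4f", seq_len(n), ch,
                         sim$tracks[[pid]])),
               file.path(dir, "rates", paste0(pid, ".res")))
  }
  invisible(dir)
}

#' Tiny hand-checkable worked example
#'
#' Three proteins, ten phospho-sites, every input format represented:
#' includes an N-terminal site (missing flank slots), two adjacent sites
#' (neighbors at distance 1), a site with a missing G2 ratio, a
#' proline-directed motif match and both ordered and disordered
#' contexts.
#'
#' @return A `phosvar_sim`-shaped list (see [simulate_dataset()]).
#' @export
make_worked_example <- function() {
  seqs <- c(
    #           1         2         3         4
    #  1234567890123456789012345678901234567890
    WE1 = "SADEKRMNLAQSPGHKTYVESTAGHLKRMEDSAPQTVKLE",
    WE2 = "MKDLRSSTGELKAVYPQDEGHSMNRLTACWKEDSGHLVRM",
    WE3 = "MAGSEVKLYRDPSAGHTMWQENKLSVRAGDTHYPELSCKV")
  ss <- c(
    WE1 = "CCCCHHHHHHCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",
    WE2 = "CCCCCCCCCCCEEEEECCCCCCCCCCCCCCCCCCCCCCCC",
    WE3 = "CCCCHHHHHCCCCCCCCCCCEEEECCCCCCCCCCCCCCCC")
  dis <- list(
    WE1 = c(rep(FALSE, 20), rep(TRUE, 20)),
    WE2 = c(rep(FALSE, 24), rep(TRUE, 16)),
    WE3 = c(rep(FALSE, 26), rep(TRUE, 14)))
  profiles <- lapply(names(seqs), function(p) {
    prob <- ifelse(dis[[p]], 0.9, 0.1)
    structure_profile(p, ss[[p]], dis[[p]], prob)
  })
  names(profiles) <- names(seqs)
  tracks <- list(
    WE1 = round(seq(-1, 1, length.out = 40) , 3),
    WE2 = round(sin(seq_len(40) / 5), 3),
    WE3 = round(cos(seq_len(40) / 7) - 0.5, 3))
  sites <- data.frame(
    protein_id = c("WE1", "WE1", "WE1", "WE1",
                   "WE2", "WE2", "WE2",
                   "WE3", "WE3", "WE3"),
    position = c(1L, 12L, 17L, 32L,
                 6L, 7L, 15L,
                 9L, 31L, 37L),
    residue = c("S", "S", "T", "S",
                "S", "S", "Y",
                "Y", "T", "S"),
    stringsAsFactors = FALSE)
  ratios <- rbind(
    c(1.0, 1.1, 0.9, 1.0, 1.1, 0.9),    # WE1:1   low variability
    c(0.5, 1.5, 2.5, 3.5, 2.0, 1.0),    # WE1:12  high, has P at +1
    c(1.2, 1.3, 1.2, 1.1, NA,  1.2),    # WE1:17  incomplete (G2 missing)
    c(0.2, 2.2, 4.0, 1.0, 3.0, 0.5),    # WE1:32  high, disordered
    c(1.0, 1.0, 1.2, 1.1, 1.0, 1.1),    # WE2:6   adjacent pair ...
    c(0.8, 2.8, 1.8, 3.8, 0.9, 2.0),    # WE2:7   ... neighbor at w=1
    c(1.0, 1.1, 1.0, 0.9, 1.0, 1.1),    # WE2:15  beta sheet (regular)
    c(0.9, 1.0, 1.1, 1.0, 0.9, 1.0),    # WE3:9   helix (regular)
    c(0.4, 1.9, 3.4, 2.4, 1.1, 2.9),    # WE3:31  disordered
    c(1.3, 2.3, 0.8, 3.3, 1.6, 2.6))    # WE3:37  disordered
  sites[RATIO_COLS] <- as.data.frame(ratios)
  motifs <- list(ProDir = parse_motif("ProDir", "pS/pT-P"),
                 PKA = parse_motif("PKA", "R-R-X-pS/pT"))
  structure(list(sequences = seqs, sites = sites, profiles = profiles,
                 tracks = tracks, motifs = motifs, truth = NULL,
                 config = NULL),
            class = "phosvar_sim")
}
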