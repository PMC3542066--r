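test_that("flank extraction is index-exact and NA beyond the termini", {
  seqs <- "ACDEFGHIKLMNPQRSTVWY"
  w <- extract_flank(seqs, 16)  # the S; offsets -6..+4 are positions 10..20
  expect_equal(unname(w[as.character(-6:4)]),
               strsplit("LMNPQRSTVWY", "")[[1]])
  expect_true(all(is.na(w[c("5", "6")])))
  expect_equal(unname(w["0"]), "S")
  w <- extract_flank("STAAAAA", 1)
  expect_true(all(is.na(w[as.character(-6:-1)])))
  expect_equal(unname(w["1"]), "T")
  expect_error(extract_flank(seqs, 1), "not S/T/Y")  # 'A' centre
  expect_error(extract_flank(seqs, 40), "outside")
})

test_that("two-sample logo flags planted frequency differences", {
  set.seed(41)
  mkwin <- function(n, plus1) {
    m <- matrix(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                       13 * n, TRUE), n, 13,
                dimnames = list(NULL, as.character(-6:6)))
    m[, "0"] <- "S"
    m[, "1"] <- plus1
    m
  }
  lo <- mkwin(20, c(rep("P", 15), rep("G", 5)))
  hi <- mkwin(20, c(rep("P", 5), rep("G", 15)))
  res <- two_sample_logo(lo, hi)
  cell <- res[res$offset == 1 & res$aa == "P", ]
  expect_equal(cell$delta_freq, 0.5)
  # Welch t on the two binary vectors, computed from first principles
  p1 <- 0.75; p2 <- 0.25
  s2 <- function(p, n) n * p * (1 - p) / (n - 1)
  tv <- (p1 - p2) / sqrt(s2(p1, 20) / 20 + s2(p2, 20) / 20)
  df <- (s2(p1, 20) / 20 + s2(p2, 20) / 20)^2 /
    ((s2(p1, 20) / 20)^2 / 19 + (s2(p2, 20) / 20)^2 / 19)
  expect_equal(cell$p_value, 2 * pt(-abs(tv), df))
  expect_equal(cell$flag, "ENRICHED")
  # identical sets: all deltas zero, nothing flagged
  res0 <- two_sample_logo(lo, lo)
  expect_true(all(res0$delta_freq == 0))
  expect_true(all(res0$flag == "NONE"))
  # degenerate zero-variance column falls back to the two-proportion z
  lo2 <- mkwin(20, rep("P", 20)); hi2 <- mkwin(20, rep("G", 20))
  cell2 <- two_sample_logo(lo2, hi2)
  cell2 <- cell2[cell2$offset == 1 & cell2$aa == "P", ]
  z <- (1 - 0) / sqrt(0.5 * 0.5 * (1 / 20 + 1 / 20))
  expect_equal(cell2$p_value, 2 * pnorm(-abs(z)))
  expect_equal(cell2$flag, "ENRICHED")
  expect_error(two_sample_logo(lo[1, , drop = FALSE], hi), "at least two")
})

test_that("logo per-offset delta frequencies sum to zero without missing slots", {
  set.seed(42)
  sim <- simulate_dataset(sim_config(n_proteins = 60, n_sites = 260,
                                     seed = 42))
  a <- add_variability(filter_complete(sim$sites))
  sp <- split_by_variability(a)
  lw <- flank_windows(sp$low, sim$sequences)
  hw <- flank_windows(sp$high, sim$sequences)
  # generator keeps sites >= 7 residues from the termini: no NA slots
  expect_false(anyNA(lw))
  res <- two_sample_logo(lw, hw)
  sums <- tapply(res$delta_freq, res$offset, sum)
  expect_true(all(abs(sums) < 1e-12))
})

test_that("composition profile recovers a planted proline excess", {
  set.seed(43)
  base <- rep(1 / 20, 20)
  rich <- base; rich[13] <- 2 * rich[13]  # double proline ('P' is 13th)
  rich <- rich / sum(rich)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  mk <- function(n, pr) matrix(sample(aa, 12 * n, TRUE, prob = pr), n, 12,
                               dimnames = list(NULL,
                                 as.character(c(-6:-1, 1:6))))
  q <- mk(400, base); p <- mk(400, rich)
  res <- composition_profile(p, q, n_boot = 200)
  pr <- res[res$aa == "P", ]
  # planted (P-Q)/Q is (2/21)/(1/21) - 1 ~= 1 after renormalisation
  expect_gt(pr$rel_diff, 0.4)
  expect_true(pr$ci_lo <= 21 / 22 * 2 - 1 + 0.3)  # CI near planted value
  expect_true(pr$significant)
  # identical sets: all zero, none significant
  res0 <- composition_profile(q, q, n_boot = 50)
  expect_true(all(res0$rel_diff == 0))
  expect_false(any(res0$significant))
  # absent background residue: undefined marker, no crash
  q_noW <- q; q_noW[q_noW == "W"] <- "A"
  resW <- composition_profile(p, q_noW, n_boot = 20)
  expect_false(resW$defined[resW$aa == "W"])
  expect_true(is.na(resW$rel_diff[resW$aa == "W"]))
})

test_that("composition bootstrap intervals reach nominal coverage", {
  set.seed(44)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  base <- rep(1 / 20, 20)
  rich <- base; rich[13] <- 1.5 * rich[13]; rich <- rich / sum(rich)
  truth <- (rich[13] - base[13]) / base[13]
  mk <- function(n, pr) matrix(sample(aa, 12 * n, TRUE, prob = pr), n, 12,
                               dimnames = list(NULL,
                                 as.character(c(-6:-1, 1:6))))
  hits <- logical(150)
  for (b in seq_along(hits)) {
    res <- composition_profile(mk(150, rich), mk(150, base),
                               n_boot = 120, conf = 0.90)
    pr <- res[res$aa == "P", ]
    hits[b] <- pr$ci_lo <= truth && truth <= pr$ci_hi
  }
  # 90% nominal; allow binomial slack at 150 replicates
  expect_gte(mean(hits), 0.84)
})

test_that("neighbor detection uses pairwise distances within a protein", {
  tab <- data.frame(protein_id = c("P1", "P1", "P1", "P2"),
                    position = c(10L, 13L, 25L, 10L),
                    residue = "S", stringsAsFactors = FALSE)
  expect_equal(find_neighbors(tab, 2), c(FALSE, FALSE, FALSE, FALSE))
  expect_equal(find_neighbors(tab, 3), c(TRUE, TRUE, FALSE, FALSE))
  tab2 <- data.frame(protein_id = "P1", position = c(10L, 11L, 25L),
                     residue = "S", stringsAsFactors = FALSE)
  expect_equal(find_neighbors(tab2, 1), c(TRUE, TRUE, FALSE))
  # a lone site has no neighbors unless a wider pool supplies them
  one <- data.frame(protein_id = "P1", position = 12L, residue = "S",
                    stringsAsFactors = FALSE)
  expect_false(find_neighbors(one, 5))
  expect_true(find_neighbors(one, 1, pool = tab2))
  # the distant site stays neighborless even against the pool
  expect_false(find_neighbors(tab2[3, ], 5, pool = tab2))
})

test_that("neighbor flags are nested in w and tables follow", {
  sim <- simulate_dataset(sim_config(n_proteins = 150, n_sites = 700,
                                     seed = 45))
  a <- add_variability(filter_complete(sim$sites))
  cl <- suppressWarnings(classify_sites(a, sim$profiles))
  prev <- rep(FALSE, nrow(cl))
  for (w in 1:6) {
    cur <- find_neighbors(cl, w)
    expect_true(all(cur[prev]))  # neighbor(w) => neighbor(w+1)
    prev <- cur
  }
  ne <- neighbor_enrichment(cl, w = 1:5)
  expect_true(all(diff(ne$dis_nb) >= 0))
  expect_true(all(diff(ne$ord_nb) >= 0))
  expect_equal(ne$dis_nb + ne$dis_no, rep(sum(cl$category2 == "DISORDERED"), 5))
})

test_that("degenerate neighbor tables surface boundary odds ratios", {
  fake <- data.frame(protein_id = rep(c("A", "B"), each = 4),
                     position = rep(c(10L, 11L, 30L, 50L), 2),
                     residue = "S",
                     category2 = rep(c("DISORDERED", "ORDERED"), each = 4),
                     stringsAsFactors = FALSE)
  # disordered protein A has the adjacent pair; ordered B sites all isolated
  fake$position[5:8] <- c(10L, 20L, 30L, 50L)
  ne <- neighbor_enrichment(fake, w = 1)
  expect_identical(ne$odds_ratio, Inf)
  expect_identical(ne$sample_odds_ratio, Inf)
})
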