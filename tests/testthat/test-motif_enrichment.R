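test_that("motif grammar parses offsets, sets and the centre token", {
  m <- parse_motif("CDK5", "pS/pT-P")
  expect_equal(m$offsets, c(0L, 1L))
  expect_setequal(m$allowed[[1]], c("S", "T"))
  expect_equal(m$allowed[[2]], "P")
  m <- parse_motif("PKA", "R-R-X-pS/pT")
  expect_equal(m$offsets, -3:0)
  expect_equal(m$allowed[[1]], "R")
  expect_equal(m$allowed[[2]], "R")
  expect_length(m$allowed[[3]], 20)
  m <- parse_motif("ACID", "pS-X-X-[DE]")
  expect_setequal(m$allowed[[4]], c("D", "E"))
  expect_error(parse_motif("BAD", "S-T"), "exactly one")
  expect_error(parse_motif("BAD", "pS-P-pT"), "exactly one")
  expect_error(parse_motif("BAD", paste(c(rep("X", 7), "pS"),
                                        collapse = "-")), "-6")
  expect_error(parse_motif("BAD", "pS-Z9"), "cannot parse|unknown")
})

test_that("the bundled example motif file parses into valid definitions", {
  f <- system.file("extdata", "textbook_motifs.tsv", package = "phosvar")
  m <- read_motifs(f)
  expect_gte(length(m), 10)
  expect_true(all(vapply(m, inherits, logical(1), "motif_definition")))
  expect_equal(m$PKA_basophilic$offsets, -3:0)
})

test_that("motif matching honours allowed sets and missing slots", {
  win <- extract_flank("AAAAAARSPAAAA", 8)  # S at 8, R at -1, P at +1
  expect_true(match_motif(win, parse_motif("m", "pS/pT-P")))
  expect_true(match_motif(win, parse_motif("m", "R-pS")))
  expect_false(match_motif(win, parse_motif("m", "R-R-X-pS/pT")))
  # missing required slot (position near terminus) never matches
  win2 <- extract_flank("SPAAAAAA", 1)
  expect_true(is.na(win2["-1"]))
  expect_false(match_motif(win2, parse_motif("m", "R-pS")))
  expect_true(match_motif(win2, parse_motif("m", "pS-P")))
})

test_that("2D enrichment scores follow the mean-rank formula exactly", {
  # members hold the m largest values: score hits the +1 bound
  x <- 1:20; y <- rep(0, 20)
  mem <- x >= 16
  r <- suppressWarnings(enrichment_2d(x, y, cbind(m = mem)))
  expect_equal(r$s_var, 1)
  # symmetric member ranks centre the score at 0
  x4 <- 1:10; mem4 <- c(TRUE, rep(FALSE, 8), TRUE)  # ranks 1 and 10
  r <- enrichment_2d(x4, rep(1:5, 2), cbind(m = mem4))
  expect_equal(r$s_var, 0)
  # n = 10, m = 3, member x-ranks {2, 5, 9}
  x10 <- seq(0.1, 1, 0.1)
  mem10 <- rank(x10) %in% c(2, 5, 9)
  r <- enrichment_2d(x10, rnorm(10), cbind(m = mem10))
  expect_equal(r$s_var, 2 * (16 / 3 - 5.5) / 7)
  expect_equal(r$s_var, -1 / 21, tolerance = 1e-12)
})

test_that("2D scores are invariant under monotone transforms of a dimension", {
  set.seed(51)
  x <- rexp(60); y <- rnorm(60)
  mem <- runif(60) < 0.3
  mem[1] <- TRUE
  r0 <- enrichment_2d(x, y, cbind(m = mem))
  r1 <- enrichment_2d(log(x), y, cbind(m = mem))
  r2 <- enrichment_2d(x, exp(y / 2), cbind(m = mem))
  expect_equal(r1$s_var, r0$s_var)
  expect_equal(r1$p_value, r0$p_value)
  expect_equal(r2$s_dis, r0$s_dis)
})

test_that("degenerate motif memberships are skipped with a warning", {
  x <- rnorm(20); y <- rnorm(20)
  mm <- cbind(none = rep(FALSE, 20), all = rep(TRUE, 20),
              ok = c(rep(TRUE, 5), rep(FALSE, 15)))
  expect_warning(expect_warning(r <- enrichment_2d(x, y, mm), "none"),
                 "all")
  expect_equal(r$motif, "ok")
  expect_error(suppressWarnings(
    enrichment_2d(x, y, cbind(a = rep(FALSE, 20)))), "no testable")
  expect_error(enrichment_2d(rnorm(5), rnorm(5), cbind(m = rep(TRUE, 5))),
               "at least 10")
})

test_that("excluding proline-directed sites removes only matching sites", {
  sim <- simulate_dataset(sim_config(n_proteins = 120, n_sites = 600,
                                     seed = 52))
  a <- add_variability(filter_complete(sim$sites))
  pro <- sim$motifs["ProDir"]
  kept <- exclude_motif_sites(a, sim$sequences, pro)
  win <- flank_windows(a, sim$sequences)
  hit <- apply(win, 1, match_motif, motif = pro$ProDir)
  expect_equal(nrow(kept), sum(!hit))
  none <- exclude_motif_sites(a, sim$sequences,
                              list(Z = parse_motif("Z", "W-W-W-pY-W-W-W")))
  expect_equal(nrow(none), nrow(a))
  expect_warning(
    empty <- exclude_motif_sites(a, sim$sequences,
                                 list(any = parse_motif("any", "pS/pT/pY"))),
    "every site")
  expect_equal(nrow(empty), 0)
})

test_that("the disorder contrast persists when planted independently of prolines", {
  # variability is planted per structural class, not via the motif, so
  # removing proline-directed sites must not abolish the contrast
  sim <- simulate_dataset(sim_config(seed = 53))
  a <- add_variability(filter_complete(sim$sites))
  cl <- suppressWarnings(classify_sites(a, sim$profiles))
  base <- compare_category_variability(cl)
  kept <- exclude_motif_sites(cl, sim$sequences, sim$motifs["ProDir"])
  after <- compare_category_variability(kept)
  expect_lt(after$ks2$p_value, 1e-6)
  expect_equal(diff(after$by_category3$median) > 0, c(TRUE, TRUE))
  expect_lt(nrow(kept), nrow(cl))
})
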