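test_that("the generator is deterministic given its seed", {
  cfg <- sim_config(n_proteins = 30, n_sites = 120, seed = 71)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$tracks, s2$tracks)
  s3 <- simulate_dataset(sim_config(n_proteins = 30, n_sites = 120,
                                    seed = 72))
  expect_false(identical(s1$sites, s3$sites))
  # no hidden global RNG pollution beyond the local scope
  set.seed(5); before <- .Random.seed
  invisible(simulate_dataset(cfg))
  expect_identical(.Random.seed, before)
})

test_that("written dataset files reproduce the in-memory objects", {
  sim <- simulate_dataset(sim_config(n_proteins = 8, n_sites = 40,
                                     seed = 73))
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  expect_equal(read_fasta(file.path(d, "seqs.fa")), sim$sequences)
  back <- read_site_table(file.path(d, "sites.tsv"))
  expect_equal(back$position, sim$sites$position)
  expect_equal(as.matrix(back[4:9]), as.matrix(sim$sites[4:9]),
               tolerance = 1e-5)
  pid <- names(sim$sequences)[1]
  expect_identical(
    as.character(read_psipred_ss2(file.path(d, "ss2", paste0(pid, ".ss2")))),
    sim$profiles[[pid]]$ss)
  expect_identical(
    read_disopred(file.path(d, "diso", paste0(pid, ".diso")))$disorder,
    sim$profiles[[pid]]$disorder)
  expect_equal(
    as.numeric(read_rate4site(file.path(d, "rates", paste0(pid, ".res")))),
    sim$tracks[[pid]], tolerance = 1e-3)
})

test_that("generated sites respect sequences, categories and the truth table", {
  sim <- simulate_dataset(sim_config(n_proteins = 60, n_sites = 300,
                                     seed = 74))
  expect_silent(validate_sites_against_sequences(sim$sites, sim$sequences))
  cl <- classify_sites(add_variability(filter_complete(sim$sites)),
                       sim$profiles)  # no D1 warning expected: generator
  # never marks helix/sheet residues disordered
  key <- paste(cl$protein_id, cl$position)
  tkey <- paste(sim$truth$protein_id, sim$truth$position)
  expect_true(all(key %in% tkey))
  m <- match(key, tkey)
  expect_equal(as.character(cl$category3), sim$truth$class3[m])
  # realized per-site variability equals the planted sigma exactly
  expect_equal(cl$variability, sim$truth$sigma[m], tolerance = 1e-12)
})

test_that("class-median calibration and missingness hit their targets", {
  cfg <- sim_config(seed = 75)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$sites), cfg$n_sites)
  complete <- filter_complete(sim$sites)
  expect_equal(nrow(complete), round(cfg$n_sites * (1 - cfg$missing_rate)))
  cl <- suppressWarnings(classify_sites(add_variability(complete),
                                        sim$profiles))
  med <- tapply(cl$variability, cl$category3, median)
  expect_lt(abs(med[["REGULAR"]] - 1.65), 0.05)
  expect_lt(abs(med[["IRREGULAR"]] - 1.83), 0.05)
  expect_lt(abs(med[["DISORDERED"]] - 2.22), 0.05)
  # class proportions mirror the planted 145:353:4675 split
  props <- as.numeric(table(cl$category3)[c("REGULAR", "IRREGULAR",
                                            "DISORDERED")]) / nrow(cl)
  expect_equal(props, c(145, 353, 4675) / 5173, tolerance = 0.1)
})

test_that("infeasible configurations fail loudly instead of degrading", {
  expect_error(sim_config(seed = 1, class_props = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(sim_config(n_sites = 100), "seed is mandatory")
  # far too many sites for the residues available
  cfg <- sim_config(n_proteins = 2, mean_protein_length = 150,
                    n_sites = 400, seed = 76)
  expect_error(simulate_dataset(cfg), "infeasible")
})

test_that("the worked example exercises every boundary the docs promise", {
  we <- make_worked_example()
  expect_equal(nrow(we$sites), 10)
  expect_length(we$sequences, 3)
  expect_silent(validate_sites_against_sequences(we$sites, we$sequences))
  # N-terminal site has missing upstream flank slots
  w <- extract_flank(we$sequences[["WE1"]], 1)
  expect_true(all(is.na(w[as.character(-6:-1)])))
  # two adjacent sites are neighbors already at w = 1
  nb <- find_neighbors(we$sites, 1)
  expect_true(nb[we$sites$protein_id == "WE2" & we$sites$position == 6])
  expect_true(nb[we$sites$protein_id == "WE2" & we$sites$position == 7])
  # one site is incomplete and drops out of the six-phase analysis set
  expect_equal(nrow(filter_complete(we$sites, 6)), 9)
  # a proline-directed motif match exists
  win <- flank_windows(filter_complete(we$sites, 6), we$sequences)
  expect_true(any(apply(win, 1, match_motif, motif = we$motifs$ProDir)))
  # all three structural categories are represented
  cl <- classify_sites(add_variability(filter_complete(we$sites)),
                       we$profiles)
  expect_setequal(unique(as.character(cl$category3)),
                  c("REGULAR", "IRREGULAR", "DISORDERED"))
})
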