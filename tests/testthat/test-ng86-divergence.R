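test_that("NG86 site counts match hand-enumerated codons", {
  expect_equal(ng86_site_counts("ATG")$s_sites, 0)
  expect_equal(ng86_site_counts("ATG")$n_sites, 3)
  expect_equal(ng86_site_counts("GCT")$s_sites, 1)
  expect_equal(ng86_site_counts("TTT")$s_sites, 1 / 3)
  # n + s = 3 per counted codon; N-containing codons are excluded
  sc <- ng86_site_counts("ATGNNNGCT")
  expect_equal(sc$codons, 2)
  expect_equal(sc$n_sites + sc$s_sites, 6)
  expect_error(ng86_site_counts("ATGTAA"), "stop")
  expect_error(ng86_site_counts("ATGA"), "divisible")
})

test_that("NG86 site counts equal the mutant-enumeration oracle for all sense codons", {
  for (cod in SENSE_CODONS) {
    want <- oracle_site_counts(cod)
    got <- ng86_site_counts(cod)
    expect_equal(got$s_sites, want$s_sites, tolerance = 1e-12, label = cod)
    expect_equal(got$n_sites, want$n_sites, tolerance = 1e-12, label = cod)
  }
})

test_that("pairwise NG86 reproduces the hand-worked single-difference case", {
  a <- strrep("AAA", 10)
  b <- paste0(strrep("AAA", 9), "AAG")
  p <- ng86_pairwise(a, b)
  expect_equal(p$ps, 0.3)
  expect_equal(p$ds, -0.75 * log(1 - 4 * 0.3 / 3))
  expect_equal(p$dn, 0)
  ident <- ng86_pairwise(a, a)
  expect_equal(c(ident$dn, ident$ds), c(0, 0))
  # saturation: p >= 3/4 has no JC correction
  expect_true(is.na(jc_correct(0.8)))
})

test_that("pathway-averaged codon differences equal the enumeration oracle", {
  skip_if_not_installed("pracma")
  set.seed(3)
  pairs <- cbind(sample(SENSE_CODONS, 120, replace = TRUE),
                 sample(SENSE_CODONS, 120, replace = TRUE))
  # include stop-adjacent multi-step cases explicitly
  pairs <- rbind(pairs, c("TGG", "TAT"), c("TTA", "TAC"), c("AGA", "TCA"))
  for (r in seq_len(nrow(pairs))) {
    want <- oracle_path_counts(pairs[r, 1], pairs[r, 2])
    got <- ng86_pairwise(pairs[r, 1], pairs[r, 2])
    expect_equal(got$Nd, unname(want["nd"]), tolerance = 1e-12,
                 label = paste(pairs[r, ], collapse = "->"))
    expect_equal(got$Sd, unname(want["sd"]), tolerance = 1e-12)
  }
})

test_that("branch assignment on the star tree handles the degenerate cases", {
  one_dev <- c(sp1 = paste0("AAG", strrep("GCT", 99)),
               sp2 = paste0("AAA", strrep("GCT", 99)),
               sp3 = paste0("AAA", strrep("GCT", 99)))
  bc <- branch_counts_3taxon(one_dev)
  expect_gt(bc$ds[1], 0)
  expect_equal(bc$Sd[2:3], c(0, 0))
  expect_equal(bc$Nd, c(0, 0, 0))

  same <- c(sp1 = strrep("GCT", 50), sp2 = strrep("GCT", 50),
            sp3 = strrep("GCT", 50))
  bc0 <- branch_counts_3taxon(same)
  expect_equal(bc0$dn, c(0, 0, 0))
  expect_equal(bc0$ds, c(0, 0, 0))
  expect_equal(attr(bc0, "skipped_fraction"), 0)
})

test_that("branch sums match pairwise NG86 when multi-hit columns are rare", {
  p <- simulation_params(n_genes = 60L, codons_per_gene = 300L,
                         branch_dS = c(sp1 = 0.02, sp2 = 0.015, sp3 = 0.015),
                         omega = 0.15, rng_seed = 41L)
  sim <- simulate_triplet_transcriptomes(p)
  aln <- vapply(sim$transcripts, function(t) paste(t$sequences, collapse = ""), "")
  bc <- branch_counts_3taxon(aln)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    pw <- ng86_pairwise(aln[pair[1]], aln[pair[2]])
    expect_equal(bc$ds[pair[1]] + bc$ds[pair[2]], pw$ds, tolerance = 0.05)
  }
})

test_that("star decomposition recovers branch distances from pairwise sums", {
  p <- simulation_params(n_genes = 80L, codons_per_gene = 250L, rng_seed = 19L)
  sim <- simulate_triplet_transcriptomes(p)
  aln <- vapply(sim$transcripts, function(t) paste(t$sequences, collapse = ""), "")
  bd <- branch_distances_star(aln)
  p12 <- ng86_pairwise(aln[1], aln[2])
  expect_equal(bd$ds[1] + bd$ds[2], p12$ds, tolerance = 1e-12)
  expect_true(all(bd$ds >= 0))
})

test_that("variable-site proportions exclude gapped columns", {
  expect_equal(pairwise_variable_sites("ACGT", "ACGT"), 0)
  expect_equal(pairwise_variable_sites("ACGT", "ACGA"), 0.25)
  expect_equal(pairwise_variable_sites("AC-T", "ACGT"), 0)
  expect_error(pairwise_variable_sites("---", "AAA"), "comparable")
  expect_error(pairwise_variable_sites("AA", "AAA"), "length")
})

test_that("unit confidence intervals behave like t intervals and reach nominal coverage", {
  expect_error(unit_confidence(1), "at least 2")
  same <- unit_confidence(rep(2.5, 8))
  expect_equal(same$lo, 2.5)
  expect_equal(same$hi, 2.5)
  two <- unit_confidence(c(1, 3))
  expect_equal(two$hi - two$mean, qt(0.975, 1) * sd(c(1, 3)) / sqrt(2))

  set.seed(77)
  n <- 20; reps <- 10000; mu <- 1.7
  x <- matrix(rnorm(n * reps, mu, 0.6), nrow = n)
  means <- colMeans(x)
  sds <- sqrt((colSums(x^2) - n * means^2) / (n - 1))
  half <- qt(0.975, n - 1) * sds / sqrt(n)
  coverage <- mean(abs(means - mu) <= half)
  expect_gt(coverage, 0.94)
  expect_lt(coverage, 0.96)
})

test_that("clock calibration and split times follow the star-tree arithmetic", {
  cal <- calibrate_rate(2.64, 245e6)
  expect_equal(cal$rate_per_year, 1.32 / 245e6)
  expect_equal(calibrate_rate(2.0, 1e8)$rate_per_year, 1e-8)
  expect_equal(calibrate_rate(2.0, 0.5e8)$rate_per_year,
               2 * calibrate_rate(2.0, 1e8)$rate_per_year)
  expect_error(calibrate_rate(-1, 1e8), "positive")

  ts <- clock_split_times(c(sp1 = 0.139, sp2 = 0.073, sp3 = 0.073), 8.4e-9)
  expect_equal(ts$t_inner_years / 1e6, 0.073 / 8.4e-9 / 1e6)
  expect_equal(ts$t_outer_years / 1e6, (0.106 / 8.4e-9) / 1e6)
  # star symmetry: equal branches give equal split times d/r
  eq <- clock_split_times(c(a = 0.05, b = 0.05, c = 0.05), 1e-8)
  expect_equal(eq$t_inner_years, eq$t_outer_years)
  expect_equal(eq$t_inner_years, 0.05 / 1e-8)
  expect_error(clock_split_times(c(0.1, 0.1, 0.1), -1), "positive")
})
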