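mk_pileup <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(contig = r[[1]], position = as.integer(r[[2]]), ref = r[[3]],
               depth = as.integer(r[[4]]), A = as.integer(r[[5]]),
               C = as.integer(r[[6]]), G = as.integer(r[[7]]),
               T = as.integer(r[[8]]), gap = as.integer(r[[9]]))))
  df
}

test_that("the caller enforces coverage, MAF, contig-length and edge filters", {
  cfg <- analysis_config()
  lens <- c(c1 = 200L)
  # depth 9: below the coverage floor
  p1 <- mk_pileup(list(list("c1", 50, "A", 9, 5, 0, 4, 0, 0)))
  expect_equal(nrow(call_variants(p1, lens, cfg)$calls), 0L)
  # maf exactly 0.3 is NOT called (strict >)
  p2 <- mk_pileup(list(list("c1", 50, "A", 10, 7, 0, 3, 0, 0)))
  expect_equal(nrow(call_variants(p2, lens, cfg)$calls), 0L)
  # maf just above 0.3 is called
  p3 <- mk_pileup(list(list("c1", 50, "A", 13, 9, 0, 4, 0, 0)))
  out3 <- call_variants(p3, lens, cfg)$calls
  expect_equal(out3$major_allele, "A")
  expect_equal(out3$minor_allele, "G")
  expect_equal(out3$maf, 4 / 13)
  # depth above the ceiling
  p4 <- mk_pileup(list(list("c1", 50, "A", 151, 90, 0, 61, 0, 0)))
  expect_equal(nrow(call_variants(p4, lens, cfg)$calls), 0L)
  # position 10 excluded by the edge trim, position 11 eligible
  p5 <- mk_pileup(list(list("c1", 10, "A", 20, 12, 0, 8, 0, 0),
                       list("c1", 11, "A", 20, 12, 0, 8, 0, 0),
                       list("c1", 190, "A", 20, 12, 0, 8, 0, 0),
                       list("c1", 191, "A", 20, 12, 0, 8, 0, 0)))
  out5 <- call_variants(p5, lens, cfg)
  expect_equal(out5$calls$position, c(11L, 190L))
  expect_equal(out5$surveyed$position, c(11L, 190L))
  # contig of exactly 100 nt is excluded entirely
  p6 <- mk_pileup(list(list("c2", 50, "A", 20, 12, 0, 8, 0, 0)))
  expect_equal(nrow(call_variants(p6, c(c2 = 100L), cfg)$calls), 0L)
  expect_equal(nrow(call_variants(p6, c(c2 = 101L), cfg)$calls), 1L)
  expect_error(call_variants(p6, c(c9 = 100L), cfg), "missing")
})

test_that("gap alleles count as indels and third alleles above the error allowance skip the site", {
  cfg <- analysis_config()
  lens <- c(c1 = 200L)
  pg <- mk_pileup(list(list("c1", 50, "A", 20, 12, 0, 0, 0, 8)))
  out <- call_variants(pg, lens, cfg)
  expect_equal(out$n_indels, 1L)
  expect_equal(nrow(out$calls), 0L)
  # a 10% third allele is incompatible with one diploid individual
  p3a <- mk_pileup(list(list("c1", 50, "A", 30, 15, 3, 12, 0, 0)))
  expect_equal(nrow(call_variants(p3a, lens, cfg)$calls), 0L)
})

test_that("every emitted call satisfies the filters, and raising maf_min never adds calls", {
  ts <- transcript_set("sp", setNames(
    vapply(1:6, function(i) random_codon_seq(80, seed = 100 + i), ""),
    paste0("g", 1:6)))
  pu <- simulate_pileups(ts, 0.02, 0.005, rng_seed = 9)$pileup
  lens <- setNames(nchar(ts$sequences), names(ts$sequences))
  cfg <- analysis_config()
  out <- call_variants(pu, lens, cfg)
  expect_true(all(out$calls$depth >= cfg$cov_min & out$calls$depth <= cfg$cov_max))
  expect_true(all(out$calls$maf > cfg$maf_min))
  expect_true(all(out$calls$position > cfg$edge_trim))
  expect_true(all(out$calls$major_allele != out$calls$minor_allele))

  key <- function(cl) paste(cl$contig, cl$position)
  for (m in c(0.35, 0.4, 0.45)) {
    stricter <- call_variants(pu, lens, analysis_config(maf_min = m))$calls
    expect_true(all(key(stricter) %in% key(out$calls)))
    expect_lte(nrow(stricter), nrow(out$calls))
    out <- list(calls = stricter)
  }
})

test_that("polarization follows the two-outgroup concordance rule", {
  calls <- data.frame(contig = "c1", position = c(30L, 31L, 32L),
                      major_allele = "A", minor_allele = "G",
                      maf = 0.4, depth = 20L)
  pol <- polarize_calls(calls, c("A", "A", "C"), c("A", "G", "C"))
  expect_equal(pol$polarization,
               c("ancestral_major", "unpolarized", "unpolarized"))
  expect_equal(pol$derived_allele[1], "G")
  # ancestral equals the minor allele
  pol2 <- polarize_calls(calls[1, ], "G", "G")
  expect_equal(pol2$polarization, "ancestral_minor")
  expect_equal(pol2$derived_allele, "A")
  # unalignable positions stay unpolarized rather than erroring
  pol3 <- polarize_calls(calls[1, ], NA, "A")
  expect_equal(pol3$polarization, "unpolarized")
})

test_that("effect classification substitutes the derived allele into the ancestral codon", {
  # transcript: 6 nt UTR, then AAA AAA ...; the ORF covers the tail
  seq <- paste0("CCTCCC", strrep("AAA", 40))
  orf <- structure(list(strand = "+", frame = 0L, start = 6L,
                        end = 6L + 120L, codon_length = 40L), class = "orf")
  mk_call <- function(pos, major, minor, anc) {
    d <- data.frame(contig = "c1", position = pos, major_allele = major,
                    minor_allele = minor, maf = 0.4, depth = 20L)
    polarize_calls(d, anc, anc)
  }
  # third codon position AAA->AAG: Lys->Lys, synonymous
  syn <- classify_effects(mk_call(12L, "A", "G", "A"), orf, seq)
  expect_equal(syn$effect, "synonymous")
  # first codon position AAA->GAA: Lys->Glu, nonsynonymous
  ns <- classify_effects(mk_call(10L, "A", "G", "A"), orf, seq)
  expect_equal(ns$effect, "nonsynonymous")
  # 5' UTR position
  utr <- classify_effects(mk_call(3L, "C", "T", "C"), orf, seq)
  expect_equal(utr$effect, "noncoding")
  # unpolarized stays undetermined
  unp <- mk_call(12L, "A", "G", "A")
  unp$polarization <- "unpolarized"
  expect_equal(classify_effects(unp, orf, seq)$effect, "undetermined")
})

test_that("piA/piS uses class-specific site denominators", {
  calls <- data.frame(effect = c(rep("nonsynonymous", 4), rep("synonymous", 4)))
  even <- pi_a_pi_s(calls, list(n_sites = 100, s_sites = 100))
  expect_equal(even$ratio, 1)
  # back-computation consistent with published count ratios:
  # 24 nonsyn and 22 syn calls over an n/s site ratio of 3.41 gives ~0.32
  calls2 <- data.frame(effect = c(rep("nonsynonymous", 24), rep("synonymous", 22)))
  sites <- list(n_sites = 341, s_sites = 100)
  expect_equal(round(pi_a_pi_s(calls2, sites)$ratio, 2), 0.32)
  # undefined ratio is flagged, not an error
  none <- pi_a_pi_s(data.frame(effect = "nonsynonymous"),
                    list(n_sites = 10, s_sites = 10))
  expect_false(none$ratio_defined)
  expect_error(pi_a_pi_s(calls, list(n_sites = 0, s_sites = 10)), "positive")
})

test_that("surveyed-position site counts are consistent with whole-ORF counts", {
  seq <- random_codon_seq(100, seed = 55)
  orf <- longest_orf(seq, search_reverse = FALSE)
  full <- coding_site_counts(seq, orf)
  all_pos <- coding_site_counts(seq, orf, positions = seq_len(nchar(seq)))
  expect_equal(full, all_pos)
  half <- coding_site_counts(seq, orf, positions = 1:150)
  expect_lt(half$s_sites, full$s_sites)
  expect_equal(half$n_sites + half$s_sites, 150)
})
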