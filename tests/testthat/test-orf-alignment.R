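test_that("minimum ORF length follows the binomial zero-stop criterion", {
  expect_identical(min_orf_codons(0.05), 63L)
  # log(0.01)/log(61/64) = 95.92 rounds up to 96
  expect_identical(min_orf_codons(0.01), 96L)
  expect_identical(min_orf_codons(0.999), 1L)
  expect_error(min_orf_codons(0), "alpha")
  expect_error(min_orf_codons(1), "alpha")
  # non-increasing in alpha
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  expect_true(all(diff(vapply(alphas, min_orf_codons, 1L)) >= 0))
})

test_that("longest ORF finds the maximal stop-free codon run", {
  o <- longest_orf("ATGAAATGA", search_reverse = FALSE)
  expect_equal(o$frame, 0)
  expect_equal(o$codon_length, 2)
  expect_equal(orf_sequence("ATGAAATGA", o), "ATGAAA")

  s63 <- random_codon_seq(63, seed = 17)
  o63 <- longest_orf(s63, search_reverse = FALSE)
  expect_equal(o63$codon_length, 63)
  expect_equal(orf_sequence(s63, o63), s63)

  # start-codon requirement trims the run to its first ATG
  o_start <- longest_orf("CCCATGAAACCC", require_start = TRUE,
                         search_reverse = FALSE)
  expect_equal(substr(orf_sequence("CCCATGAAACCC", o_start), 1, 3), "ATG")

  expect_error(longest_orf("AT"), "shorter")
})

test_that("longest ORF equals the exhaustive six-frame oracle on random input", {
  set.seed(23)
  for (r in 1:40) {
    s <- random_dna(sample(60:260, 1),
                    alphabet = c("A", "C", "G", "T",
                                 if (r %% 4 == 0) "N"))
    got <- longest_orf(s)
    want <- oracle_longest_orf(s)
    expect_equal(got[c("strand", "frame", "start", "end", "codon_length")],
                 want[c("strand", "frame", "start", "end", "codon_length")])
    # the reported ORF never contains a stop codon
    expect_false(grepl("*", translate_dna(orf_sequence(s, got)), fixed = TRUE))
  }
})

test_that("curation cuts at frame-shift gaps and moves in-frame gaps to codon boundaries", {
  # no gaps: identity
  aln0 <- c(a = "ATGAAACCC", b = "ATGAAACCC")
  expect_equal(curate_alignment(aln0), aln0)

  # frame-shift 2-nt gap starting at column 31: all rows cut to 30 columns
  r1 <- paste0(strrep("ATG", 10), "--", "AAA")
  r2 <- paste0(strrep("ATG", 10), "CC", "AAA")
  cur <- curate_alignment(c(a = r1, b = r2))
  expect_equal(unique(nchar(cur)), 30L)
  expect_equal(cur[["b"]], strrep("ATG", 10))

  # 3-nt gap starting mid-codon is relocated to the nearest codon boundary
  cur2 <- curate_alignment(c(a = "ATGA---AAATT", b = "ATGACCCAAATT"))
  expect_equal(cur2[["a"]], "ATG---AAAATT")
  # residue multiset of every row is unchanged
  residues <- function(x) sort(strsplit(gsub("-", "", x), "")[[1]])
  expect_equal(residues(cur2[["a"]]), residues("ATGA---AAATT"))
  expect_equal(residues(cur2[["b"]]), residues("ATGACCCAAATT"))
})

test_that("curation never creates residues and keeps gap runs in frame", {
  set.seed(13)
  for (r in 1:20) {
    n <- 3 * sample(20:40, 1)
    base <- random_codon_seq(n / 3)
    rows <- vapply(1:3, function(i) {
      s <- strsplit(base, "")[[1]]
      # inject 0-2 gap runs of length 1-6
      for (g in seq_len(sample(0:2, 1))) {
        at <- sample(length(s) - 8, 1)
        len <- sample(1:6, 1)
        s[at:(at + len - 1)] <- "-"
      }
      paste(s, collapse = "")
    }, "")
    names(rows) <- c("a", "b", "c")
    cur <- curate_alignment(rows)
    w <- unique(nchar(cur))
    expect_length(w, 1)
    expect_equal(w %% 3, 0)
    for (nm in names(rows)) {
      before <- gsub("-", "", rows[[nm]])
      after <- gsub("-", "", cur[[nm]])
      # truncation only: curated residues are a prefix-permutation bounded by input
      expect_lte(nchar(after), nchar(before))
      expect_equal(sort(strsplit(after, "")[[1]]),
                   sort(strsplit(substr(before, 1, nchar(after)), "")[[1]]))
    }
    # remaining gap runs are in frame at codon boundaries
    for (row in cur) {
      runs <- gregexpr("-+", row)[[1]]
      if (runs[1] == -1) next
      expect_true(all(attr(runs, "match.length") %% 3 == 0))
      expect_true(all((runs - 1) %% 3 == 0))
    }
  }
})

test_that("length filter keeps 189-column alignments and drops shorter ones", {
  mk <- function(n) c(a = strrep("A", n), b = strrep("A", n))
  out <- filter_short(list(keep = mk(189), drop = mk(186), big = mk(300)))
  expect_setequal(names(out$kept), c("keep", "big"))
  expect_equal(out$log$alignment, "drop")
  empty <- filter_short(list())
  expect_length(empty$kept, 0)
  expect_equal(nrow(empty$log), 0)
})

test_that("concatenation deals genes into nearly equal units, deterministically", {
  mk <- function(i) c(a = "ATGAAA", b = "ATGAAA", c = "ATGAAA")
  alns <- setNames(lapply(1:1345, mk), paste0("g", 1:1345))
  units <- concatenate_units(alns, 20, rng_seed = 2)
  sizes <- vapply(units, function(u) length(attr(u, "genes")), 1L)
  expect_equal(sort(unique(sizes)), c(67L, 68L))
  expect_equal(sum(sizes == 68L), 5L)
  expect_equal(sum(sizes == 67L), 15L)
  # disjoint and exhaustive partition of the gene set
  genes <- unlist(lapply(units, attr, "genes"))
  expect_equal(sort(genes), sort(names(alns)))

  units2 <- concatenate_units(alns, 20, rng_seed = 2)
  expect_identical(lapply(units, attr, "genes"), lapply(units2, attr, "genes"))

  one_each <- concatenate_units(alns[1:20], 20, rng_seed = 1)
  expect_true(all(vapply(one_each, function(u) length(attr(u, "genes")), 1L) == 1L))
  expect_error(concatenate_units(alns[1:10], 20), "fewer")
})
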