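test_that("best hits select by bitscore with deterministic tie-breaks", {
  h <- data.frame(query = c("a1", "a1"), subject = c("b1", "b2"),
                  bitscore = c(50, 40), evalue = c(1e-30, 1e-30))
  expect_equal(best_hits(h), c(a1 = "b1"))

  # the E-value cut-off removes queries whose only hit is weak
  h2 <- data.frame(query = "a1", subject = "b1", bitscore = 50, evalue = 1e-4)
  expect_equal(length(best_hits(h2, 1e-5)), 0L)

  # bitscore tie: lower evalue wins, then lexicographic subject
  h3 <- data.frame(query = c("a1", "a1"), subject = c("b2", "b1"),
                   bitscore = c(50, 50), evalue = c(1e-30, 1e-30))
  expect_equal(best_hits(h3), c(a1 = "b1"))
  h4 <- data.frame(query = c("a1", "a1"), subject = c("b2", "b1"),
                   bitscore = c(50, 50), evalue = c(1e-40, 1e-30))
  expect_equal(best_hits(h4), c(a1 = "b2"))
})

test_that("reciprocal pairs require mutual best hits", {
  expect_equal(reciprocal_pairs(c(a1 = "b1"), c(b1 = "a1")),
               data.frame(id_a = "a1", id_b = "b1"))
  expect_equal(nrow(reciprocal_pairs(c(a1 = "b1"), c(b1 = "a2"))), 0L)
  expect_equal(nrow(reciprocal_pairs(setNames(character(0), character(0)),
                                     c(b1 = "a1"))), 0L)
})

test_that("triplet classification matches the three-way acceptance diagram", {
  pab <- data.frame(id_a = "a1", id_b = "b1")
  pbc <- data.frame(id_a = "b1", id_b = "c1")
  pac <- data.frame(id_a = "a1", id_b = "c1")
  t1 <- classify_triplets(pab, pbc, pac)
  expect_equal(t1$status, "accepted_three_way")
  expect_equal(c(t1$id_a, t1$id_b, t1$id_c), c("a1", "b1", "c1"))

  t2 <- classify_triplets(pab, pbc, pac[0, ])
  expect_equal(t2$status, "two_pair_only")

  t3 <- classify_triplets(pab, pbc, data.frame(id_a = "a1", id_b = "c2"))
  expect_equal(unique(t3$status), "inconsistent_triangle")

  t4 <- classify_triplets(pab, pbc[0, ], pac[0, ])
  expect_equal(t4$status, "single_pair")
})

test_that("triplet classification is invariant under species relabeling", {
  set.seed(42)
  for (r in 1:10) {
    ab <- oracle_rbh(random_hit_table(8, 8, 25, "a", "b"),
                     random_hit_table(8, 8, 25, "b", "a"))
    bc <- oracle_rbh(random_hit_table(8, 8, 25, "b", "c"),
                     random_hit_table(8, 8, 25, "c", "b"))
    ac <- oracle_rbh(random_hit_table(8, 8, 25, "a", "c"),
                     random_hit_table(8, 8, 25, "c", "a"))
    t_abc <- classify_triplets(ab, bc, ac)
    # relabel (A,B,C) -> (C,A,B): pairs CA, AB, CB
    swap <- function(p) data.frame(id_a = p$id_b, id_b = p$id_a)
    t_cab <- classify_triplets(swap(ac), ab, swap(bc))
    expect_equal(sort(table(t_abc$status)), sort(table(t_cab$status)))
    acc1 <- t_abc[t_abc$status == "accepted_three_way", ]
    acc2 <- t_cab[t_cab$status == "accepted_three_way", ]
    expect_setequal(acc1$id_a, acc2$id_b)   # species A sits in slot b after relabel
  }
})

test_that("reciprocal pairs agree with the brute-force oracle on random tables", {
  set.seed(7)
  for (r in 1:25) {
    hab <- random_hit_table(12, 12, 40, "a", "b")
    hba <- random_hit_table(12, 12, 40, "b", "a")
    fast <- reciprocal_pairs(best_hits(hab), best_hits(hba))
    slow <- oracle_rbh(hab, hba)
    rownames(fast) <- rownames(slow) <- NULL
    expect_equal(fast, slow)
  }
})

test_that("no transcript appears in two accepted triplets", {
  set.seed(9)
  for (r in 1:5) {
    ab <- oracle_rbh(random_hit_table(15, 15, 60, "a", "b"),
                     random_hit_table(15, 15, 60, "b", "a"))
    bc <- oracle_rbh(random_hit_table(15, 15, 60, "b", "c"),
                     random_hit_table(15, 15, 60, "c", "b"))
    ac <- oracle_rbh(random_hit_table(15, 15, 60, "a", "c"),
                     random_hit_table(15, 15, 60, "c", "a"))
    acc <- classify_triplets(ab, bc, ac)
    acc <- acc[acc$status == "accepted_three_way", ]
    ids <- c(acc$id_a, acc$id_b, acc$id_c)
    expect_equal(anyDuplicated(ids), 0L)
  }
})

test_that("the k-mer scorer ranks identity highest and zero-overlap at zero", {
  set.seed(21)
  a <- transcript_set("A", c(x1 = random_codon_seq(60), x2 = random_codon_seq(60)))
  b <- transcript_set("B", c(y1 = a$sequences[["x1"]], y2 = random_codon_seq(60)))
  hits <- toy_similarity_scores(a, b, k = 12)
  best <- hits[hits$query == "x1", ]
  expect_equal(best$subject[which.max(best$bitscore)], "y1")
  expect_equal(max(best$bitscore), nchar(a$sequences[["x1"]]) - 12 + 1)

  c1 <- transcript_set("A", c(p = strrep("A", 40)))
  c2 <- transcript_set("B", c(q = strrep("C", 40)))
  expect_equal(nrow(toy_similarity_scores(c1, c2, k = 8)), 0L)
  expect_error(toy_similarity_scores(c1, c2, k = 3), "k must be")
  expect_error(toy_similarity_scores(c1, c2, k = 50), "shortest")
})

test_that("accepted triplets equal true orthologs on a clean simulated fixture", {
  p <- simulation_params(n_genes = 40L, codons_per_gene = 150L, rng_seed = 31L)
  sim <- simulate_triplet_transcriptomes(p)
  tr <- sim$transcripts
  bh <- function(x, y) best_hits(toy_similarity_scores(x, y), 1e-5)
  pab <- reciprocal_pairs(bh(tr[[1]], tr[[2]]), bh(tr[[2]], tr[[1]]))
  pbc <- reciprocal_pairs(bh(tr[[2]], tr[[3]]), bh(tr[[3]], tr[[2]]))
  pac <- reciprocal_pairs(bh(tr[[1]], tr[[3]]), bh(tr[[3]], tr[[1]]))
  tri <- classify_triplets(pab, pbc, pac, names(tr))
  acc <- tri[tri$status == "accepted_three_way", ]
  truth <- sim$truth$orthologs
  expect_equal(nrow(acc), nrow(truth))
  expect_setequal(paste(acc$id_a, acc$id_b, acc$id_c),
                  paste(truth$id_sp1, truth$id_sp2, truth$id_sp3))
})
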