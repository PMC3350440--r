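#!/usr/bin/env Rscript

# Step 2: three-way orthology by reciprocal best hits.
#
# All six directed similarity searches use the package's k-mer scorer
# (standing in for nucleotide BLAST on real data); best hits are taken
# by bitscore under the E-value cut-off, reciprocal pairs require
# mutual bests, and triplets are accepted only when the triangle of
# pairwise reciprocal best hits closes on the same three transcripts.
# Open or inconsistent triangles (the paralogy signature) are excluded.

suppressPackageStartupMessages(library(orthotrio))

cfg <- analysis_config()
sim <- readRDS("scratch/sim/sim.rds")
tr <- sim$transcripts

bh <- function(x, y) best_hits(toy_similarity_scores(x, y),
                               cfg$evalue_cutoff_orthology)
message("similarity search + best hits ...")
pairs_ab <- reciprocal_pairs(bh(tr[[1]], tr[[2]]), bh(tr[[2]], tr[[1]]))
pairs_bc <- reciprocal_pairs(bh(tr[[2]], tr[[3]]), bh(tr[[3]], tr[[2]]))
pairs_ac <- reciprocal_pairs(bh(tr[[1]], tr[[3]]), bh(tr[[3]], tr[[1]]))

triplets <- classify_triplets(pairs_ab, pairs_bc, pairs_ac, names(tr))
write_result_table(triplets, "scratch/sim/triplet_status.tsv", cfg)
saveRDS(triplets, "scratch/sim/triplets.rds")

counts <- table(triplets$status)
write_result_table(as.data.frame(counts), "results/02_triplet_counts.tsv", cfg)
print(counts)

acc <- triplets[triplets$status == "accepted_three_way", ]
truth <- sim$truth$orthologs
hit <- sum(paste(acc$id_a, acc$id_b, acc$id_c) %in%
           paste(truth$id_sp1, truth$id_sp2, truth$id_sp3))
message(sprintf("accepted triplets: %d; matching simulated truth: %d (%.1f%% of %d true orthologs)",
                nrow(acc), hit, 100 * hit / nrow(truth), nrow(truth)))
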