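Package: orthotrio
Title: Three-Way Transcriptome Orthology, Polymorphism and Molecular
    Evolution for a Species Trio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for comparative transcriptomics of three
    closely related species sequenced without a reference genome:
    reciprocal-best-hit ortholog triplet detection, statistically
    thresholded open-reading-frame extraction and frame-aware alignment
    curation, pileup-based SNP and indel mining with outgroup
    polarization and piA/piS estimation, branch-wise dN/dS on
    concatenated alignment units by Nei-Gojobori counting with
    Jukes-Cantor correction, background-corrected effective number of
    codons (Nc') and GC3 codon-usage statistics, and molecular-clock
    calibration with split-time estimation. Includes a codon-level
    simulator of three transcriptomes descending from a common ancestor
    on a star phylogeny, with known orthology, per-branch divergence and
    planted heterozygosity, so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
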