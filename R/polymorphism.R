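#' Call SNPs and indels from a pileup
#'
#' Applies the published mining filters: sites are considered only on
#' contigs strictly longer than `min_contig_len`, at positions more than
#' `edge_trim` bases from either contig edge, with depth inside
#' `[cov_min, cov_max]`. At a considered site the two most frequent
#' alleles (among A, C, G, T and gap) define the putative polymorphism;
#' the minor allele frequency, computed among the top two alleles, must
#' be strictly greater than `maf_min`. A site whose third allele exceeds
#' the sequencing-error allowance (1% of depth) is skipped, since a
#' single diploid individual carries at most two true alleles. A gap
#' among the top two alleles is counted as an indel event, not a SNP.
#'
#' @param pileup Pileup data.frame from [read_pileup()] or
#'   [simulate_pileups()].
#' @param contig_lengths Named integer vector of contig lengths; every
#'   pileup contig must be present.
#' @param config An [analysis_config()].
#' @return List with `calls` (data.frame: contig, position,
#'   major_allele, minor_allele, maf, depth), `n_indels`, and `surveyed`
#'   (data.frame of contig/position for every site that passed the
#'   contig, edge and coverage filters — the denominator for per-site
#'   polymorphism rates).
#' @export
call_variants <- function(pileup, contig_lengths, config = analysis_config()) {
  len <- contig_lengths[pileup$contig]
  if (anyNA(len))
    stop("contig(s) missing from length table: ",
         paste(unique(pileup$contig[is.na(len)])[1:1], collapse = ", "))
  eligible <- len > config$min_contig_len &
    pileup$position > config$edge_trim &
    pileup$position <= len - config$edge_trim &
    pileup$depth >= config$cov_min & pileup$depth <= config$cov_max
  surveyed <- pileup[eligible, c("contig", "position")]
  rownames(surveyed) <- NULL
  sub <- pileup[eligible, , drop = FALSE]
  empty <- data.frame(contig = character(), position = integer(),
                      major_allele = character(), minor_allele = character(),
                      maf = numeric(), depth = integer())
  if (nrow(sub) == 0)
    return(list(calls = empty, n_indels = 0L, surveyed = surveyed))

  alleles <- c("A", "C", "G", "T", "-")
  m <- as.matrix(sub[, c("A", "C", "G", "T", "gap")])
  n <- nrow(m)
  j1 <- max.col(m, ties.method = "first")
  c1 <- m[cbind(seq_len(n), j1)]
  m2 <- m; m2[cbind(seq_len(n), j1)] <- -1L
  j2 <- max.col(m2, ties.method = "first")
  c2 <- m2[cbind(seq_len(n), j2)]
  m3 <- m2; m3[cbind(seq_len(n), j2)] <- -1L
  c3 <- m3[cbind(seq_len(n), max.col(m3, ties.method = "first"))]

  maf <- ifelse(c1 + c2 > 0, c2 / (c1 + c2), 0)
  poly <- c2 > 0 & maf > config$maf_min & c3 <= 0.01 * sub$depth
  is_indel <- poly & (j1 == 5L | j2 == 5L)
  is_snp <- poly & !is_indel

  calls <- data.frame(contig = sub$contig[is_snp],
                      position = sub$position[is_snp],
                      major_allele = alleles[j1[is_snp]],
                      minor_allele = alleles[j2[is_snp]],
                      maf = maf[is_snp],
                      depth = sub$depth[is_snp])
  rownames(calls) <- NULL
  list(calls = calls, n_indels = sum(is_indel), surveyed = surveyed)
}

#' Polarize SNP calls with two outgroup bases
#'
#' The ancestral allele is the base shown by both other species at the
#' orthologous position, provided they agree and that base is one of the
#' two observed alleles; otherwise the call stays unpolarized. `NA`
#' outgroup bases (position not alignable) also yield unpolarized.
#'
#' @param calls Call data.frame from [call_variants()].
#' @param base_sp2,base_sp3 Character vectors of outgroup bases, one per
#'   call (NA allowed).
#' @return `calls` with columns `polarization`
#'   (ancestral_major/ancestral_minor/unpolarized), `ancestral_allele`
#'   and `derived_allele` (NA when unpolarized).
#' @export
polarize_calls <- function(calls, base_sp2, base_sp3) {
  n <- nrow(calls)
  stopifnot(length(base_sp2) == n, length(base_sp3) == n)
  b2 <- toupper(base_sp2); b3 <- toupper(base_sp3)
  agree <- !is.na(b2) & !is.na(b3) & b2 == b3
  anc_major <- agree & b2 == calls$major_allele
  anc_minor <- agree & b2 == calls$minor_allele
  calls$polarization <- ifelse(anc_major, "ancestral_major",
                        ifelse(anc_minor, "ancestral_minor", "unpolarized"))
  calls$ancestral_allele <- ifelse(anc_major, calls$major_allele,
                            ifelse(anc_minor, calls$minor_allele, NA))
  calls$derived_allele <- ifelse(anc_major, calls$minor_allele,
                          ifelse(anc_minor, calls$major_allele, NA))
  calls
}

#' Classify polarized SNPs as synonymous or nonsynonymous
#'
#' The derived allele is substituted into the ancestral codon (the codon
#' of the transcript's reading frame with the ancestral allele at the
#' SNP position). An amino-acid change is nonsynonymous, no change is
#' synonymous; positions outside the ORF are noncoding; unpolarized
#' calls, and codons containing `N`, are undetermined.
#'
#' @param calls Polarized call data.frame for one contig (from
#'   [polarize_calls()]).
#' @param orf The contig's [longest_orf()].
#' @param seq The contig's nucleotide sequence.
#' @param code Genetic code.
#' @return `calls` with an `effect` column.
#' @export
classify_effects <- function(calls, orf, seq, code = genetic_code()) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  L <- nchar(seq)
  s <- if (orf$strand == "+") seq else revcomp(seq)
  tab <- code$table
  n <- nrow(calls)
  effect <- character(n)
  for (i in seq_len(n)) {
    if (calls$polarization[i] == "unpolarized") { effect[i] <- "undetermined"; next }
    ## map the transcript position onto the ORF strand
    if (orf$strand == "+") {
      p0 <- calls$position[i] - 1L
      anc <- calls$ancestral_allele[i]; der <- calls$derived_allele[i]
    } else {
      p0 <- L - calls$position[i]
      anc <- chartr("ACGTN", "TGCAN", calls$ancestral_allele[i])
      der <- chartr("ACGTN", "TGCAN", calls$derived_allele[i])
    }
    if (p0 < orf$start || p0 >= orf$end) { effect[i] <- "noncoding"; next }
    off <- p0 - orf$start
    cod_start <- orf$start + 3L * (off %/% 3L)
    codon <- strsplit(substr(s, cod_start + 1L, cod_start + 3L), "")[[1]]
    codon[off %% 3L + 1L] <- anc
    anc_codon <- paste(codon, collapse = "")
    codon[off %% 3L + 1L] <- der
    der_codon <- paste(codon, collapse = "")
    if (grepl("N", anc_codon) || grepl("N", der_codon)) {
      effect[i] <- "undetermined"
    } else {
      effect[i] <- if (tab[[anc_codon]] == tab[[der_codon]])
        "synonymous" else "nonsynonymous"
    }
  }
  calls$effect <- effect
  calls
}

#' piA/piS from classified calls and site counts
#'
#' With a single diploid individual per species, heterozygous calls per
#' site are used as the polymorphism measure; the per-site constant
#' cancels in the ratio. `pi_a` is the number of nonsynonymous calls per
#' nonsynonymous site, `pi_s` the number of synonymous calls per
#' synonymous site.
#'
#' @param calls Classified call data.frame (with `effect`).
#' @param site_counts List with `n_sites` and `s_sites` covering the
#'   same surveyed coding positions (see [ng86_site_counts()] and
#'   [coding_site_counts()]).
#' @return List with `pi_a`, `pi_s`, `ratio` (NA with a flag when there
#'   are no synonymous calls), `n_nonsyn`, `n_syn`.
#' @export
pi_a_pi_s <- function(calls, site_counts) {
  if (!(site_counts$n_sites > 0 && site_counts$s_sites > 0))
    stop("site counts must be positive")
  n_nonsyn <- sum(calls$effect == "nonsynonymous")
  n_syn <- sum(calls$effect == "synonymous")
  pi_a <- n_nonsyn / site_counts$n_sites
  pi_s <- n_syn / site_counts$s_sites
  list(pi_a = pi_a, pi_s = pi_s,
       ratio = if (n_syn > 0) pi_a / pi_s else NA_real_,
       ratio_defined = n_syn > 0,
       n_nonsyn = n_nonsyn, n_syn = n_syn)
}

#' Site counts over the surveyed coding positions of one contig
#'
#' Restricts Nei-Gojobori site fractions to the coding positions of the
#' ORF that were actually surveyed (passed the caller's contig, edge and
#' coverage filters), so per-site polymorphism rates use a consistent
#' denominator.
#'
#' @param seq Contig sequence.
#' @param orf Its [longest_orf()].
#' @param positions 1-based surveyed transcript positions, or NULL for
#'   all coding positions.
#' @param code Genetic code.
#' @return List with `n_sites` and `s_sites`.
#' @export
coding_site_counts <- function(seq, orf, positions = NULL,
                               code = genetic_code()) {
  cds <- orf_sequence(seq, orf)
  sc <- ng86_site_counts(cds, code, per_position = TRUE)
  s_pos <- sc$s_pos
  L <- nchar(gsub("U", "T", toupper(seq), fixed = TRUE))
  if (is.null(positions)) {
    s <- sum(s_pos, na.rm = TRUE)
    n <- sum(!is.na(s_pos)) - s
    return(list(n_sites = n, s_sites = s))
  }
  p0 <- if (orf$strand == "+") positions - 1L else L - positions
  off <- p0 - orf$start + 1L                     # 1-based offset into CDS
  off <- off[off >= 1L & off <= length(s_pos)]
  s <- sum(s_pos[off], na.rm = TRUE)
  n <- sum(!is.na(s_pos[off])) - s
  list(n_sites = n, s_sites = s)
}
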