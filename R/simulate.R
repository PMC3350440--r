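#' Parameters for the three-species transcriptome simulator
#'
#' Defaults emulate the study conditions the package was built to
#' re-analyse: a three-taxon star phylogeny with per-branch synonymous
#' divergences 0.139 (outer species) and 0.073 (the two inner species),
#' dN/dS of about 0.1 on every branch, and diploid heterozygosity about
#' eight-fold depressed in the permanently inbreeding species (sp2)
#' relative to the two outcrossers. Per-species (synonymous,
#' nonsynonymous) heterozygosity targets are expressed as expected
#' heterozygous sites per synonymous/nonsynonymous site; the defaults
#' give within-species piA/piS of 0.10 (sp1), 0.32 (sp2, social) and
#' 0.18 (sp3).
#'
#' @param n_genes Number of ortholog genes.
#' @param codons_per_gene Integer, integer vector (recycled), or a
#'   function of n returning gene lengths in codons.
#' @param branch_dS Named per-branch expected synonymous substitutions
#'   per synonymous site.
#' @param omega Per-branch dN/dS; scalar or named like `branch_dS`.
#' @param codon_frequencies 61-vector over sense codons (default
#'   uniform); must sum to 1.
#' @param pi_per_species List per species of `c(syn = , nonsyn = )`
#'   heterozygosity targets in `[0, 0.1]`.
#' @param coverage_mean,coverage_size Negative-binomial read-depth law
#'   for simulated pileups (mean and size/dispersion).
#' @param error_rate Per-base sequencing error rate in pileups.
#' @param decoy_specific Species-specific (orphan) genes appended per
#'   species.
#' @param decoy_paralog Number of genes duplicated in one species and
#'   evolved an extra two-fold branch length, to exercise the paralogy
#'   rejection path of the orthology stage.
#' @param rng_seed Integer seed; all outputs are reproducible from it.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 200L,
                              codons_per_gene = 300L,
                              branch_dS = c(sp1 = 0.139, sp2 = 0.073,
                                            sp3 = 0.073),
                              omega = 0.1,
                              codon_frequencies = NULL,
                              pi_per_species = list(
                                sp1 = c(syn = 0.008,  nonsyn = 0.0008),
                                sp2 = c(syn = 0.001,  nonsyn = 0.00032),
                                sp3 = c(syn = 0.007,  nonsyn = 0.00126)),
                              coverage_mean = 50, coverage_size = 20,
                              error_rate = 0.002,
                              decoy_specific = 0L, decoy_paralog = 0L,
                              rng_seed = 1L) {
  if (length(omega) == 1) omega <- stats::setNames(rep(omega, 3), names(branch_dS))
  if (!setequal(names(omega), names(branch_dS)))
    stop("omega branch names must match branch_dS names")
  omega <- omega[names(branch_dS)]
  if (any(branch_dS < 0) || any(omega < 0)) stop("branch_dS and omega must be >= 0")
  tabs <- codon_tables(genetic_code())
  if (is.null(codon_frequencies)) {
    codon_frequencies <- rep(0, 64)
    codon_frequencies[!tabs$is_stop] <- 1 / sum(!tabs$is_stop)
  } else {
    if (length(codon_frequencies) == 61)
      codon_frequencies <- {
        f <- rep(0, 64); f[!tabs$is_stop] <- codon_frequencies; f
      }
    if (abs(sum(codon_frequencies) - 1) > 1e-9)
      stop("codon_frequencies must sum to 1")
    if (any(codon_frequencies[tabs$is_stop] != 0))
      stop("codon_frequencies must assign 0 to stop codons")
  }
  for (p in pi_per_species)
    if (any(p < 0 | p > 0.1)) stop("pi targets must lie in [0, 0.1]")
  structure(list(n_genes = as.integer(n_genes),
                 codons_per_gene = codons_per_gene,
                 branch_dS = branch_dS, omega = omega,
                 codon_frequencies = codon_frequencies,
                 pi_per_species = pi_per_species,
                 coverage_mean = coverage_mean,
                 coverage_size = coverage_size,
                 error_rate = error_rate,
                 decoy_specific = as.integer(decoy_specific),
                 decoy_paralog = as.integer(decoy_paralog),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_params")
}

## Evolve codon states down one branch: continuous-time model in which
## each single-nucleotide codon change fires at relative rate 1
## (synonymous) or omega (nonsynonymous); stop-generating changes are
## rejected (rate 0). The branch length is calibrated on the ancestral
## sequence so the expected synonymous flux per NG86 synonymous site
## equals dS.
.evolve_codons <- function(idx, dS, omega, tabs) {
  if (dS == 0) return(list(state = idx, n_syn = 0L, n_nonsyn = 0L))
  w <- matrix(0, 64, 9)
  w[tabs$nb_syn] <- 1
  w[!tabs$nb_syn & !tabs$nb_stop] <- omega
  w[tabs$is_stop, ] <- 0
  lam <- rowSums(w)
  Pc <- w / ifelse(lam > 0, lam, 1)
  Pc <- t(apply(Pc, 1, cumsum))

  syn_n <- rowSums(tabs$nb_syn)
  S_anc <- sum(tabs$site_s[idx])
  flux <- sum(syn_n[idx])
  if (flux == 0) stop("ancestral sequence admits no synonymous change")
  T_branch <- dS * S_anc / flux

  state <- idx
  rem <- rep(T_branch, length(idx))
  act <- seq_along(idx)
  n_syn <- n_nonsyn <- 0L
  while (length(act)) {
    lam_a <- lam[state[act]]
    live <- lam_a > 0
    act <- act[live]
    if (!length(act)) break
    t <- stats::rexp(length(act), rate = lam_a[live])
    jump <- t < rem[act]
    act <- act[jump]
    if (!length(act)) break
    rem[act] <- rem[act] - t[jump]
    u <- stats::runif(length(act))
    k <- rowSums(Pc[state[act], , drop = FALSE] < u) + 1L
    sel <- cbind(state[act], k)
    syn_step <- tabs$nb_syn[sel]
    n_syn <- n_syn + sum(syn_step)
    n_nonsyn <- n_nonsyn + sum(!syn_step)
    state[act] <- tabs$nb_idx[sel]
  }
  list(state = state, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' Simulate three transcriptomes on a star phylogeny
#'
#' Each gene is drawn as an ancestral codon sequence from the codon
#' frequencies and evolved independently down the three star branches
#' under a continuous-time codon model: single-nucleotide codon changes
#' fire at relative rate 1 when synonymous and `omega` when
#' nonsynonymous, stop-generating changes are rejected, and the branch
#' length is calibrated so the expected number of synonymous changes per
#' synonymous site equals `branch_dS`. Optional decoys (species-specific
#' orphan genes; a duplicated, extra-diverged paralog copy) are
#' appended.
#'
#' @param params A [simulation_params()].
#' @return List with `transcripts` (list of three [transcript_set]s) and
#'   `truth`: `orthologs` (gene to per-species transcript id table),
#'   `ancestors` (named ancestral sequences), `events` (realized
#'   per-branch synonymous/nonsynonymous substitution counts) and
#'   `params`.
#' @export
simulate_triplet_transcriptomes <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  tabs <- codon_tables(genetic_code())
  with_preserved_rng(params$rng_seed, {
    n <- params$n_genes
    lens <- params$codons_per_gene
    if (is.function(lens)) lens <- lens(n)
    lens <- as.integer(rep_len(lens, n))

    anc_all <- sample.int(64, sum(lens), replace = TRUE,
                          prob = params$codon_frequencies)
    gene_of <- rep(seq_len(n), lens)
    species <- names(params$branch_dS)

    evolved <- list()
    events <- data.frame(branch = species, n_syn = 0L, n_nonsyn = 0L)
    for (i in seq_along(species)) {
      ev <- .evolve_codons(anc_all, params$branch_dS[[i]],
                           params$omega[[i]], tabs)
      evolved[[species[i]]] <- ev$state
      events$n_syn[i] <- ev$n_syn
      events$n_nonsyn[i] <- ev$n_nonsyn
    }

    gene_ids <- sprintf("g%04d", seq_len(n))
    cstr <- .codon_strings()
    seq_of <- function(state) {
      vapply(split(cstr[state], gene_of), paste, "", collapse = "")
    }
    sets <- list()
    ortho <- data.frame(gene = gene_ids)
    for (sp in species) {
      seqs <- seq_of(evolved[[sp]])
      ids <- paste0(sp, "_", gene_ids)
      names(seqs) <- ids
      ortho[[paste0("id_", sp)]] <- ids

      if (params$decoy_specific > 0) {
        dlens <- rep_len(lens, params$decoy_specific)
        didx <- sample.int(64, sum(dlens), replace = TRUE,
                           prob = params$codon_frequencies)
        dseqs <- vapply(split(cstr[didx],
                              rep(seq_len(params$decoy_specific), dlens)),
                        paste, "", collapse = "")
        names(dseqs) <- paste0(sp, "_x", sprintf("%03d", seq_len(params$decoy_specific)))
        seqs <- c(seqs, dseqs)
      }
      sets[[sp]] <- seqs
    }

    ## paralog decoys: duplicate gene copies in one species, evolved an
    ## extra 2x branch length from that species' sequence
    if (params$decoy_paralog > 0) {
      pick <- sample.int(n, min(params$decoy_paralog, n))
      for (j in seq_along(pick)) {
        sp <- species[(j - 1L) %% 3L + 1L]
        g <- pick[j]
        src <- evolved[[sp]][gene_of == g]
        ev <- .evolve_codons(src, 2 * params$branch_dS[[sp]],
                             params$omega[[sp]], tabs)
        pseq <- paste(cstr[ev$state], collapse = "")
        names(pseq) <- paste0(sp, "_p", sprintf("%03d", j))
        sets[[sp]] <- c(sets[[sp]], pseq)
      }
    }

    transcripts <- lapply(species, function(sp) transcript_set(sp, sets[[sp]]))
    names(transcripts) <- species
    ancestors <- vapply(split(cstr[anc_all], gene_of), paste, "", collapse = "")
    names(ancestors) <- gene_ids
    list(transcripts = transcripts,
         truth = list(orthologs = ortho, ancestors = ancestors,
                      events = events, params = params))
  })
}

#' Simulate diploid base-count pileups with planted heterozygosity
#'
#' Treats each transcript as a fully coding contig (frame 0, as produced
#' by [simulate_triplet_transcriptomes()]) and plants heterozygous sites
#' at the requested synonymous and nonsynonymous per-site rates:
#' `round(pi * sites)` positions are drawn among the eligible positions
#' (more than `edge_trim` bases from each contig edge) that admit a
#' change of that effect class, and a random alternative allele of that
#' class becomes the second allele. Read depth per site follows a
#' negative binomial; at heterozygous sites the minor-allele read count
#' is Binomial(depth, 1/2) (`allele_balance = "binomial"`) or a
#' deterministic half split (`"exact"`, for error-free recovery
#' fixtures); sequencing errors are sprinkled per base at `error_rate`.
#'
#' @param transcripts A [transcript_set].
#' @param pi_syn,pi_nonsyn Planted heterozygosity per synonymous /
#'   nonsynonymous site.
#' @param coverage_mean,coverage_size Negative-binomial depth law.
#' @param error_rate Per-base error rate (0 for error-free pileups).
#' @param allele_balance `"binomial"` or `"exact"`.
#' @param edge_trim Plant only inside this margin (matches the caller's
#'   edge exclusion).
#' @param min_contig_len Plant only on contigs strictly longer than this
#'   (matches the caller's contig filter).
#' @param rng_seed Integer seed.
#' @return List with `pileup` (data.frame in the package's pileup
#'   dialect) and `truth` (data.frame of planted SNPs: contig, position,
#'   ancestral, derived, effect).
#' @export
simulate_pileups <- function(transcripts, pi_syn, pi_nonsyn,
                             coverage_mean = 50, coverage_size = 20,
                             error_rate = 0.002,
                             allele_balance = c("binomial", "exact"),
                             edge_trim = 10L, min_contig_len = 100L,
                             rng_seed = 1L) {
  allele_balance <- match.arg(allele_balance)
  tabs <- codon_tables(genetic_code())
  seqs <- transcripts$sequences
  with_preserved_rng(rng_seed, {
    ## per-position candidate table across all transcripts
    contig <- rep(names(seqs), nchar(seqs))
    pos <- unlist(lapply(nchar(seqs), seq_len), use.names = FALSE)
    base <- unlist(strsplit(unname(seqs), "", fixed = TRUE), use.names = FALSE)
    L <- rep(nchar(seqs), nchar(seqs))
    per_seq <- lapply(unname(seqs), function(s) {
      nl <- nchar(s)
      ci <- codon_indices(s)
      cod <- rep(ci, each = 3L)
      length(cod) <- nl                      # NA-pad a trailing partial codon
      list(cod = cod, cpos = rep_len(1:3, nl))
    })
    cod <- unlist(lapply(per_seq, `[[`, "cod"), use.names = FALSE)
    cpos <- unlist(lapply(per_seq, `[[`, "cpos"), use.names = FALSE)
    in_codon <- !is.na(cod) & !tabs$is_stop[ifelse(is.na(cod), 1L, cod)]
    eligible <- in_codon & pos > edge_trim & pos <= L - edge_trim &
      L > min_contig_len

    ## per (codon, codon position): synonymous / nonsynonymous-sense
    ## alternative counts
    nb_by_pos <- function(type) {
      m <- matrix(0L, 64, 3)
      for (p in 1:3) {
        sel <- tabs$nb_pos == p
        cnt <- if (type == "syn") rowSums(tabs$nb_syn & sel)
               else rowSums(!tabs$nb_syn & !tabs$nb_stop & sel)
        m[, p] <- cnt
      }
      m[tabs$is_stop, ] <- 0L
      m
    }
    syn_cnt <- nb_by_pos("syn")
    ns_cnt <- nb_by_pos("nonsyn")

    cod_safe <- ifelse(in_codon, cod, 1L)
    s_per_pos <- tabs$site_pos[cbind(cod_safe, cpos)]
    s_sites <- sum(s_per_pos[eligible])
    n_sites <- sum(eligible) - s_sites

    can_syn <- eligible & syn_cnt[cbind(cod_safe, cpos)] > 0
    can_ns <- eligible & ns_cnt[cbind(cod_safe, cpos)] > 0

    n_syn_t <- round(pi_syn * s_sites)
    n_ns_t <- round(pi_nonsyn * n_sites)
    if (n_syn_t > sum(can_syn) || n_ns_t > sum(can_ns))
      stop("pi target implies more heterozygous sites than available")

    syn_pick <- sample(which(can_syn), n_syn_t)
    ns_pool <- setdiff(which(can_ns), syn_pick)
    ns_pick <- sample(ns_pool, n_ns_t)

    pick_alt <- function(i, want_syn) {
      sel <- tabs$nb_pos[cod[i], ] == cpos[i] &
        (if (want_syn) tabs$nb_syn[cod[i], ]
         else !tabs$nb_syn[cod[i], ] & !tabs$nb_stop[cod[i], ])
      nb <- tabs$nb_idx[cod[i], sel]
      j <- if (length(nb) > 1) sample(nb, 1) else nb
      substr(tabs$codons[j], cpos[i], cpos[i])
    }
    alt <- character(length(pos))
    for (i in syn_pick) alt[i] <- pick_alt(i, TRUE)
    for (i in ns_pick) alt[i] <- pick_alt(i, FALSE)
    het <- logical(length(pos))
    het[c(syn_pick, ns_pick)] <- TRUE

    depth <- stats::rnbinom(length(pos), size = coverage_size,
                            mu = coverage_mean)
    minor <- integer(length(pos))
    minor[het] <- if (allele_balance == "binomial")
      stats::rbinom(sum(het), depth[het], 0.5) else depth[het] %/% 2L

    counts <- matrix(0L, length(pos), 5,
                     dimnames = list(NULL, c("A", "C", "G", "T", "gap")))
    bi <- match(base, .BASES)
    counts[cbind(seq_along(pos), bi)] <- depth - minor
    hi <- which(het)
    counts[cbind(hi, match(alt[hi], .BASES))] <-
      counts[cbind(hi, match(alt[hi], .BASES))] + minor[hi]

    if (error_rate > 0) {
      ne <- stats::rbinom(length(pos), depth, error_rate)
      ei <- which(ne > 0)
      for (i in ei) {
        tgt <- sample(setdiff(1:4, bi[i]), 1)
        take <- min(ne[i], counts[i, bi[i]])
        counts[i, bi[i]] <- counts[i, bi[i]] - take
        counts[i, tgt] <- counts[i, tgt] + take
      }
    }

    pileup <- data.frame(contig = contig, position = pos, ref = base,
                         depth = as.integer(rowSums(counts)),
                         A = counts[, 1], C = counts[, 2], G = counts[, 3],
                         T = counts[, 4], gap = counts[, 5])
    planted <- sort(c(syn_pick, ns_pick))
    truth <- data.frame(contig = contig[planted], position = pos[planted],
                        ancestral = base[planted], derived = alt[planted],
                        effect = ifelse(planted %in% syn_pick,
                                        "synonymous", "nonsynonymous"))
    rownames(truth) <- NULL
    list(pileup = pileup, truth = truth,
         site_totals = list(n_sites = n_sites, s_sites = s_sites))
  })
}

#' Write a self-contained simulated fixture bundle
#'
#' Presets: `"tiny"` (a dozen genes; completes in seconds) and
#' `"paper_scale"` (1,345 ortholog genes with codon lengths log-normally
#' distributed around a median of 171 codons, truncated to 63-1,092).
#' Writes per-species FASTA, pairwise toy hit tables, pileups, and truth
#' tables; byte-identical for a given seed.
#'
#' @param preset `"tiny"` or `"paper_scale"`.
#' @param outdir Output directory (created).
#' @param rng_seed Integer seed.
#' @return Invisibly, the list of written paths.
#' @export
make_fixture_bundle <- function(preset = c("tiny", "paper_scale"),
                                outdir, rng_seed = 1L) {
  preset <- match.arg(preset)
  params <- switch(preset,
    tiny = simulation_params(n_genes = 12L,
                             codons_per_gene = function(n)
                               sample(70:120, n, replace = TRUE),
                             decoy_specific = 2L, decoy_paralog = 1L,
                             rng_seed = rng_seed),
    paper_scale = simulation_params(
      n_genes = 1345L,
      codons_per_gene = function(n)
        pmin(pmax(round(stats::rlnorm(n, log(171), 0.55)), 63L), 1092L),
      decoy_specific = 100L, decoy_paralog = 20L,
      rng_seed = rng_seed))
  ## the seeded length-sampling functions above run inside the
  ## simulator's preserved-RNG block, so the bundle is reproducible
  sim <- simulate_triplet_transcriptomes(params)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  species <- names(sim$transcripts)
  for (sp in species)
    paths[[paste0("fasta_", sp)]] <-
      write_fasta(sim$transcripts[[sp]], file.path(outdir, paste0(sp, ".fasta")))
  combos <- utils::combn(species, 2)
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    hits <- toy_similarity_scores(sim$transcripts[[a]], sim$transcripts[[b]])
    paths[[paste0("hits_", a, "_", b)]] <-
      write_hits(hits, file.path(outdir, sprintf("hits_%s_%s.tsv", a, b)))
    rev <- toy_similarity_scores(sim$transcripts[[b]], sim$transcripts[[a]])
    paths[[paste0("hits_", b, "_", a)]] <-
      write_hits(rev, file.path(outdir, sprintf("hits_%s_%s.tsv", b, a)))
  }
  for (i in seq_along(species)) {
    sp <- species[i]
    pi_t <- params$pi_per_species[[sp]]
    pu <- simulate_pileups(sim$transcripts[[sp]], pi_t[["syn"]],
                           pi_t[["nonsyn"]],
                           coverage_mean = params$coverage_mean,
                           coverage_size = params$coverage_size,
                           error_rate = params$error_rate,
                           rng_seed = params$rng_seed + i)
    paths[[paste0("pileup_", sp)]] <-
      write_pileup(pu$pileup, file.path(outdir, paste0(sp, ".pileup.tsv")))
    paths[[paste0("snp_truth_", sp)]] <-
      write_result_table(pu$truth, file.path(outdir, paste0(sp, ".snp_truth.tsv")))
  }
  paths$orthologs <- write_result_table(
    sim$truth$orthologs, file.path(outdir, "ortholog_truth.tsv"))
  invisible(paths)
}
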