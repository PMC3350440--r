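#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end — simulate (optional), orthology,
#' ORF detection, alignment curation and length filtering, concatenation
#' into units, SNP mining with polarization and piA/piS, branch-wise
#' dN/dS with unit confidence limits, codon usage, and clock dating —
#' and writes result tables plus a JSON manifest of every threshold and
#' count to `out_dir`. The pipeline is a pure function of (inputs,
#' config, seed): rerunning with the same arguments reproduces the
#' manifest counts exactly.
#'
#' Without external inputs the pipeline runs on a simulated fixture
#' (`simulate = "tiny"` or `"paper_scale"`). Alternatively, `inputs`
#' may name per-species FASTA files and pairwise hit tables produced by
#' an external similarity search; ortholog transcripts are then compared
#' where their ORFs align without indels (external aligner output is
#' accepted through the lower-level functions, not the one-shot
#' pipeline).
#'
#' @param config An [analysis_config()] (or path to a config file, see
#'   [validate_config()]).
#' @param out_dir Output directory.
#' @param simulate `"tiny"`, `"paper_scale"`, or `NULL` when `inputs`
#'   are given.
#' @param inputs Optional list with `fasta` (named character vector of
#'   three FASTA paths) and optionally `pileups` (named pileup TSV
#'   paths).
#' @param seed Integer seed overriding `config$rng_seed`.
#' @param calib_total_ds,calib_time_years Clock calibration (defaults:
#'   total synonymous divergence 2.64 to an outgroup tarantula lineage
#'   over a 245 My split).
#' @param direct_rate A second, directly measured per-year rate used for
#'   alternative dating (default 8.4e-9, a Drosophila mutation-
#'   accumulation estimate).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = analysis_config(), out_dir,
                         simulate = "tiny", inputs = NULL, seed = NULL,
                         calib_total_ds = 2.64, calib_time_years = 245e6,
                         direct_rate = 8.4e-9) {
  if (is.character(config)) config <- validate_config(config)
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %s", format(Sys.time() - t0),
                                          name))
  manifest <- list(config = unclass(config), stages = list())

  ## ---- stage: inputs / simulation -------------------------------------
  truth <- NULL
  pileups <- NULL
  if (!is.null(inputs)) {
    stage("load inputs")
    if (is.null(inputs$fasta) || length(inputs$fasta) != 3)
      stop("stage inputs: need three per-species FASTA paths")
    transcripts <- lapply(inputs$fasta, read_transcripts)
    if (!is.null(names(inputs$fasta)))
      for (i in seq_along(transcripts))
        transcripts[[i]]$species_id <- names(inputs$fasta)[i]
    names(transcripts) <- vapply(transcripts, `[[`, "", "species_id")
    if (!is.null(inputs$pileups))
      pileups <- lapply(inputs$pileups, read_pileup)
  } else {
    if (is.null(simulate)) stop("stage inputs: no inputs and no simulate preset")
    stage(paste0("simulate (", simulate, ")"))
    params <- switch(simulate,
      tiny = simulation_params(n_genes = 12L,
                               codons_per_gene = function(n)
                                 sample(70:120, n, replace = TRUE),
                               decoy_specific = 2L, decoy_paralog = 1L,
                               rng_seed = config$rng_seed),
      paper_scale = simulation_params(
        n_genes = 1345L,
        codons_per_gene = function(n)
          pmin(pmax(round(stats::rlnorm(n, log(171), 0.55)), 63L), 1092L),
        decoy_specific = 100L, decoy_paralog = 20L,
        rng_seed = config$rng_seed),
      stop("unknown preset: ", simulate))
    sim <- simulate_triplet_transcriptomes(params)
    transcripts <- sim$transcripts
    truth <- sim$truth
    pu <- lapply(seq_along(transcripts), function(i) {
      sp <- names(transcripts)[i]
      pi_t <- params$pi_per_species[[sp]]
      simulate_pileups(transcripts[[sp]], pi_t[["syn"]], pi_t[["nonsyn"]],
                       coverage_mean = params$coverage_mean,
                       coverage_size = params$coverage_size,
                       error_rate = params$error_rate,
                       edge_trim = config$edge_trim,
                       min_contig_len = config$min_contig_len,
                       rng_seed = config$rng_seed + i)
    })
    pileups <- lapply(pu, `[[`, "pileup")
    names(pileups) <- names(transcripts)
  }
  species <- names(transcripts)
  manifest$stages$inputs <- list(
    species = species,
    n_transcripts = vapply(transcripts, function(t) length(t$sequences), 1L))

  ## ---- stage: orthology ----------------------------------------------
  stage("orthology")
  bh <- list()
  for (k in list(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1))) {
    hits <- toy_similarity_scores(transcripts[[k[1]]], transcripts[[k[2]]])
    bh[[paste(k, collapse = "")]] <-
      best_hits(hits, config$evalue_cutoff_orthology)
  }
  pairs_ab <- reciprocal_pairs(bh[["12"]], bh[["21"]])
  pairs_bc <- reciprocal_pairs(bh[["23"]], bh[["32"]])
  pairs_ac <- reciprocal_pairs(bh[["13"]], bh[["31"]])
  triplets <- classify_triplets(pairs_ab, pairs_bc, pairs_ac, species)
  write_result_table(triplets, file.path(out_dir, "triplets.tsv"), config)
  accepted <- triplets[triplets$status == "accepted_three_way", , drop = FALSE]
  manifest$stages$orthology <- list(
    status_counts = as.list(table(triplets$status)),
    accepted = nrow(accepted))
  if (nrow(accepted) == 0) stop("stage orthology: no accepted triplets")

  ## ---- stage: ORF + curation + units ----------------------------------
  stage("orf/curate/concatenate")
  min_codons <- min_orf_codons(config$orf_alpha)
  alignments <- list()
  orfs <- list()
  for (r in seq_len(nrow(accepted))) {
    ids <- c(accepted$id_a[r], accepted$id_b[r], accepted$id_c[r])
    seqs <- vapply(seq_along(species), function(i)
      transcripts[[i]]$sequences[[ids[i]]], "")
    o <- lapply(seqs, longest_orf)
    if (length(unique(vapply(o, `[[`, 1L, "codon_length"))) != 1)
      next                                  # ORFs disagree: needs an aligner
    rows <- stats::setNames(mapply(orf_sequence, seqs, o), species)
    aln <- curate_alignment(rows)
    if (nchar(aln[[1]]) == 0) next
    alignments[[ids[1]]] <- aln
    orfs[[ids[1]]] <- o[[1]]
    names(orfs)[length(orfs)] <- ids[1]
  }
  fl <- filter_short(alignments, 3L * min_codons)
  kept <- fl$kept
  if (length(kept) < 2) stop("stage orf: fewer than 2 surviving alignments")
  n_units <- min(config$n_units, length(kept))
  if (n_units < config$n_units)
    message("reducing units to the ", n_units, " surviving alignments")
  manifest$stages$orf <- list(
    min_orf_codons = min_codons, min_bp = 3L * min_codons,
    aligned = length(alignments), discarded_short = nrow(fl$log),
    kept = length(kept), n_units = n_units)
  units <- concatenate_units(kept, n_units, config$rng_seed)

  ## ---- stage: polymorphism --------------------------------------------
  if (!is.null(pileups)) {
    stage("polymorphism")
    poly <- list()
    for (i in seq_along(species)) {
      sp <- species[i]
      pup <- pileups[[sp]]
      lens <- stats::setNames(nchar(transcripts[[i]]$sequences),
                              names(transcripts[[i]]$sequences))
      cv <- call_variants(pup, lens, config)
      calls <- cv$calls
      ## polarize against the two other species at the same coordinate
      ## (star-tree ortholog transcripts share coordinates when their
      ## ORFs align without indels)
      others <- setdiff(seq_along(species), i)
      id_cols <- c("id_a", "id_b", "id_c")
      id_col <- id_cols[i]
      og <- lapply(others, function(j) {
        map <- stats::setNames(
          transcripts[[j]]$sequences[accepted[[id_cols[j]]]],
          accepted[[id_col]])
        ifelse(calls$contig %in% names(map),
               substr(map[calls$contig], calls$position, calls$position),
               NA_character_)
      })
      calls <- polarize_calls(calls, og[[1]], og[[2]])
      calls$effect <- "undetermined"
      sc_n <- sc_s <- 0
      for (ct in intersect(unique(c(calls$contig, cv$surveyed$contig)),
                           accepted[[id_col]])) {
        seq_ct <- transcripts[[i]]$sequences[[ct]]
        orf_ct <- longest_orf(seq_ct)
        sel <- calls$contig == ct
        if (any(sel))
          calls[sel, ] <- classify_effects(calls[sel, , drop = FALSE],
                                           orf_ct, seq_ct)
        sv <- cv$surveyed$position[cv$surveyed$contig == ct]
        sc <- coding_site_counts(seq_ct, orf_ct, sv)
        sc_n <- sc_n + sc$n_sites
        sc_s <- sc_s + sc$s_sites
      }
      pis <- if (sc_n > 0 && sc_s > 0)
        pi_a_pi_s(calls, list(n_sites = sc_n, s_sites = sc_s))
      else list(pi_a = NA, pi_s = NA, ratio = NA, n_nonsyn = 0, n_syn = 0)
      write_result_table(calls, file.path(out_dir, paste0(sp, ".snps.tsv")),
                         config)
      write_snp_vcf(calls, file.path(out_dir, paste0(sp, ".snps.vcf")), config)
      poly[[sp]] <- list(n_snps = nrow(calls), n_indels = cv$n_indels,
                         surveyed_sites = nrow(cv$surveyed),
                         n_syn = pis$n_syn, n_nonsyn = pis$n_nonsyn,
                         pi_a = pis$pi_a, pi_s = pis$pi_s,
                         pi_a_pi_s = pis$ratio)
    }
    manifest$stages$polymorphism <- poly
  }

  ## ---- stage: divergence + clock --------------------------------------
  stage("divergence/clock")
  est <- branch_estimates(units)
  write_result_table(est, file.path(out_dir, "branches.tsv"), config)
  pooled <- vapply(species, function(r)
    paste(vapply(units, `[[`, "", r), collapse = ""), "")
  pvar <- c(sp12 = pairwise_variable_sites(pooled[1], pooled[2]),
            sp13 = pairwise_variable_sites(pooled[1], pooled[3]),
            sp23 = pairwise_variable_sites(pooled[2], pooled[3]))
  calib <- calibrate_rate(calib_total_ds, calib_time_years)
  ds <- stats::setNames(est$ds, est$branch)
  times_calib <- clock_split_times(ds, calib)
  times_direct <- clock_split_times(ds, direct_rate)
  manifest$stages$divergence <- list(
    branches = stats::setNames(
      lapply(seq_len(nrow(est)), function(b)
        list(dn = est$dn[b], ds = est$ds[b], omega = est$omega[b],
             omega_ci = c(est$omega_lo[b], est$omega_hi[b]))),
      est$branch),
    pairwise_variable_sites = as.list(pvar))
  manifest$stages$clock <- list(
    calibrated_rate = calib$rate_per_year,
    t_inner_my_calibrated = times_calib$t_inner_years / 1e6,
    t_outer_my_calibrated = times_calib$t_outer_years / 1e6,
    direct_rate = direct_rate,
    t_inner_my_direct = times_direct$t_inner_years / 1e6,
    t_outer_my_direct = times_direct$t_outer_years / 1e6)

  ## ---- stage: codon usage ---------------------------------------------
  stage("codon usage")
  usage <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    rows <- vapply(units, `[[`, "", sp)
    unit_tabs <- lapply(rows, codon_usage_table)
    nc_stat <- function(u) effective_codons_corrected(combine_usage_tables(u))
    ci <- bootstrap_ci(nc_stat, unit_tabs, n_boot = 200L,
                       seed = config$rng_seed)
    usage[[sp]] <- list(
      gc = gc_content(paste(gsub("-", "", rows), collapse = "")),
      gc3 = gc3(paste(gsub("-", "", rows), collapse = "")),
      nc_prime = ci$point, nc_ci = c(ci$lo, ci$hi))
  }
  manifest$stages$codon_usage <- usage

  manifest$seed <- config$rng_seed
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
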