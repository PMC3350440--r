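#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' For each codon, each of the three positions contributes a synonymous
#' site fraction equal to the share of its possible single-base changes
#' (stop-creating changes excluded from the possible set) that preserve
#' the amino acid; the nonsynonymous fraction is the complement, so each
#' counted codon contributes exactly three sites. Codons containing `N`
#' (or gaps) are excluded from counting.
#'
#' @param coding_seq In-frame nucleotide string (length divisible by 3,
#'   no internal stop codon).
#' @param code Genetic code.
#' @param per_position If `TRUE`, also return the per-nucleotide-position
#'   synonymous site fractions (NA at excluded codons), which lets
#'   callers restrict site totals to a surveyed subset of positions.
#' @return List with `n_sites`, `s_sites`, `codons` (number counted) and,
#'   when requested, `s_pos` (numeric vector, one entry per nucleotide).
#' @examples
#' ng86_site_counts("ATG")$n_sites   # 3: every change to ATG is nonsynonymous
#' ng86_site_counts("TTT")$s_sites   # 1/3: only TTT->TTC is synonymous
#' @export
ng86_site_counts <- function(coding_seq, code = genetic_code(),
                             per_position = FALSE) {
  if (nchar(coding_seq) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3")
  tabs <- codon_tables(code)
  idx <- codon_indices(gsub("-", "N", toupper(coding_seq), fixed = TRUE))
  if (any(tabs$is_stop[idx[!is.na(idx)]]))
    stop("internal stop codon in coding sequence")
  valid <- !is.na(idx)
  s <- sum(tabs$site_s[idx[valid]])
  out <- list(n_sites = 3 * sum(valid) - s, s_sites = s,
              codons = sum(valid))
  if (per_position) {
    sp <- matrix(NA_real_, nrow = 3, ncol = length(idx))
    sp[, valid] <- t(tabs$site_pos[idx[valid], , drop = FALSE])
    out$s_pos <- as.vector(sp)
  }
  out
}

## Jukes-Cantor correction for multiple hits; NA (flagged) when p >= 3/4.
#' @rdname ng86_pairwise
#' @param p Proportion of observed differences per site.
#' @export
jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise dN and dS by Nei-Gojobori (1986) counting
#'
#' Site counts are averaged over the two sequences; differences per
#' codon are averaged over the minimal mutational pathways between the
#' two codons, with equal weights, skipping pathways through stop codons
#' (all pathways are used in the degenerate case where every pathway
#' crosses a stop). Proportions are corrected for multiple hits with the
#' Jukes-Cantor formula d = -(3/4) log(1 - 4p/3); p >= 3/4 yields `NA`.
#' Codon columns containing a gap or `N` in either sequence are masked.
#'
#' @param a,b In-frame gapped or ungapped nucleotide strings of equal
#'   codon length.
#' @param code Genetic code.
#' @return List with `dn`, `ds`, `pn`, `ps`, `Nd`, `Sd`, `N`, `S`,
#'   `codons` (codon columns compared) and `omega` (`dn/ds`, NA when
#'   `ds` is 0 or undefined).
#' @export
ng86_pairwise <- function(a, b, code = genetic_code()) {
  tabs <- codon_tables(code)
  ia <- codon_indices(gsub("-", "N", toupper(a), fixed = TRUE))
  ib <- codon_indices(gsub("-", "N", toupper(b), fixed = TRUE))
  if (length(ia) != length(ib)) stop("sequences differ in codon length")
  ok <- !is.na(ia) & !is.na(ib) & !tabs$is_stop[ia] & !tabs$is_stop[ib]
  ## replace NA flags produced by is_stop[NA]
  ok[is.na(ok)] <- FALSE
  ia <- ia[ok]; ib <- ib[ok]
  if (length(ia) == 0) stop("no comparable codons")
  N <- (sum(3 - tabs$site_s[ia]) + sum(3 - tabs$site_s[ib])) / 2
  S <- (sum(tabs$site_s[ia]) + sum(tabs$site_s[ib])) / 2
  Nd <- sum(tabs$ND[cbind(ia, ib)])
  Sd <- sum(tabs$SD[cbind(ia, ib)])
  pn <- Nd / N
  ps <- Sd / S
  dn <- jc_correct(pn)
  ds <- jc_correct(ps)
  omega <- if (!is.na(ds) && ds > 0) dn / ds else NA_real_
  list(dn = dn, ds = ds, pn = pn, ps = ps, Nd = Nd, Sd = Sd,
       N = N, S = S, codons = length(ia), omega = omega)
}

#' Per-branch dN and dS on a three-taxon star tree by parsimony counting
#'
#' At each codon column where exactly one species deviates from the
#' other two, the shared state is taken as the internal-node codon and
#' the differences are assigned to the deviating branch, classified
#' synonymous/nonsynonymous by pathway-averaged Nei-Gojobori counting.
#' Columns where all three species differ (no unambiguous assignment)
#' are skipped and their fraction reported; columns with gaps or `N` are
#' masked. Per-branch proportions are normalized by the site counts of
#' the inferred ancestral sequence and Jukes-Cantor corrected.
#'
#' @param aln Named character vector of three equal-length in-frame rows.
#' @param code Genetic code.
#' @return Data.frame with one row per species/branch: `Nd`, `Sd`, `N`,
#'   `S`, `pn`, `ps`, `dn`, `ds`, `omega`; the fraction of skipped
#'   (three-state) codons among usable columns is in
#'   `attr(, "skipped_fraction")` and the ancestral codon count in
#'   `attr(, "ancestral_codons")`. A warning is issued when more than 5%
#'   of usable codons are skipped.
#' @export
branch_counts_3taxon <- function(aln, code = genetic_code()) {
  stopifnot(length(aln) == 3)
  sp <- names(aln)
  if (is.null(sp)) sp <- paste0("sp", 1:3)
  tabs <- codon_tables(code)
  idx <- lapply(aln, function(s)
    codon_indices(gsub("-", "N", toupper(s), fixed = TRUE)))
  if (length(unique(lengths(idx))) != 1) stop("rows differ in codon length")
  i1 <- idx[[1]]; i2 <- idx[[2]]; i3 <- idx[[3]]
  usable <- !is.na(i1) & !is.na(i2) & !is.na(i3) &
    !tabs$is_stop[i1] & !tabs$is_stop[i2] & !tabs$is_stop[i3]
  usable[is.na(usable)] <- FALSE
  i1 <- i1[usable]; i2 <- i2[usable]; i3 <- i3[usable]
  if (length(i1) == 0) stop("no usable codon columns")

  eq12 <- i1 == i2; eq13 <- i1 == i3; eq23 <- i2 == i3
  all_eq <- eq12 & eq13
  dev1 <- eq23 & !eq12          # species 1 deviates, ancestor = shared i2
  dev2 <- eq13 & !eq12
  dev3 <- eq12 & !eq13
  three_state <- !(all_eq | dev1 | dev2 | dev3)

  anc <- integer(length(i1))
  anc[all_eq] <- i1[all_eq]
  anc[dev1] <- i2[dev1]
  anc[dev2] <- i1[dev2]
  anc[dev3] <- i1[dev3]
  anc_used <- anc[!three_state]

  N <- sum(3 - tabs$site_s[anc_used])
  S <- sum(tabs$site_s[anc_used])

  branch <- function(dev_mask, dev_idx) {
    a <- anc[dev_mask]; d <- dev_idx[dev_mask]
    Nd <- sum(tabs$ND[cbind(a, d)])
    Sd <- sum(tabs$SD[cbind(a, d)])
    pn <- Nd / N; ps <- Sd / S
    dn <- jc_correct(pn); ds <- jc_correct(ps)
    c(Nd = Nd, Sd = Sd, N = N, S = S, pn = pn, ps = ps, dn = dn, ds = ds,
      omega = if (!is.na(ds) && ds > 0) dn / ds else NA_real_)
  }
  out <- as.data.frame(rbind(branch(dev1, i1), branch(dev2, i2),
                             branch(dev3, i3)))
  out <- cbind(branch = sp, out)
  rownames(out) <- NULL
  skipped <- mean(three_state)
  if (skipped > 0.05)
    warning(sprintf("%.1f%% of codon columns have three states and were skipped",
                    100 * skipped))
  attr(out, "skipped_fraction") <- skipped
  attr(out, "ancestral_codons") <- length(anc_used)
  out
}
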