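#' GC content of a sequence
#'
#' `N`s are excluded from the denominator.
#'
#' @param seq Nucleotide string.
#' @return Fraction of G+C among A/C/G/T bases.
#' @export
gc_content <- function(seq) {
  ch <- strsplit(gsub("U", "T", toupper(seq), fixed = TRUE), "",
                 fixed = TRUE)[[1]]
  acgt <- ch[ch %in% .BASES]
  if (length(acgt) == 0) stop("sequence contains no A/C/G/T bases")
  mean(acgt %in% c("G", "C"))
}

#' GC content at degenerate third codon positions (GC3s)
#'
#' Counts G+C among third positions of codons whose third position
#' admits at least one synonymous change — i.e. all sense codons except
#' ATG (Met) and TGG (Trp) under the standard code. Codons containing
#' `N` are excluded.
#'
#' @param coding_seq In-frame coding sequence (no internal stops).
#' @param code Genetic code.
#' @return Fraction in `[0, 1]`.
#' @export
gc3 <- function(coding_seq, code = genetic_code()) {
  if (nchar(coding_seq) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3")
  tabs <- codon_tables(code)
  idx <- codon_indices(gsub("-", "N", toupper(coding_seq), fixed = TRUE))
  idx <- idx[!is.na(idx)]
  if (any(tabs$is_stop[idx])) stop("internal stop codon")
  degen <- tabs$site_pos[idx, 3] > 0
  idx <- idx[degen]
  if (length(idx) == 0) stop("no codons with a degenerate third position")
  third <- ((idx - 1L) %% 4L)      # 0=A 1=C 2=G 3=T
  mean(third %in% c(1L, 2L))
}

#' Codon usage table with background composition
#'
#' @param seqs Character vector of in-frame coding sequences.
#' @param background `"from-data"` (nucleotide composition of the input
#'   sequences), `"uniform"`, or a numeric 4-vector of A/C/G/T
#'   frequencies summing to 1.
#' @param code Genetic code.
#' @return List of class `codon_usage_table` with `counts` (named
#'   integer vector over the sense codons) and `background` (named
#'   A/C/G/T frequencies).
#' @export
codon_usage_table <- function(seqs, background = "from-data",
                              code = genetic_code()) {
  tabs <- codon_tables(code)
  idx <- unlist(lapply(gsub("-", "N", toupper(seqs), fixed = TRUE),
                       codon_indices), use.names = FALSE)
  idx <- idx[!is.na(idx)]
  idx <- idx[!tabs$is_stop[idx]]
  counts <- tabulate(idx, nbins = 64L)
  names(counts) <- tabs$codons
  counts <- counts[!tabs$is_stop]
  if (identical(background, "from-data")) {
    ch <- strsplit(paste(toupper(seqs), collapse = ""), "", fixed = TRUE)[[1]]
    bg <- table(factor(ch[ch %in% .BASES], levels = .BASES))
    background <- as.numeric(bg / sum(bg))
  } else if (identical(background, "uniform")) {
    background <- rep(0.25, 4)
  }
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-9)
  if (any(background <= 0))
    stop("background composition must be strictly positive")
  structure(list(counts = counts,
                 background = stats::setNames(background, .BASES)),
            class = "codon_usage_table")
}

#' Combine codon usage tables
#'
#' Sums the counts of several [codon_usage_table()]s and pools their
#' backgrounds weighted by codon totals. Useful for bootstrapping a
#' statistic over concatenation units without re-tokenizing sequence:
#' tabulate each unit once, then combine resamples.
#'
#' @param tables List of `codon_usage_table`s.
#' @return A single `codon_usage_table`.
#' @export
combine_usage_tables <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "codon_usage_table")))
  counts <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  w <- vapply(tables, function(t) sum(t$counts), 1)
  bg <- Reduce(`+`, Map(function(t, wi) t$background * wi, tables, w)) / sum(w)
  structure(list(counts = counts, background = bg / sum(bg)),
            class = "codon_usage_table")
}

#' Background-corrected effective number of codons (Nc')
#'
#' Implements the composition-corrected effective number of codons: for
#' each synonymous family, expected codon frequencies are computed from
#' the background nucleotide composition (product over the three codon
#' positions, normalized within the family), a chi-square statistic of
#' observed versus expected counts is converted to the
#' homozygosity-analogue `F = (chi2 + n - k) / (k (n - 1))` (n = codons
#' observed for the amino acid, k = family size), and class-averaged F
#' values are aggregated as `Nc' = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` for
#' the standard code's 9 two-fold, 1 three-fold, 5 four-fold and 3
#' six-fold families (Leu, Ser and Arg kept as single six-fold
#' families). The result is clamped to `[20, 61]`: 61 means no bias
#' beyond background composition, 20 maximal bias (one codon per amino
#' acid).
#'
#' @param table A [codon_usage_table()].
#' @param min_codons Minimum total codon count (default 100).
#' @return Nc' as a single number.
#' @export
effective_codons_corrected <- function(table, min_codons = 100L) {
  stopifnot(inherits(table, "codon_usage_table"))
  if (sum(table$counts) < min_codons)
    stop("need at least ", min_codons, " codons for a stable estimate")
  tabs <- codon_tables(genetic_code())
  code_aa <- tabs$aa[!tabs$is_stop]
  fam <- split(names(table$counts), code_aa)
  fam <- fam[lengths(fam) > 1]             # Met/Trp enter as the constant 2
  bg <- table$background

  f_hat <- function(codons) {
    n_c <- table$counts[codons]
    n <- sum(n_c)
    if (n < 2) return(NA_real_)            # too few observations
    k <- length(codons)
    e <- vapply(codons, function(cd) {
      b <- strsplit(cd, "", fixed = TRUE)[[1]]
      prod(bg[b])
    }, 1)
    e <- e / sum(e)
    chi2 <- sum((n_c - n * e)^2 / (n * e))
    (chi2 + n - k) / (k * (n - 1))
  }

  F_by_fam <- vapply(fam, f_hat, 1)
  degeneracy <- lengths(fam)
  class_weights <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  nc <- 2
  for (k in names(class_weights)) {
    Fk <- F_by_fam[degeneracy == as.integer(k)]
    Fk <- Fk[!is.na(Fk) & Fk > 0]
    if (length(Fk) == 0)
      stop("no observed family with degeneracy ", k,
           "; cannot aggregate Nc'")
    nc <- nc + class_weights[[k]] / mean(Fk)
  }
  min(max(nc, 20), 61)
}

#' Percentile bootstrap confidence interval over concatenation units
#'
#' Resamples the units with replacement and evaluates the statistic on
#' each resample; the interval is the (1-level)/2 and 1-(1-level)/2
#' percentiles. Deterministic under the given seed.
#'
#' @param statistic Function taking a list of units and returning one
#'   number.
#' @param units List of >= 2 units.
#' @param n_boot Number of bootstrap replicates; fewer than 100 draws a
#'   warning.
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `lo`, `hi`, `point` (statistic on the full set).
#' @export
bootstrap_ci <- function(statistic, units, n_boot = 1000L, seed = 1L,
                         level = 0.95) {
  stopifnot(length(units) >= 2)
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  point <- statistic(units)
  reps <- with_preserved_rng(seed, {
    vapply(seq_len(n_boot), function(b)
      statistic(units[sample.int(length(units), replace = TRUE)]), 1)
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(lo = qs[1], hi = qs[2], point = point)
}
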