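#' The standard genetic code
#'
#' Returns the genetic code used throughout the package: a named map from
#' the 64 DNA codons to one-letter amino-acid symbols (stops as `"*"`),
#' plus the set of stop codons. The standard table is taken from
#' [Biostrings::GENETIC_CODE].
#'
#' The probability that a uniformly random codon is a stop codon under
#' this code is 3/64, the quantity behind the minimum-ORF-length
#' criterion (see [min_orf_codons()]).
#'
#' @return A list with elements `table` (named character vector of length
#'   64) and `stop_codons` (character vector, `c("TAA","TAG","TGA")` for
#'   the standard code).
#' @examples
#' gc <- genetic_code()
#' gc$table[["ATG"]]   # "M"
#' gc$stop_codons
#' @export
genetic_code <- function() {
  tab <- Biostrings::GENETIC_CODE
  stopifnot(length(tab) == 64L)
  list(table = tab, stop_codons = names(tab)[tab == "*"])
}

## Fixed codon order used for all integer encodings: index =
## 16*(b1-1) + 4*(b2-1) + b3 with bases ordered A,C,G,T.
.BASES <- c("A", "C", "G", "T")

.codon_strings <- function() {
  b <- .BASES
  paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
}

## Package-level cache for the (expensive) codon tables of the standard
## code; non-standard codes are rebuilt on demand.
.codon_env <- new.env(parent = emptyenv())

#' Precomputed codon tables for fast counting
#'
#' Internal workhorse: per-codon neighbour structure (all 9 single
#' nucleotide mutants), synonymous/stop flags, Nei-Gojobori per-position
#' synonymous site fractions, and the 64 x 64 pathway-averaged
#' synonymous/nonsynonymous difference tables used by the pairwise and
#' branch-wise estimators.
#'
#' Site fractions use stop-excluded denominators: at each codon position
#' the synonymous fraction is (number of synonymous single-base changes) /
#' (number of single-base changes not creating a stop), so every position
#' contributes exactly one site and n + s = 3 per codon.
#'
#' @param code A genetic code as returned by [genetic_code()].
#' @return A list of lookup tables (see source).
#' @keywords internal
codon_tables <- function(code = genetic_code()) {
  std <- identical(code$table, Biostrings::GENETIC_CODE)
  if (std && !is.null(.codon_env$std_tables)) return(.codon_env$std_tables)

  codons <- .codon_strings()
  aa <- unname(code$table[codons])
  if (anyNA(aa)) stop("genetic code table must cover all 64 codons")
  is_stop <- aa == "*"

  ## neighbour matrices: 9 single-nucleotide mutants per codon
  nb_idx <- matrix(0L, 64, 9)
  nb_pos <- matrix(0L, 64, 9)
  nb_syn <- matrix(FALSE, 64, 9)
  nb_stop <- matrix(FALSE, 64, 9)
  base_of <- function(i, p) ((i - 1L) %/% 4L^(3L - p)) %% 4L # 0..3
  for (i in 1:64) {
    k <- 0L
    for (p in 1:3) {
      b <- base_of(i, p)
      for (nb in setdiff(0:3, b)) {
        k <- k + 1L
        j <- i + (nb - b) * 4L^(3L - p)
        nb_idx[i, k] <- j
        nb_pos[i, k] <- p
        nb_syn[i, k] <- !is_stop[i] && !is_stop[j] && aa[j] == aa[i]
        nb_stop[i, k] <- is_stop[j]
      }
    }
  }

  ## per-position synonymous site fractions (NG86, stop-excluded)
  site_pos <- matrix(NA_real_, 64, 3)
  for (i in which(!is_stop)) {
    for (p in 1:3) {
      sel <- nb_pos[i, ] == p
      nonstop <- sel & !nb_stop[i, ]
      site_pos[i, p] <- if (any(nonstop)) sum(nb_syn[i, sel]) / sum(nonstop) else 0
    }
  }
  site_s <- rowSums(site_pos)

  ## pathway-averaged pairwise differences (nd, sd) between sense codons
  ND <- matrix(NA_real_, 64, 64)
  SD <- matrix(NA_real_, 64, 64)
  sense <- which(!is_stop)
  for (i in sense) {
    for (j in sense) {
      if (i == j) { ND[i, j] <- 0; SD[i, j] <- 0; next }
      cnt <- .pathway_counts(i, j, aa, is_stop)
      ND[i, j] <- cnt[1]
      SD[i, j] <- cnt[2]
    }
  }

  out <- list(
    codons = codons, aa = aa, is_stop = is_stop,
    nb_idx = nb_idx, nb_pos = nb_pos, nb_syn = nb_syn, nb_stop = nb_stop,
    site_pos = site_pos, site_s = site_s, ND = ND, SD = SD
  )
  if (std) .codon_env$std_tables <- out
  out
}

## Average (nonsyn, syn) step counts over minimal mutational pathways
## from codon i to codon j, skipping pathways through stop codons.
## If every pathway passes through a stop, all pathways are used.
.pathway_counts <- function(i, j, aa, is_stop) {
  pos <- which(.codon_digits(i) != .codon_digits(j))
  m <- length(pos)
  orders <- .perms(pos)
  nd <- sd <- numeric(0)
  nd_all <- sd_all <- numeric(0)
  dj <- .codon_digits(j)
  for (r in seq_len(nrow(orders))) {
    cur <- .codon_digits(i)
    n_ns <- n_s <- 0
    hit_stop <- FALSE
    for (p in orders[r, ]) {
      nxt <- cur
      nxt[p] <- dj[p]
      ci <- .digits_to_idx(cur); ni <- .digits_to_idx(nxt)
      if (is_stop[ni]) hit_stop <- TRUE
      if (!is_stop[ni] && !is_stop[ci] && aa[ni] == aa[ci]) n_s <- n_s + 1
      else n_ns <- n_ns + 1
      cur <- nxt
    }
    nd_all <- c(nd_all, n_ns); sd_all <- c(sd_all, n_s)
    if (!hit_stop) { nd <- c(nd, n_ns); sd <- c(sd, n_s) }
  }
  if (length(nd) == 0L) { nd <- nd_all; sd <- sd_all }
  c(mean(nd), mean(sd))
}

.codon_digits <- function(i) {
  i <- i - 1L
  c(i %/% 16L, (i %/% 4L) %% 4L, i %% 4L)
}

.digits_to_idx <- function(d) 16L * d[1] + 4L * d[2] + d[3] + 1L

.perms <- function(x) {
  n <- length(x)
  if (n <= 1L) return(matrix(x, nrow = 1L))
  out <- NULL
  for (k in seq_len(n)) {
    rest <- .perms(x[-k])
    out <- rbind(out, cbind(x[k], rest))
  }
  out
}

#' Encode a nucleotide sequence as codon indices
#'
#' Maps an in-frame A/C/G/T/N string to integer codon indices in the
#' package's fixed codon order; any codon containing a character other
#' than A/C/G/T (e.g. `N`, or a gap) encodes as `NA`.
#'
#' @param seq A single nucleotide string; characters beyond the last
#'   complete codon are ignored.
#' @return Integer vector of length `floor(nchar(seq)/3)` with values in
#'   1..64 or `NA`.
#' @keywords internal
codon_indices <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(integer(0))
  ch <- strsplit(substr(seq, 1L, 3L * n), "", fixed = TRUE)[[1]]
  d <- match(ch, .BASES) - 1L
  dim(d) <- c(3L, n)
  idx <- 16L * d[1L, ] + 4L * d[2L, ] + d[3L, ] + 1L
  idx
}

#' Decode codon indices back to a nucleotide string
#' @param idx Integer codon indices (1..64), no NAs.
#' @return A single nucleotide string.
#' @keywords internal
codons_from_indices <- function(idx) {
  paste(.codon_strings()[idx], collapse = "")
}

#' Translate a nucleotide sequence
#'
#' Translates in the given frame under a genetic code. Stop codons are
#' rendered as `*`; codons containing `N` as `X`. Trailing bases short of
#' a full codon are dropped.
#'
#' @param seq Nucleotide string over A/C/G/T/N (case-insensitive; `U`
#'   accepted as `T`).
#' @param frame 0, 1 or 2: number of bases skipped before the first codon.
#' @param code Genetic code, see [genetic_code()].
#' @return Amino-acid string of length `floor((nchar(seq)-frame)/3)`.
#' @examples
#' translate_dna("ATGAAATGA")      # "MK*"
#' translate_dna("ATGAAATGA", 1)   # "*N"
#' @export
translate_dna <- function(seq, frame = 0, code = genetic_code()) {
  stopifnot(length(seq) == 1L, frame %in% 0:2)
  s <- toupper(seq)
  s <- gsub("U", "T", s, fixed = TRUE)
  if (grepl("[^ACGTN]", s)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", s), "")[[1]])
    stop("invalid nucleotide character(s): ", paste(bad, collapse = ", "))
  }
  if (frame >= nchar(s)) stop("frame must be smaller than sequence length")
  s <- substr(s, frame + 1L, nchar(s))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  idx <- codon_indices(s)
  aa <- codon_tables(code)$aa[idx]
  aa[is.na(idx)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of a nucleotide string
#' @param seq Nucleotide string over A/C/G/T/N.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}
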