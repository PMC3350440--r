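#' Minimum ORF length under the random-stop criterion
#'
#' The number of stop codons in n random codons is Binomial(n, p) with
#' p = 3/64 under the standard code. The probability of a stop-free run
#' of length n is (1 - p)^n; the minimum accepted ORF length is the
#' smallest integer n for which this probability falls below `alpha`,
#' i.e. the ceiling of log(alpha)/log(1 - p). At alpha = 0.05 the real
#' bound is 62.3991, giving a threshold of 63 codons (189 bp).
#'
#' @param alpha Significance level in (0, 1).
#' @param p_stop Per-codon stop probability (3/64 for the standard code).
#' @return Integer codon count.
#' @examples
#' min_orf_codons(0.05)  # 63
#' @export
min_orf_codons <- function(alpha, p_stop = 3 / 64) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must lie strictly in (0, 1)")
  n <- as.integer(ceiling(log(alpha) / log(1 - p_stop)))
  if (n < 1L) n <- 1L
  ## strict inequality: on an exact-integer bound the next n is needed
  while ((1 - p_stop)^n >= alpha) n <- n + 1L
  n
}

#' Longest open reading frame
#'
#' Finds the longest maximal run of non-stop codons over the searched
#' frames (three forward frames, and the three reverse-complement frames
#' unless `search_reverse = FALSE`). A start codon is not required by
#' default: the length statistic behind [min_orf_codons()] models
#' stop-free runs, not ATG-anchored genes. Codons containing `N` break a
#' run (they cannot be certified stop-free). Ties are broken by forward
#' strand first, then lower frame, then smaller start.
#'
#' @param seq Nucleotide string (>= 3 nt).
#' @param code Genetic code.
#' @param require_start If `TRUE`, runs are trimmed to begin at their
#'   first ATG.
#' @param search_reverse Also search the reverse complement (default).
#' @return A list of class `orf` with elements `strand` (`"+"`/`"-"`),
#'   `frame` (0/1/2), `start`, `end` (0-based half-open nucleotide
#'   coordinates on the reported strand) and `codon_length`.
#' @export
longest_orf <- function(seq, code = genetic_code(), require_start = FALSE,
                        search_reverse = TRUE) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  if (nchar(seq) < 3) stop("sequence shorter than one codon")
  tabs <- codon_tables(code)
  best <- NULL
  strands <- if (search_reverse) c("+", "-") else "+"
  for (strand in strands) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      if (nchar(s) - frame < 3) next
      idx <- codon_indices(substr(s, frame + 1L, nchar(s)))
      if (length(idx) == 0) next
      ok <- !is.na(idx) & !tabs$is_stop[idx]
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      for (k in runs) {
        a <- starts[k]; b <- ends[k]         # codon indices within frame
        if (require_start) {
          hit <- which(tabs$codons[idx[a:b]] == "ATG")
          if (length(hit) == 0) next
          a <- a + hit[1] - 1L
        }
        len <- b - a + 1L
        if (is.null(best) || len > best$codon_length) {
          best <- list(strand = strand, frame = frame,
                       start = frame + 3L * (a - 1L),
                       end = frame + 3L * b,
                       codon_length = len)
        }
      }
    }
  }
  if (is.null(best)) stop("no open reading frame found")
  class(best) <- "orf"
  best
}

#' Extract the nucleotide sequence of an ORF
#' @param seq The transcript the ORF was found in.
#' @param orf An `orf` from [longest_orf()].
#' @return In-frame nucleotide string of length `3 * codon_length`.
#' @export
orf_sequence <- function(seq, orf) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  s <- if (orf$strand == "+") seq else revcomp(seq)
  substr(s, orf$start + 1L, orf$end)
}
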