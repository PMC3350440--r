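#' Curate a codon alignment for frame integrity
#'
#' Applies the frame-aware cleaning protocol for externally aligned
#' coding sequences:
#' \enumerate{
#'   \item The alignment is cut before the first gap run whose length is
#'     not divisible by three in any row (a putative frame shift from a
#'     sequencing/assembly error); everything from that run onward is
#'     discarded in \emph{all} rows, since cutting a single row would
#'     break the columnar alignment. This is repeated until no
#'     frame-shift run remains (a cut can bisect a later run).
#'   \item Every remaining gap run (length divisible by three) is moved
#'     to the closest codon boundary (ties move left), so gaps align
#'     with codons.
#'   \item Trailing columns short of a full codon are trimmed.
#' }
#' Residue content of each row is never altered, only truncated or
#' locally reordered around gaps.
#'
#' @param aln Named character vector of equal-length gapped rows
#'   (gap character `-`), one per species.
#' @return The curated alignment (same class of object); zero columns if
#'   the first frame shift is at the start, which callers should treat
#'   as "alignment dropped".
#' @export
curate_alignment <- function(aln) {
  stopifnot(is.character(aln), length(aln) >= 2)
  w <- unique(nchar(aln))
  if (length(w) != 1) stop("alignment rows differ in length")

  repeat {
    cut_at <- Inf
    for (row in aln) {
      runs <- gregexpr("-+", row)[[1]]
      if (runs[1] == -1) next
      len <- attr(runs, "match.length")
      bad <- len %% 3L != 0L
      if (any(bad)) cut_at <- min(cut_at, runs[bad][1])
    }
    if (!is.finite(cut_at)) break
    aln <- substr(aln, 1L, cut_at - 1L)
  }

  aln <- vapply(aln, .shift_gaps_inframe, "", USE.NAMES = TRUE)

  keep <- (nchar(aln)[1] %/% 3L) * 3L
  substr(aln, 1L, keep)
}

## Move every (mod-3) gap run of one row to the nearest codon boundary.
## The row is rebuilt from its residues: because every run length is
## divisible by three, a run starting at 0-based column c sits at a codon
## boundary iff its residue offset o (residues preceding it) satisfies
## o %% 3 == 0, so each run is re-inserted at the nearest such offset
## (ties left; runs merging at one offset stay on a boundary).
.shift_gaps_inframe <- function(row) {
  runs <- gregexpr("-+", row)[[1]]
  if (runs[1] == -1) return(row)
  lens <- attr(runs, "match.length")
  residues <- gsub("-", "", row, fixed = TRUE)
  nres <- nchar(residues)
  cum_g <- c(0, cumsum(lens))[seq_along(runs)]
  o <- runs - 1L - cum_g                  # residue offset of each run
  r <- o %% 3L
  o_new <- ifelse(r == 0L, o,
           ifelse(r <= 3L - r, o - r, o + 3L - r))
  o_new <- ifelse(o_new > nres, o - r, o_new)
  ## rebuild: walk residues, dropping gap runs at their target offsets
  ord <- order(o_new)
  o_new <- o_new[ord]; glen <- lens[ord]
  out <- character(0)
  prev <- 0L
  for (k in seq_along(o_new)) {
    out <- c(out, substr(residues, prev + 1L, o_new[k]),
             strrep("-", glen[k]))
    prev <- o_new[k]
  }
  out <- c(out, substr(residues, prev + 1L, nres))
  paste(out, collapse = "")
}

#' Discard alignments shorter than the ORF-derived threshold
#'
#' @param alignments List of curated codon alignments.
#' @param min_bp Minimum column count; alignments strictly shorter are
#'   discarded. Defaults to three times the 0.05-level codon threshold
#'   of [min_orf_codons()], i.e. 189 bp.
#' @return List with elements `kept` (the surviving alignments) and
#'   `log` (data.frame of rejected alignment names and lengths).
#' @export
filter_short <- function(alignments, min_bp = 3L * min_orf_codons(0.05)) {
  if (length(alignments) == 0)
    return(list(kept = alignments,
                log = data.frame(alignment = character(), columns = integer())))
  ncols <- vapply(alignments, function(a) nchar(a[[1]]), 1L)
  drop <- ncols < min_bp
  nm <- names(alignments)
  if (is.null(nm)) nm <- as.character(seq_along(alignments))
  list(kept = alignments[!drop],
       log = data.frame(alignment = nm[drop], columns = ncols[drop],
                        row.names = NULL))
}

#' Concatenate alignments into equal-sized units
#'
#' Genes are shuffled by a seeded RNG and dealt in that order into
#' `n_units` groups whose gene counts differ by at most one (the first
#' `N %% n_units` groups receive the extra gene). Within a unit the rows
#' of the member alignments are concatenated species-wise.
#'
#' @param alignments Named list of codon alignments sharing row names.
#' @param n_units Number of units (default 20).
#' @param rng_seed Seed for the shuffle.
#' @return List of `n_units` concatenated alignments; each carries the
#'   member gene names in `attr(, "genes")`.
#' @export
concatenate_units <- function(alignments, n_units = 20L, rng_seed = 1L) {
  N <- length(alignments)
  if (N < n_units) stop("fewer alignments (", N, ") than units (", n_units, ")")
  ord <- with_preserved_rng(rng_seed, sample.int(N))
  sizes <- rep(N %/% n_units, n_units) + (seq_len(n_units) <= N %% n_units)
  bounds <- cumsum(sizes)
  start <- c(1L, utils::head(bounds, -1L) + 1L)
  rows <- names(alignments[[1]])
  lapply(seq_len(n_units), function(u) {
    members <- alignments[ord[start[u]:bounds[u]]]
    unit <- vapply(rows, function(r)
      paste(vapply(members, `[[`, "", r), collapse = ""), "")
    attr(unit, "genes") <- names(members)
    unit
  })
}

#' Evaluate an expression under a fixed seed, restoring the RNG state
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_preserved_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
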