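#' Best hits per query
#'
#' Applies the E-value cut-off, then keeps for each query the
#' maximum-bitscore subject. Ties on bitscore are broken by lower
#' E-value, then by lexicographically smaller subject id, so the result
#' is deterministic.
#'
#' @param hits Hit data.frame (query, subject, bitscore, evalue), all
#'   from one query-species to subject-species direction.
#' @param evalue_cutoff Hits with evalue strictly greater are discarded.
#' @return Named character vector: query id -> best subject id.
#' @export
best_hits <- function(hits, evalue_cutoff = 1e-5) {
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0) return(stats::setNames(character(0), character(0)))
  o <- order(hits$query, -hits$bitscore, hits$evalue, hits$subject,
             method = "radix")
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(hits$query)
  stats::setNames(hits$subject[keep], hits$query[keep])
}

#' Reciprocal best-hit pairs
#'
#' A pair (a, b) is reciprocal iff a's best hit is b and b's best hit
#' is a.
#'
#' @param best_ab,best_ba Named vectors from [best_hits()] in the two
#'   directions.
#' @return Data.frame with columns `id_a`, `id_b`, ordered by `id_a`.
#' @export
reciprocal_pairs <- function(best_ab, best_ba) {
  a <- names(best_ab)
  b <- unname(best_ab)
  back <- unname(best_ba[b])
  keep <- !is.na(back) & back == a
  out <- data.frame(id_a = a[keep], id_b = b[keep])
  out[order(out$id_a), , drop = FALSE]
}

#' Classify ortholog triplets from three pairwise RBH sets
#'
#' Builds the graph whose nodes are transcripts and whose edges are the
#' reciprocal best-hit pairs of the three species comparisons, then
#' classifies each connected component:
#' \describe{
#'   \item{accepted_three_way}{a closed triangle: one transcript per
#'     species, all three pairwise RBH edges present and agreeing.}
#'   \item{two_pair_only}{exactly two edges (an open path); the third
#'     comparison failed to close the triangle. Excluded downstream as
#'     possible paralogy.}
#'   \item{single_pair}{one edge only.}
#'   \item{inconsistent_triangle}{components whose edges disagree on the
#'     member ids (e.g. two different partners claimed in one species).}
#' }
#'
#' @param pairs_ab,pairs_bc,pairs_ac RBH pair data.frames from
#'   [reciprocal_pairs()] for the species pairs (A,B), (B,C), (A,C).
#' @param species Character vector of the three species labels, in the
#'   order (A, B, C).
#' @return Data.frame with one row per component: columns `id_a`,
#'   `id_b`, `id_c` (NA when that species is absent; the first id
#'   encountered when a species contributes several) and `status`.
#' @export
classify_triplets <- function(pairs_ab, pairs_bc, pairs_ac,
                              species = c("sp1", "sp2", "sp3")) {
  edge <- function(p, sa, sb) {
    if (nrow(p) == 0) return(NULL)
    data.frame(u = paste0(sa, "\r", p$id_a), v = paste0(sb, "\r", p$id_b))
  }
  edges <- rbind(edge(pairs_ab, "A", "B"),
                 edge(pairs_bc, "B", "C"),
                 edge(pairs_ac, "A", "C"))
  empty <- data.frame(id_a = character(), id_b = character(),
                      id_c = character(), status = character())
  if (is.null(edges) || nrow(edges) == 0) return(empty)

  nodes <- sort(unique(c(edges$u, edges$v)))
  comp <- stats::setNames(seq_along(nodes), nodes)
  ## union-find over the (tiny) RBH graph
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (r in seq_len(nrow(edges))) {
    i <- find(match(edges$u[r], nodes))
    j <- find(match(edges$v[r], nodes))
    if (i != j) comp[max(i, j)] <- min(i, j)
  }
  roots <- vapply(seq_along(nodes), find, 1L)
  groups <- split(nodes, roots)

  eu <- match(edges$u, nodes)
  edge_root <- roots[eu]

  rows <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    sp <- substr(members, 1, 1)
    id <- substr(members, 3, nchar(members))
    n_edges <- sum(edge_root == as.integer(g))
    per_sp <- table(factor(sp, levels = c("A", "B", "C")))
    pick <- function(s) { i <- which(sp == s); if (length(i)) id[i[1]] else NA_character_ }
    status <-
      if (any(per_sp > 1)) "inconsistent_triangle"
      else if (n_edges == 3 && all(per_sp == 1)) "accepted_three_way"
      else if (n_edges == 2) "two_pair_only"
      else if (n_edges == 1) "single_pair"
      else "inconsistent_triangle"
    data.frame(id_a = pick("A"), id_b = pick("B"), id_c = pick("C"),
               status = status)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("id_a", "id_b", "id_c", "status")
  key <- ifelse(is.na(out$id_a), ifelse(is.na(out$id_b), out$id_c, out$id_b),
                out$id_a)
  out <- out[order(key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "species") <- species
  out
}

#' Shared k-mer similarity scores between two transcript sets
#'
#' A lightweight internal similarity scorer so simulated data can be
#' pushed through the orthology stage without an external aligner. The
#' score of a pair is the number of distinct k-mers the two sequences
#' share, reported as the bitscore; the E-value is the monotone stand-in
#' `10^-score` (so smaller means more similar, as usual).
#'
#' @param set_a,set_b [transcript_set]s.
#' @param k K-mer length (>= 4); the default 12 tolerates the few
#'   percent per-site divergence typical of congeneric species.
#' @return Hit data.frame (query from `set_a`, subject from `set_b`)
#'   containing all pairs with at least one shared k-mer.
#' @export
toy_similarity_scores <- function(set_a, set_b, k = 12L) {
  if (k < 4) stop("k must be >= 4")
  if (min(nchar(set_a$sequences), nchar(set_b$sequences)) < k)
    stop("k longer than the shortest sequence")
  kmer_table <- function(seqs) {
    ids <- rep(names(seqs), vapply(seqs, nchar, 1L) - k + 1L)
    km <- unlist(lapply(seqs, function(s)
      substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))), use.names = FALSE)
    unique(data.table::data.table(id = ids, kmer = km))
  }
  ta <- kmer_table(set_a$sequences)
  tb <- kmer_table(set_b$sequences)
  data.table::setkey(ta, kmer)
  data.table::setkey(tb, kmer)
  m <- merge(ta, tb, by = "kmer", allow.cartesian = TRUE,
             suffixes = c(".a", ".b"))
  if (nrow(m) == 0)
    return(data.frame(query = character(), subject = character(),
                      bitscore = numeric(), evalue = numeric()))
  cnt <- m[, .N, by = c("id.a", "id.b")]
  data.frame(query = cnt$id.a, subject = cnt$id.b,
             bitscore = as.numeric(cnt$N), evalue = 10^(-as.numeric(cnt$N)))
}
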