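# Shared fixture builders and independent oracles. Oracles are written
# from the definitions, independently of the package internals they
# check.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

random_codon_seq <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

random_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Enumeration oracle for NG86 site fractions of one codon: at each
# position, the synonymous fraction among single-base changes that do
# not create a stop.
oracle_site_counts <- function(codon) {
  tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    syn <- 0; tot <- 0
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (tab[[mut]] == "*") next
      tot <- tot + 1
      if (tab[[mut]] == tab[[codon]]) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  list(s_sites = s, n_sites = 3 - s)
}

# Pathway-enumeration oracle for the (nonsyn, syn) difference counts
# between two sense codons, averaging over stop-free minimal pathways
# (all pathways if none is stop-free).
oracle_path_counts <- function(c1, c2) {
  tab <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(nd = 0, sd = 0))
  orders <- pracma::perms(pos)
  if (is.null(dim(orders))) orders <- matrix(orders, nrow = 1)
  res <- list(); res_all <- list()
  for (r in seq_len(nrow(orders))) {
    cur <- c1; nd <- 0; sd <- 0; stopped <- FALSE
    for (p in orders[r, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (tab[[nxt]] == "*") stopped <- TRUE
      if (tab[[nxt]] != "*" && tab[[cur]] != "*" && tab[[nxt]] == tab[[cur]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res_all[[r]] <- c(nd, sd)
    if (!stopped) res[[length(res) + 1]] <- c(nd, sd)
  }
  if (length(res) == 0) res <- res_all
  m <- do.call(rbind, res)
  c(nd = mean(m[, 1]), sd = mean(m[, 2]))
}

# Brute-force O(n^2) reciprocal-best-hit oracle over a raw hit table.
oracle_best <- function(hits, cutoff = 1e-5) {
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  out <- character(0)
  for (q in unique(hits$query)) {
    h <- hits[hits$query == q, , drop = FALSE]
    best <- h[1, ]
    for (r in seq_len(nrow(h))) {
      cand <- h[r, ]
      if (cand$bitscore > best$bitscore ||
          (cand$bitscore == best$bitscore && cand$evalue < best$evalue) ||
          (cand$bitscore == best$bitscore && cand$evalue == best$evalue &&
           cand$subject < best$subject))
        best <- cand
    }
    out[q] <- best$subject
  }
  out
}

oracle_rbh <- function(hits_ab, hits_ba, cutoff = 1e-5) {
  fa <- oracle_best(hits_ab, cutoff)
  fb <- oracle_best(hits_ba, cutoff)
  pairs <- data.frame(id_a = character(), id_b = character())
  for (a in names(fa)) {
    b <- fa[[a]]
    if (!is.na(fb[b]) && fb[[b]] == a)
      pairs <- rbind(pairs, data.frame(id_a = a, id_b = b))
  }
  pairs[order(pairs$id_a), , drop = FALSE]
}

# Random hit table between two id universes.
random_hit_table <- function(n_a, n_b, n_hits, prefix_a, prefix_b) {
  data.frame(
    query = sample(paste0(prefix_a, seq_len(n_a)), n_hits, replace = TRUE),
    subject = sample(paste0(prefix_b, seq_len(n_b)), n_hits, replace = TRUE),
    bitscore = sample(seq(20, 60, by = 5), n_hits, replace = TRUE),
    evalue = 10^-sample(3:30, n_hits, replace = TRUE))
}

# Exhaustive six-frame ORF oracle with the package's tie-break order.
oracle_longest_orf <- function(seq) {
  tab <- Biostrings::GENETIC_CODE
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    for (frame in 0:2) {
      i <- frame + 1
      run_start <- NA; run_len <- 0
      k <- 0
      while (i + 2 <= nchar(s)) {
        cod <- substr(s, i, i + 2)
        ok <- !grepl("N", cod) && tab[[cod]] != "*"
        if (ok) {
          if (run_len == 0) run_start <- k
          run_len <- run_len + 1
        }
        if (!ok || i + 5 > nchar(s)) {
          if (run_len > 0 && (is.null(best) || run_len > best$codon_length))
            best <- list(strand = strand, frame = frame,
                         start = frame + 3 * run_start,
                         end = frame + 3 * (run_start + run_len),
                         codon_length = run_len)
          if (!ok) run_len <- 0
        }
        i <- i + 3; k <- k + 1
      }
    }
  }
  best
}
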