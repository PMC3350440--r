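#' Transcript sets
#'
#' A transcript set is one species' collection of putative transcripts:
#' a named character vector of uppercase A/C/G/T/N sequences plus a
#' species label. This is the unit every pipeline stage consumes.
#'
#' @param species_id Species label.
#' @param sequences Named character vector of nucleotide sequences.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(species_id, sequences) {
  stopifnot(is.character(sequences), length(sequences) > 0)
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "")) stop("all transcripts must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate transcript id(s): ",
                        paste(unique(dup), collapse = ", "))
  if (any(nchar(sequences) == 0)) stop("empty sequence(s) in transcript set")
  seqs <- gsub("U", "T", toupper(sequences), fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN characters in transcript(s): ",
                     paste(utils::head(ids[bad], 5), collapse = ", "))
  names(seqs) <- ids
  structure(list(species_id = species_id, sequences = seqs),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("<transcript_set> species:", x$species_id,
      "|", length(x$sequences), "transcripts, total",
      sum(nchar(x$sequences)), "nt\n")
  invisible(x)
}

#' Read a FASTA file of transcripts
#'
#' Sequences are uppercased and `U` is mapped to `T`. Record ids are the
#' header up to the first whitespace. Duplicate ids and empty files are
#' hard errors.
#'
#' @param path FASTA file.
#' @param species_id Species label; defaults to the file name without
#'   extension.
#' @return A [transcript_set].
#' @export
read_transcripts <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (is.null(species_id))
    species_id <- tools::file_path_sans_ext(basename(path))
  transcript_set(species_id, stats::setNames(as.character(x), ids))
}

#' Write a transcript set (or any named sequences) as FASTA
#' @param x A [transcript_set] or named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "transcript_set")) x$sequences else x
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a tabular similarity-hit file
#'
#' Parses BLAST outfmt-6-style whitespace- or tab-separated tables into a
#' hit table with columns `query`, `subject`, `bitscore`, `evalue`.
#' Filtering (e.g. by E-value) is deliberately not done here.
#'
#' @param path Hit table file.
#' @param columns Integer positions of the query, subject, bitscore and
#'   evalue columns (defaults 1, 2, 12, 11 are overridden to 1,2,3,4 when
#'   the file has fewer than 12 columns; the standard BLAST outfmt 6 has
#'   bitscore last and evalue second-to-last).
#' @return A data.frame of hits (possibly empty).
#' @export
read_hits <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(query = character(), subject = character(),
                      bitscore = numeric(), evalue = numeric()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncol <- vapply(fields, length, 1L)
  if (any(ncol < 4)) stop("hit table needs >= 4 columns; row(s) ",
                          paste(utils::head(which(ncol < 4), 5), collapse = ", "),
                          " have fewer")
  if (is.null(columns)) {
    columns <- if (min(ncol) >= 12) c(1L, 2L, 12L, 11L) else c(1L, 2L, 3L, 4L)
  }
  if (any(ncol < max(columns))) stop("hit table rows have fewer columns than requested")
  get <- function(k) vapply(fields, `[[`, "", k)
  bit <- suppressWarnings(as.numeric(get(columns[3])))
  eva <- suppressWarnings(as.numeric(get(columns[4])))
  bad <- which(is.na(bit) | is.na(eva))
  if (length(bad)) stop("unparseable numeric field(s) in row(s): ",
                        paste(utils::head(bad, 10), collapse = ", "))
  data.frame(query = get(columns[1]), subject = get(columns[2]),
             bitscore = bit, evalue = eva)
}

#' Write a hit table in 4-column tabular form
#' @param hits Data.frame with query, subject, bitscore, evalue.
#' @param path Output file.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, c("query", "subject", "bitscore", "evalue")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-base pileup table
#'
#' The pileup dialect is a plain 9-column TSV with header
#' `contig position ref depth A C G T gap` (the `gap` column may be
#' absent, in which case it is taken as zero). Positions are 1-based and
#' must be strictly increasing within a contig; a contig may not be
#' interrupted by another contig's rows. Rows whose `depth` field does
#' not equal the sum of the base and gap counts are kept but flagged in
#' the logical `depth_mismatch` column.
#'
#' @param path Pileup TSV.
#' @return Data.frame with columns contig, position, ref, depth, A, C,
#'   G, T, gap, depth_mismatch.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("contig", "position", "ref", "depth", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    stop("pileup must have columns: ", paste(need, collapse = ", "))
  if (!"gap" %in% names(df)) df$gap <- 0L
  ## sortedness: strictly increasing positions, contigs contiguous
  r <- rle(df$contig)
  if (anyDuplicated(r$values))
    stop("pileup contigs are interleaved: ",
         r$values[duplicated(r$values)][1])
  bad <- unlist(lapply(split(df$position, factor(df$contig, unique(df$contig))),
                       function(p) any(diff(p) <= 0)))
  if (any(bad))
    stop("positions not strictly increasing within contig(s): ",
         paste(names(bad)[bad], collapse = ", "))
  df$depth_mismatch <- df$depth != df$A + df$C + df$G + df$T + df$gap
  df
}

#' Write a pileup table in the package's TSV dialect
#' @param pileup Data.frame as produced by [read_pileup()] or
#'   [simulate_pileups()].
#' @param path Output file.
#' @export
write_pileup <- function(pileup, path) {
  cols <- c("contig", "position", "ref", "depth", "A", "C", "G", "T", "gap")
  utils::write.table(pileup[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a result table with a config-echo header
#'
#' Every result table carries `#`-prefixed header lines recording the
#' thresholds and seed that produced it, so outputs are self-describing.
#'
#' @param df Data.frame to write.
#' @param path Output file.
#' @param config Optional [analysis_config()] echoed into the header.
#' @param extra Optional named character vector of extra header fields.
#' @export
write_result_table <- function(df, path, config = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    for (k in names(config))
      writeLines(sprintf("# %s = %s", k, format(config[[k]])), con)
  }
  if (!is.null(extra)) {
    for (k in names(extra))
      writeLines(sprintf("# %s = %s", k, extra[[k]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export SNP calls as minimal VCF 4.2
#'
#' Writes CHROM/POS/REF/ALT plus INFO fields DP, MAF, EFFECT and
#' POLARITY. REF is the major allele and ALT the minor allele unless the
#' site is polarized, in which case REF is the ancestral and ALT the
#' derived allele.
#'
#' @param calls SNP call data.frame from [call_variants()] (optionally
#'   polarized/classified).
#' @param path Output file.
#' @param config Optional [analysis_config()] echoed as `##` meta lines.
#' @export
write_snp_vcf <- function(calls, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(config))
    for (k in names(config))
      writeLines(sprintf("##orthotrio_%s=%s", k, format(config[[k]])), con)
  writeLines(c(
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=MAF,Number=1,Type=Float,Description="Minor allele frequency">',
    '##INFO=<ID=EFFECT,Number=1,Type=String,Description="synonymous|nonsynonymous|noncoding|undetermined">',
    '##INFO=<ID=POLARITY,Number=1,Type=String,Description="ancestral_major|ancestral_minor|unpolarized">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    eff <- if ("effect" %in% names(calls)) calls$effect else "undetermined"
    pol <- if ("polarization" %in% names(calls)) calls$polarization else "unpolarized"
    ref <- calls$major_allele
    alt <- calls$minor_allele
    anc_minor <- pol == "ancestral_minor"
    ref[anc_minor] <- calls$minor_allele[anc_minor]
    alt[anc_minor] <- calls$major_allele[anc_minor]
    info <- sprintf("DP=%d;MAF=%.4f;EFFECT=%s;POLARITY=%s",
                    calls$depth, calls$maf, eff, pol)
    writeLines(paste(calls$contig, calls$position, ".", ref, alt, ".",
                     "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}
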