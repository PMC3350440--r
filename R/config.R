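#' Analysis configuration
#'
#' Bundles every threshold the pipeline applies, with defaults matching
#' the published protocol the package re-implements: orthology E-value
#' cut-off 1e-5; SNP calling restricted to coverage 10-150, minor allele
#' frequency strictly above 0.3, contigs longer than 100 nt, with 10 nt
#' trimmed from each contig edge; ORF length threshold derived at
#' significance 0.05 from the 3/64 per-codon stop probability; 20
#' concatenation units.
#'
#' @param evalue_cutoff_orthology E-value cut-off for best hits.
#' @param cov_min,cov_max Inclusive depth window for SNP calling.
#' @param maf_min Minor allele frequency threshold (calls require
#'   MAF strictly greater than this); must lie in (0, 0.5).
#' @param min_contig_len Contigs must be strictly longer than this.
#' @param edge_trim Bases excluded from each contig edge.
#' @param orf_alpha Significance level for the minimum-ORF-length rule.
#' @param n_units Number of concatenation units.
#' @param rng_seed Integer seed recorded in outputs.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(evalue_cutoff_orthology = 1e-5,
                            cov_min = 10L, cov_max = 150L,
                            maf_min = 0.3, min_contig_len = 100L,
                            edge_trim = 10L, orf_alpha = 0.05,
                            n_units = 20L, rng_seed = 1L) {
  cfg <- list(evalue_cutoff_orthology = as.numeric(evalue_cutoff_orthology),
              cov_min = as.integer(cov_min), cov_max = as.integer(cov_max),
              maf_min = as.numeric(maf_min),
              min_contig_len = as.integer(min_contig_len),
              edge_trim = as.integer(edge_trim),
              orf_alpha = as.numeric(orf_alpha),
              n_units = as.integer(n_units),
              rng_seed = as.integer(rng_seed))
  .check_config(cfg)
  structure(cfg, class = c("analysis_config", "list"))
}

.check_config <- function(cfg) {
  with(cfg, {
    if (!(maf_min > 0 && maf_min < 0.5))
      stop("maf_min must lie in (0, 0.5), got ", maf_min)
    if (cov_min > cov_max)
      stop("cov_min (", cov_min, ") must not exceed cov_max (", cov_max, ")")
    if (!(orf_alpha > 0 && orf_alpha < 1))
      stop("orf_alpha must lie in (0, 1)")
    if (evalue_cutoff_orthology < 0) stop("evalue cutoff must be >= 0")
    if (n_units < 1) stop("n_units must be >= 1")
    if (edge_trim < 0 || min_contig_len < 0) stop("negative threshold")
  })
  invisible(cfg)
}

#' Read and validate a configuration file
#'
#' The file is plain `key: value` text (a YAML mapping). Missing keys
#' take the protocol defaults of [analysis_config()]; unknown keys are
#' an error. An empty or absent-key file therefore yields the full
#' default configuration.
#'
#' @param path Config file; `NULL` for pure defaults.
#' @return An [analysis_config()].
#' @export
validate_config <- function(path = NULL) {
  if (is.null(path)) return(analysis_config())
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  ## numeric strings like "1e-5" are accepted
  vals <- lapply(vals, function(v)
    if (is.character(v) && !is.na(suppressWarnings(as.numeric(v))))
      as.numeric(v) else v)
  do.call(analysis_config, vals)
}
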