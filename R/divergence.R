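#' Pairwise proportion of variable sites
#'
#' Columns where either row carries a gap (or `N`) are excluded; the
#' proportion is the number of differing comparable columns over the
#' total comparable columns.
#'
#' @param a,b Equal-length (gapped) sequence rows.
#' @return Proportion in `[0, 1]`.
#' @export
pairwise_variable_sites <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("rows differ in length")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- ca %in% .BASES & cb %in% .BASES
  if (!any(ok)) stop("no comparable (gap-free) columns")
  mean(ca[ok] != cb[ok])
}

#' t-based confidence interval from unit-level estimates
#'
#' The concatenation units play the role of replicates: the interval is
#' mean +/- t(n-1, (1+level)/2) * SE across units.
#'
#' @param values Numeric vector of per-unit estimates (length >= 2).
#' @param level Confidence level (default 0.95).
#' @return List with `mean`, `lo`, `hi`, `se`, `n`.
#' @export
unit_confidence <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 units to form a confidence interval")
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  tq <- stats::qt((1 + level) / 2, df = n - 1)
  list(mean = m, lo = m - tq * se, hi = m + tq * se, se = se, n = n)
}

#' Per-branch distances by star decomposition of pairwise NG86 distances
#'
#' On the three-taxon star topology every pairwise distance is the sum
#' of the two terminal branches, so the branch lengths follow from the
#' three pairwise Nei-Gojobori + Jukes-Cantor distances:
#' `b1 = (d12 + d13 - d23) / 2`, and cyclically. Unlike per-column
#' parsimony assignment ([branch_counts_3taxon()]) this uses every codon
#' including multi-hit columns, and is essentially unbiased at
#' divergences of a few percent up to tens of percent; it is the
#' package's default branch estimator. Negative solved lengths (sampling
#' noise at very low divergence) are clamped to zero.
#'
#' @param aln Named character vector of three equal-length in-frame rows.
#' @param code Genetic code.
#' @return Data.frame with one row per branch: `dn`, `ds`, `omega`.
#' @export
branch_distances_star <- function(aln, code = genetic_code()) {
  stopifnot(length(aln) == 3)
  sp <- names(aln)
  if (is.null(sp)) sp <- paste0("sp", 1:3)
  p12 <- ng86_pairwise(aln[[1]], aln[[2]], code)
  p13 <- ng86_pairwise(aln[[1]], aln[[3]], code)
  p23 <- ng86_pairwise(aln[[2]], aln[[3]], code)
  solve3 <- function(d12, d13, d23)
    pmax(c((d12 + d13 - d23) / 2,
           (d12 + d23 - d13) / 2,
           (d13 + d23 - d12) / 2), 0)
  ds <- solve3(p12$ds, p13$ds, p23$ds)
  dn <- solve3(p12$dn, p13$dn, p23$dn)
  data.frame(branch = sp, dn = dn, ds = ds,
             omega = ifelse(ds > 0, dn / ds, NA_real_))
}

#' Branch-wise divergence estimates over concatenation units
#'
#' Runs the branch estimator on each unit and on the pooled data, and
#' attaches unit-based 95% confidence limits to dN, dS and omega of
#' every branch. The default estimator is [branch_distances_star()]
#' (pairwise NG86 + JC decomposed on the star topology);
#' `method = "parsimony"` switches to the per-column assignment of
#' [branch_counts_3taxon()], which additionally reports raw counts but
#' under-counts multi-hit codons at higher divergence.
#'
#' @param units List of three-row codon alignments (from
#'   [concatenate_units()]).
#' @param code Genetic code.
#' @param level Confidence level.
#' @param method `"decomposition"` (default) or `"parsimony"`.
#' @return Data.frame with one row per branch: point estimates from the
#'   pooled alignment plus `dn_lo/dn_hi`, `ds_lo/ds_hi`,
#'   `omega_lo/omega_hi` across units.
#' @export
branch_estimates <- function(units, code = genetic_code(), level = 0.95,
                             method = c("decomposition", "parsimony")) {
  method <- match.arg(method)
  stopifnot(length(units) >= 2)
  estimator <- if (method == "decomposition") branch_distances_star
               else branch_counts_3taxon
  per_unit <- lapply(units, estimator, code = code)
  pooled_aln <- vapply(names(units[[1]]), function(r)
    paste(vapply(units, `[[`, "", r), collapse = ""), "")
  pooled <- estimator(pooled_aln, code = code)
  ci_of <- function(col, b) unit_confidence(
    vapply(per_unit, function(u) u[[col]][b], 1), level)
  for (col in c("dn", "ds", "omega")) {
    lo <- hi <- numeric(nrow(pooled))
    for (b in seq_len(nrow(pooled))) {
      ci <- ci_of(col, b)
      lo[b] <- ci$lo; hi[b] <- ci$hi
    }
    pooled[[paste0(col, "_lo")]] <- lo
    pooled[[paste0(col, "_hi")]] <- hi
  }
  pooled
}
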