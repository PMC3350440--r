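#' Calibrate a synonymous molecular clock
#'
#' Given the total synonymous path divergence between two calibration
#' taxa and their (independently estimated) split time, the per-branch
#' substitution rate is `(calib_total_ds / 2) / calib_time_years`.
#' For example, a total dS of 2.64 (1.32 on each branch) over a 245
#' million year split yields 5.39e-9 per site per year.
#'
#' @param calib_total_ds Total synonymous divergence along the path
#'   between the two calibration taxa.
#' @param calib_time_years Split time in years.
#' @return List of class `clock_calibration` with `calib_total_ds`,
#'   `calib_time_years`, `rate_per_year`.
#' @export
calibrate_rate <- function(calib_total_ds, calib_time_years) {
  if (!(calib_total_ds > 0 && calib_time_years > 0))
    stop("calibration dS and time must both be positive")
  structure(list(calib_total_ds = calib_total_ds,
                 calib_time_years = calib_time_years,
                 rate_per_year = (calib_total_ds / 2) / calib_time_years),
            class = "clock_calibration")
}

#' Date the splits of the three-taxon star tree
#'
#' Under a molecular clock of synonymous substitutions, the inner pair
#' (species 2 and 3) split at `t_inner = mean(d2, d3) / rate` and the
#' outer species split from their common ancestor at
#' `t_outer = ((d1 + mean(d2, d3)) / 2) / rate` (midpoint rooting of the
#' path from species 1 to the inner pair). Rates are per year; time in
#' generations is obtained through `generations_per_year` (annual
#' species: 1).
#'
#' @param branch_ds Named numeric vector of per-branch synonymous
#'   divergences; the first element is the outer species, the remaining
#'   two the inner pair.
#' @param rate Synonymous substitution rate per site per year (or a
#'   [calibrate_rate()] object).
#' @param generations_per_year Generations per year.
#' @return List with `t_inner_years`, `t_outer_years`,
#'   `t_inner_generations`, `t_outer_generations`.
#' @export
clock_split_times <- function(branch_ds, rate, generations_per_year = 1) {
  if (inherits(rate, "clock_calibration")) rate <- rate$rate_per_year
  if (!(is.numeric(rate) && rate > 0)) stop("rate must be positive")
  stopifnot(length(branch_ds) == 3)
  d1 <- branch_ds[[1]]
  inner <- (branch_ds[[2]] + branch_ds[[3]]) / 2
  t_inner <- inner / rate
  t_outer <- ((d1 + inner) / 2) / rate
  list(t_inner_years = t_inner, t_outer_years = t_outer,
       t_inner_generations = t_inner * generations_per_year,
       t_outer_generations = t_outer * generations_per_year)
}
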