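#' Slope-to-fraction conversions for the dual-label tracer
#'
#' The regression slopes of the labelling experiment convert into source
#' fractions by comparison with the theoretical enrichment of the labelled
#' compound:
#'
#' * `carbon_retention_fraction()`: the slope of excess 13C vs excess 15N
#'   (both molar) divided by the source's all-carbon-retained molar excess
#'   ratio ([molar_excess_ratio()], 2.5 for glutamine) gives the fraction of
#'   source-derived carbon retained in biomass; its complement is lost by
#'   respiration.
#' * `n_fraction_from_source()`: the slope of excess 15N vs total N divided
#'   by the source 15N enrichment (`excess_15n/100`, 0.10 at 10 atom%
#'   excess) gives the fraction of tissue N acquired from the source.
#'
#' @param slope Regression slope (dimensionless; both axes in the same
#'   basis).
#' @param source A [labelled_source()].
#' @param tolerance Fractions above `1 + tolerance` (i.e. >100% retention /
#'   >100% N from source) trigger a warning — they indicate an inconsistent
#'   background or basis, and are returned unclipped.
#' @return A fraction in `[0, 1]` (possibly above 1, with a warning).
#' @export
carbon_retention_fraction <- function(slope, source = glutamine_source(),
                                      tolerance = 0.02) {
  stopifnot(all(slope >= 0))
  frac <- slope / molar_excess_ratio(source)
  if (any(frac > 1 + tolerance)) {
    warning("slope implies >100% retention of source-derived C", call. = FALSE)
  }
  frac
}

#' @rdname carbon_retention_fraction
#' @export
n_fraction_from_source <- function(slope, source = glutamine_source(),
                                   tolerance = 0.02) {
  stopifnot(all(slope >= 0))
  frac <- slope / (source$excess_15n / 100)
  if (any(frac > 1 + tolerance)) {
    warning("slope implies >100% of N from source", call. = FALSE)
  }
  frac
}

#' Source-derived carbon as a concentration and as a share of tissue C
#'
#' `source_c_conc_pct_dw()` estimates the concentration of tissue carbon
#' derived from the labelled source, as the product of tissue N
#' concentration (% DW) and the excess-13C vs excess-15N regression slope.
#' The default `"literal"` mode takes the plain product of the %DW nitrogen
#' concentration with the molar slope. A `"strict"` mode additionally
#' applies the C/N atomic-mass factor (12.011/14.007) that converts a molar
#' slope to a mass ratio; the two differ by about 14%.
#'
#' `source_c_share()` expresses that concentration as a percentage of total
#' tissue carbon, using the unrounded source-derived concentration.
#'
#' @param n_conc Tissue N concentration, % of dry weight.
#' @param slope Excess-13C vs excess-15N regression slope (molar).
#' @param mode `"literal"` (plain product) or `"strict"` (mass-basis).
#' @return % of dry weight (`source_c_conc_pct_dw`) or % of tissue C
#'   (`source_c_share`).
#' @export
source_c_conc_pct_dw <- function(n_conc, slope, mode = c("literal", "strict")) {
  mode <- match.arg(mode)
  stopifnot(all(n_conc >= 0), all(slope >= 0))
  out <- n_conc * slope
  if (mode == "strict") out <- out * ATOMIC_MASS_C / ATOMIC_MASS_N
  out
}

#' @rdname source_c_conc_pct_dw
#' @param source_c Source-derived C concentration, % DW (unrounded).
#' @param total_c Total tissue C concentration, % DW.
#' @export
source_c_share <- function(source_c, total_c) {
  if (any(total_c <= 0)) stop("total_c must be positive", call. = FALSE)
  if (any(source_c > total_c)) {
    warning("source-derived C exceeds total C", call. = FALSE)
  }
  100 * source_c / total_c
}
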