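#' Carbon assimilation cost parameters
#'
#' The carbon-use-efficiency model prices biomass growth with three costs:
#' `c_c`, the growth respiration per unit biomass C (g C per g C, fixed at
#' 0.2 by assumption — it must lie below the ~0.43 whole-cost estimate that
#' includes N assimilation); `on_c`, the C cost per g N assimilated from the
#' organic source (glutamine); and `in_c`, per g N from the inorganic source
#' (nitrate). Defaults for `on_c`/`in_c` are the fitted values 2.63 and
#' 4.56 g C per g N.
#'
#' @param c_c,on_c,in_c Non-negative costs (see above).
#' @return A `cost_params` list.
#' @export
cost_params <- function(c_c = 0.2, on_c = 2.63, in_c = 4.56) {
  stopifnot(c_c >= 0, on_c >= 0, in_c >= 0)
  structure(list(c_c = c_c, on_c = on_c, in_c = in_c), class = "cost_params")
}

#' Observed carbon use efficiency from biomass isotope excess
#'
#' CUE is the fraction of carbon taken up that remains in biomass. Assuming
#' all N taken up stays in the biomass, the biomass excess 13C : 15N molar
#' ratio, normalized by the same ratio in the labelled source
#' ([molar_excess_ratio()]), observes the fraction of source-derived C
#' retained — the observed CUE.
#'
#' @param excess_13c_umol,excess_15n_umol Plant-level molar excess contents
#'   (any common unit).
#' @param source A [labelled_source()].
#' @return Observed CUE (vectorized); `NA` with a warning where the 15N
#'   excess is not positive.
#' @export
observed_cue <- function(excess_13c_umol, excess_15n_umol,
                         source = glutamine_source()) {
  bad <- !is.finite(excess_15n_umol) | excess_15n_umol <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive excess 15N: CUE undefined",
            call. = FALSE)
  }
  out <- (excess_13c_umol / excess_15n_umol) / molar_excess_ratio(source)
  out[bad] <- NA_real_
  out
}

#' Modelled carbon use efficiency from assimilation costs
#'
#' The cost model: of the carbon taken up, `c_b` ends up in biomass and the
#' rest is respired in assimilation, so
#' `CUE_m = c_b / (c_c*c_b + on_c*on_b + in_c*in_b + c_b)`,
#' where `on_b`/`in_b` are the masses of biomass N assimilated from the
#' organic and inorganic source. CUE_m lies in (0, 1], equals
#' `1/(1 + c_c)` when no N cost is paid, and decreases in every cost and
#' every N amount.
#'
#' @param c_b New biomass C (g), > 0.
#' @param on_b,in_b Biomass N from the organic / inorganic source (g), >= 0.
#' @param params A [cost_params()].
#' @return Modelled CUE (vectorized).
#' @export
modelled_cue <- function(c_b, on_b, in_b, params = cost_params()) {
  stopifnot(inherits(params, "cost_params"),
            all(c_b > 0), all(on_b >= 0), all(in_b >= 0))
  c_b / (params$c_c * c_b + params$on_c * on_b + params$in_c * in_b + c_b)
}
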