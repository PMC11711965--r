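#' Per-plant carbon and nitrogen budgets for the cost fit
#'
#' Builds, for every labelled plant (shoot + root records), the quantities
#' entering the CUE cost model:
#'
#' * `on_b_g` — biomass N from the organic source: total excess 15N mass
#'   divided by the source enrichment (`excess_15n/100`);
#' * `in_b_g` — biomass N from the inorganic source: the N increment over
#'   the day-0 baseline not accounted for by `on_b` (exactly 0 for
#'   glutamine-only plants, whose only N source is the tracer);
#' * `c_b_g` — new biomass C: the C increment over the baseline;
#' * `c_u_g` — C taken up with the organic N: `on_b` times the source's
#'   g C per g N ratio;
#' * `cue_obs` — observed CUE ([observed_cue()]) from the plant-summed
#'   molar excess contents;
#' * `root_mass_mg` — harvested root dry mass.
#'
#' Increments are taken against the mean initial C and N mass per organ of
#' a day-0 cohort; negative increments (plants smaller than the baseline
#' mean) are floored at 0 with a warning.
#'
#' @param samples Labelled-plant measurement table (treatments `gln_only` /
#'   `mixed`), one shoot and one root row per `sample_id`.
#' @param controls Unlabelled control measurements for background
#'   correction (may be `NULL`: natural-abundance fallback).
#' @param baseline Day-0 cohort summary: tibble with columns `treatment`,
#'   `organ`, `n_mass_g`, `c_mass_g` (mean initial masses), as produced by
#'   [generate_baseline()].
#' @param source A [labelled_source()].
#' @param pool_controls Passed to [excess_atom_fractions()].
#' @return Tibble with one row per plant: `plant_id`, `treatment`, `day`,
#'   `c_b_g`, `on_b_g`, `in_b_g`, `c_u_g`, `cue_obs`, `root_mass_mg`.
#' @export
build_budgets <- function(samples, controls = NULL, baseline,
                          source = glutamine_source(),
                          pool_controls = FALSE) {
  samples <- validate_measurements(samples)
  samples <- dplyr::filter(samples, .data$treatment %in% c("gln_only", "mixed"))
  if (nrow(samples) == 0) stop("no labelled samples", call. = FALSE)
  stopifnot(all(c("treatment", "organ", "n_mass_g", "c_mass_g") %in%
                  names(baseline)))

  organ_n <- samples |>
    dplyr::count(.data$sample_id) |>
    dplyr::filter(.data$n != 2L)
  if (nrow(organ_n) > 0) {
    stop("plants without exactly one shoot and one root record: ",
         paste(head(organ_n$sample_id, 5), collapse = ", "), call. = FALSE)
  }

  ex <- excess_atom_fractions(samples, controls, pool_controls = pool_controls)
  ex <- excess_content(ex)
  ex <- dplyr::mutate(
    ex,
    n_mass_g = .data$dry_mass_mg / 1000 * .data$n_conc_pct_dw / 100,
    c_mass_g = .data$dry_mass_mg / 1000 * .data$c_conc_pct_dw / 100,
    excess_15n_mass_g = .data$excess_frac_15n * .data$n_mass_g
  )

  base <- baseline |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(n0_g = sum(.data$n_mass_g), c0_g = sum(.data$c_mass_g),
                     .groups = "drop")
  if (!all(unique(ex$treatment) %in% base$treatment)) {
    stop("baseline missing treatment(s): ",
         paste(setdiff(unique(ex$treatment), base$treatment), collapse = ", "),
         call. = FALSE)
  }

  per_plant <- ex |>
    dplyr::group_by(.data$sample_id, .data$treatment, .data$day) |>
    dplyr::summarise(
      n_mass_g = sum(.data$n_mass_g),
      c_mass_g = sum(.data$c_mass_g),
      excess_15n_mass_g = sum(.data$excess_15n_mass_g),
      excess_13c_umol = sum(.data$excess_13c_umol),
      excess_15n_umol = sum(.data$excess_15n_umol),
      root_mass_mg = .data$dry_mass_mg[.data$organ == "root"],
      .groups = "drop"
    ) |>
    dplyr::left_join(base, by = "treatment")

  out <- per_plant |>
    dplyr::mutate(
      on_b_g = pmax(0, .data$excess_15n_mass_g / (source$excess_15n / 100)),
      c_b_raw = .data$c_mass_g - .data$c0_g,
      in_b_raw = .data$n_mass_g - .data$n0_g - .data$on_b_g,
      c_b_g = pmax(0, .data$c_b_raw),
      in_b_g = ifelse(.data$treatment == "gln_only", 0,
                      pmax(0, .data$in_b_raw)),
      c_u_g = .data$on_b_g * source$c_mass_per_n_mass,
      cue_obs = observed_cue(.data$excess_13c_umol, .data$excess_15n_umol,
                             source)
    )

  n_floored <- sum(out$c_b_raw < 0) +
    sum(out$in_b_raw < 0 & out$treatment != "gln_only")
  if (n_floored > 0) {
    warning(n_floored,
            " negative baseline-subtracted increment(s) floored at 0",
            call. = FALSE)
  }

  out |>
    dplyr::transmute(
      plant_id = .data$sample_id, .data$treatment, .data$day,
      .data$c_b_g, .data$on_b_g, .data$in_b_g, .data$c_u_g,
      .data$cue_obs, .data$root_mass_mg
    )
}
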