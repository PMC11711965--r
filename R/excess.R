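#' Background-correct atom% to excess atom fractions
#'
#' Converts measured atom% 13C and 15N into excess atom fractions by
#' subtracting the background abundance. The background is, per sample, the
#' mean atom% of the matched unlabelled control cohort (same control
#' treatment, organ and day) — this is what corrects for photosynthetic
#' re-fixation of respired 13CO2, which inflates 13C in labelled and control
#' plants alike. If no control table is supplied, fixed natural-abundance
#' constants (1.1078 atom% 13C, 0.3663 atom% 15N) are used and
#' `background_source` records the fallback.
#'
#' @param samples Measurement table ([measurement-schema]).
#' @param controls Optional measurement table of unlabelled control plants
#'   (treatments `control_gln_only` / `control_mixed`).
#' @param pool_controls If `TRUE`, controls are pooled across organ and day
#'   within each control treatment. By default a sample whose organ/day has
#'   no matched control is an error, not silently corrected against a
#'   mismatched background.
#' @param floor_frac Excess fractions below this value (default -1e-4, i.e.
#'   -0.01 atom%) are flagged in `below_floor`; negative values are kept,
#'   not clipped, since clipping would bias regressions near the origin.
#'
#' @return The sample table with columns `excess_frac_13c`,
#'   `excess_frac_15n` (atom fractions, atom%/100), `background_source`
#'   (`"matched_controls"` or `"natural_abundance"`) and `below_floor`.
#' @export
excess_atom_fractions <- function(samples, controls = NULL,
                                  pool_controls = FALSE,
                                  floor_frac = -1e-4) {
  samples <- validate_measurements(samples)
  have_controls <- !is.null(controls) && nrow(controls) > 0
  if (!have_controls) {
    out <- dplyr::mutate(
      samples,
      excess_frac_13c = (.data$atom_pct_13c - NAT_ABUND_13C) / 100,
      excess_frac_15n = (.data$atom_pct_15n - NAT_ABUND_15N) / 100,
      background_source = "natural_abundance"
    )
  } else {
    controls <- validate_measurements(controls)
    key <- if (pool_controls) "treatment" else c("treatment", "organ", "day")
    bg <- controls |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
      dplyr::summarise(
        bg_13c = mean(.data$atom_pct_13c),
        bg_15n = mean(.data$atom_pct_15n),
        .groups = "drop"
      ) |>
      dplyr::rename(control_treatment = "treatment")
    out <- samples |>
      dplyr::mutate(control_treatment = control_treatment_for(.data$treatment)) |>
      dplyr::left_join(bg, by = if (pool_controls) "control_treatment" else
        c("control_treatment", "organ", "day"))
    if (anyNA(out$bg_13c)) {
      miss <- dplyr::filter(out, is.na(.data$bg_13c))
      stop("no matched control background (treatment/organ/day) for sample(s): ",
           paste(head(miss$sample_id, 5), collapse = ", "),
           "; supply matched controls or set pool_controls = TRUE",
           call. = FALSE)
    }
    out <- out |>
      dplyr::mutate(
        excess_frac_13c = (.data$atom_pct_13c - .data$bg_13c) / 100,
        excess_frac_15n = (.data$atom_pct_15n - .data$bg_15n) / 100,
        background_source = "matched_controls"
      ) |>
      dplyr::select(-"control_treatment", -"bg_13c", -"bg_15n")
  }
  dplyr::mutate(
    out,
    below_floor = .data$excess_frac_13c < floor_frac |
      .data$excess_frac_15n < floor_frac
  )
}

#' Excess isotope contents in micromoles
#'
#' Converts excess atom fractions into molar excess contents:
#' `excess_umol = excess_fraction * (dry_mass_mg * conc/100) / atomic_mass * 1000`,
#' i.e. the excess fraction applied to the organ's elemental pool in umol.
#' The molar basis is canonical here: it makes the all-carbon-retained slope
#' of excess 13C vs excess 15N equal the labelled source's molar excess
#' ratio (2.5 for uniformly labelled glutamine).
#'
#' @param samples_ex Output of [excess_atom_fractions()].
#' @return The table with columns `excess_13c_umol` and `excess_15n_umol`
#'   added.
#' @export
excess_content <- function(samples_ex) {
  stopifnot(all(c("excess_frac_13c", "excess_frac_15n") %in% names(samples_ex)))
  if (any(samples_ex$dry_mass_mg <= 0 | samples_ex$c_conc_pct_dw <= 0 |
            samples_ex$n_conc_pct_dw <= 0)) {
    stop("non-positive dry mass or concentration", call. = FALSE)
  }
  dplyr::mutate(
    samples_ex,
    excess_13c_umol = .data$excess_frac_13c *
      (.data$dry_mass_mg * .data$c_conc_pct_dw / 100) / ATOMIC_MASS_C * 1000,
    excess_15n_umol = .data$excess_frac_15n *
      (.data$dry_mass_mg * .data$n_conc_pct_dw / 100) / ATOMIC_MASS_N * 1000
  )
}
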