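#' Tracer regression tables
#'
#' `fig_regressions()` fits, per labelled treatment and organ (plus a
#' whole-plant aggregate summing organs within plants), the regression of
#' molar excess 13C on excess 15N content, and converts each slope into the
#' percentage of glutamine-derived C retained via
#' [carbon_retention_fraction()].
#'
#' `n_source_regressions()` fits excess 15N mass against total N mass per
#' treatment and organ and converts each slope into the fraction of tissue
#' N derived from the labelled source via [n_fraction_from_source()].
#'
#' @param excess_tbl Output of [excess_content()] (labelled samples).
#' @param source A [labelled_source()].
#' @return A tibble with one row per group: slope, intercept, `r_squared`,
#'   `slope_se`, `n`, and the derived fraction / reported percentage.
#' @export
fig_regressions <- function(excess_tbl, source = glutamine_source()) {
  lab <- dplyr::filter(excess_tbl,
                       .data$treatment %in% c("gln_only", "mixed"))
  whole <- lab |>
    dplyr::group_by(.data$sample_id, .data$treatment, .data$day) |>
    dplyr::summarise(excess_13c_umol = sum(.data$excess_13c_umol),
                     excess_15n_umol = sum(.data$excess_15n_umol),
                     .groups = "drop") |>
    dplyr::mutate(organ = "whole_plant")
  groups <- dplyr::bind_rows(
    dplyr::select(lab, "treatment", "organ",
                  "excess_13c_umol", "excess_15n_umol"),
    dplyr::select(whole, "treatment", "organ",
                  "excess_13c_umol", "excess_15n_umol")
  )
  groups |>
    dplyr::group_by(.data$treatment, .data$organ) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_line(d$excess_15n_umol, d$excess_13c_umol)
      frac <- carbon_retention_fraction(max(0, f$slope), source)
      tibble::tibble(
        slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
        slope_se = f$slope_se, n = f$n,
        retention_fraction = frac,
        retention_pct_reported = round(100 * frac)
      )
    }) |>
    dplyr::ungroup()
}

#' @rdname fig_regressions
#' @param samples_ex Output of [excess_atom_fractions()] (labelled samples).
#' @export
n_source_regressions <- function(samples_ex, source = glutamine_source()) {
  lab <- samples_ex |>
    dplyr::filter(.data$treatment %in% c("gln_only", "mixed")) |>
    dplyr::mutate(
      n_mass_mg = .data$dry_mass_mg * .data$n_conc_pct_dw / 100,
      excess_15n_mass_mg = .data$excess_frac_15n * .data$n_mass_mg
    )
  lab |>
    dplyr::group_by(.data$treatment, .data$organ) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_line(d$n_mass_mg, d$excess_15n_mass_mg)
      frac <- n_fraction_from_source(max(0, f$slope), source)
      tibble::tibble(
        slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
        slope_se = f$slope_se, n = f$n,
        n_fraction_from_source = frac
      )
    }) |>
    dplyr::ungroup()
}

#' Group summaries (mean +/- SE)
#'
#' Per-group n, mean and standard error of every numeric measurement
#' column, in long form. Groups of size 1 report `NA` standard error and
#' are flagged.
#'
#' @param samples A measurement (or any) tibble.
#' @param by Grouping columns.
#' @param cols Numeric columns to summarise (default: all numeric columns
#'   not used for grouping).
#' @return Long tibble: grouping columns, `variable`, `n`, `mean`, `se`,
#'   `se_missing`.
#' @export
group_summary <- function(samples, by = c("treatment", "organ", "day"),
                          cols = NULL) {
  x <- tibble::as_tibble(samples)
  stopifnot(all(by %in% names(x)))
  if (is.null(cols)) {
    cols <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], by)
  }
  x |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "variable") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "variable")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(se_missing = is.na(.data$se))
}

#' Run the full tracer analysis pipeline
#'
#' Orchestrates simulate (optional) -> background correction -> excess
#' contents -> tracer regressions -> budgets -> cost fit -> uptake ratio,
#' and optionally writes every table (plus a provenance file echoing the
#' configuration and package version) to an output directory. Given the
#' same inputs/config and seed the outputs are byte-identical.
#'
#' @param measurements Labelled + control measurement table; if `NULL`, a
#'   synthetic experiment is generated from `config`.
#' @param baseline Day-0 baseline summary; if `NULL` and simulating, one is
#'   generated from `config`.
#' @param config A [sim_config()] (used when simulating; its `source` and
#'   `seed` also drive the analysis).
#' @param mode `"literal"` or `"strict"` concentration arithmetic (see
#'   [source_c_conc_pct_dw()]); echoed into provenance and used for the
#'   source-C concentration table.
#' @param n_boot Bootstrap draws for the uptake ratio.
#' @param out_dir Optional output directory for CSV tables.
#' @return Invisible list of tables: `excess`, `regressions`, `n_source`,
#'   `budgets`, `cost_fit` (tibble, both fit scopes), `uptake`,
#'   `summaries`, plus `truth` when simulated.
#' @export
run_pipeline <- function(measurements = NULL, baseline = NULL,
                         config = sim_config(), mode = c("literal", "strict"),
                         n_boot = 1000, out_dir = NULL) {
  mode <- match.arg(mode)
  truth <- NULL
  if (is.null(measurements)) {
    sim <- generate_experiment2(config)
    measurements <- sim$measurements
    truth <- sim$truth
    if (is.null(baseline)) baseline <- generate_baseline(config)
  }
  measurements <- validate_measurements(measurements)
  if (is.null(baseline)) stop("baseline summary required", call. = FALSE)
  source <- config$source

  is_control <- measurements$treatment %in% c("control_gln_only",
                                              "control_mixed")
  controls <- measurements[is_control, ]
  labelled <- measurements[!is_control, ]
  if (nrow(controls) == 0) controls <- NULL

  ex <- excess_atom_fractions(labelled, controls)
  exc <- excess_content(ex)
  regressions <- fig_regressions(exc, source)
  n_source <- n_source_regressions(ex, source)
  budgets <- build_budgets(labelled, controls, baseline, source)
  fits <- lapply(c("all_days", "final_day"), function(sc) {
    f <- estimate_costs(budgets, c_c = config$true_costs$c_c, fit_scope = sc)
    tibble::tibble(
      fit_scope = sc, c_c_assumed = f$c_c_assumed,
      on_c_hat = f$on_c_hat, on_c_se = f$on_c_se,
      in_c_hat = f$in_c_hat, in_c_se = f$in_c_se,
      r_squared_model_vs_obs = f$r_squared_model_vs_obs,
      n_plants = f$n_plants
    )
  })
  cost_fit <- dplyr::bind_rows(fits)
  uptake <- uptake_per_root_mass(budgets, n_boot = n_boot,
                                 seed = config$seed + 2000029L)
  uptake_tbl <- tibble::tibble(
    ratio_mixed_over_gln = uptake$ratio,
    ci_lower = uptake$ci[1], ci_upper = uptake$ci[2], n_boot = uptake$n_boot
  )
  summaries <- group_summary(measurements)

  # glutamine-derived C as %DW and as share of tissue C, per group mean
  conc <- group_summary(labelled, by = c("treatment", "organ"),
                        cols = c("n_conc_pct_dw", "c_conc_pct_dw")) |>
    dplyr::select("treatment", "organ", "variable", "mean") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "mean") |>
    dplyr::inner_join(
      dplyr::filter(regressions, .data$organ != "whole_plant") |>
        dplyr::select("treatment", "organ", "slope"),
      by = c("treatment", "organ")
    ) |>
    dplyr::mutate(
      source_c_pct_dw = source_c_conc_pct_dw(.data$n_conc_pct_dw,
                                             .data$slope, mode = mode),
      source_c_pct_of_c = source_c_share(.data$source_c_pct_dw,
                                         .data$c_conc_pct_dw)
    )

  tables <- list(excess = exc, regressions = regressions,
                 n_source = n_source, budgets = budgets,
                 cost_fit = cost_fit, uptake = uptake_tbl,
                 source_c = conc, summaries = summaries, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("excess", "regressions", "n_source", "budgets",
                 "cost_fit", "uptake", "source_c", "summaries")) {
      readr::write_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
    }
    prov <- c(
      sprintf("glntrace %s", as.character(utils::packageVersion("glntrace"))),
      sprintf("mode: %s", mode),
      sprintf("seed: %d", config$seed),
      sprintf("n_boot: %d", n_boot),
      sprintf("source: %s (C%g N%g, %g/%g atom%% excess)", source$name,
              source$n_carbon, source$n_nitrogen, source$excess_13c,
              source$excess_15n),
      sprintf("config: n_gln=%d n_mixed=%d n_control=%d days=%s cv=%g",
              config$n_gln, config$n_mixed, config$n_control,
              paste(config$harvest_days, collapse = ","),
              config$measurement_cv)
    )
    writeLines(prov, file.path(out_dir, "run_info.txt"))
  }
  invisible(tables)
}
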