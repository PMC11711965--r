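#' Tissue measurement table schema
#'
#' One row per organ of one plant at one harvest. Columns:
#' `sample_id` (plant identifier, shared between a plant's shoot and root
#' rows), `treatment` (one of `gln_only`, `mixed`, `control_gln_only`,
#' `control_mixed`), `organ` (`shoot` or `root`), `day` (harvest day; 0
#' allowed for a baseline cohort), `dry_mass_mg`, `c_conc_pct_dw`,
#' `n_conc_pct_dw` (elemental concentrations in % of dry weight) and the
#' measured isotope abundances `atom_pct_13c`, `atom_pct_15n` (atom%).
#'
#' @name measurement-schema
NULL

MEASUREMENT_COLS <- c(
  "sample_id", "treatment", "organ", "day", "dry_mass_mg",
  "c_conc_pct_dw", "n_conc_pct_dw", "atom_pct_13c", "atom_pct_15n"
)

TREATMENT_LEVELS <- c("gln_only", "mixed", "control_gln_only", "control_mixed")
ORGAN_LEVELS <- c("shoot", "root")

# labelled treatment -> unlabelled control cohort grown alongside it
control_treatment_for <- function(treatment) {
  unname(c(gln_only = "control_gln_only", mixed = "control_mixed",
           control_gln_only = "control_gln_only",
           control_mixed = "control_mixed")[treatment])
}

#' Validate a tissue measurement table
#'
#' Checks the column set, enum levels and physical ranges of the
#' measurement schema (see [measurement-schema]). Violations are reported
#' with offending row numbers.
#'
#' @param x A data frame of tissue measurements.
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_measurements <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(MEASUREMENT_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop("measurement table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_rows <- function(ok, what) {
    if (any(!ok)) {
      stop(sprintf("invalid %s in rows: %s", what,
                   paste(head(which(!ok), 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_rows(x$treatment %in% TREATMENT_LEVELS, "treatment")
  bad_rows(x$organ %in% ORGAN_LEVELS, "organ")
  bad_rows(is.finite(x$day) & x$day >= 0, "day")
  bad_rows(is.finite(x$dry_mass_mg) & x$dry_mass_mg > 0, "dry_mass_mg")
  bad_rows(is.finite(x$c_conc_pct_dw) & x$c_conc_pct_dw > 0 &
             x$c_conc_pct_dw < 100, "c_conc_pct_dw")
  bad_rows(is.finite(x$n_conc_pct_dw) & x$n_conc_pct_dw > 0 &
             x$n_conc_pct_dw < 100, "n_conc_pct_dw")
  bad_rows(is.finite(x$atom_pct_13c) & x$atom_pct_13c > 0 &
             x$atom_pct_13c < 100, "atom_pct_13c")
  bad_rows(is.finite(x$atom_pct_15n) & x$atom_pct_15n > 0 &
             x$atom_pct_15n < 100, "atom_pct_15n")
  x
}

#' Read / write tissue measurements as CSV
#'
#' The on-disk form is a plain comma-separated, "." decimal, UTF-8 table
#' with a header row, columns as in [measurement-schema].
#'
#' @param path File path.
#' @return `read_tissue_csv()` returns a validated tibble.
#' @export
read_tissue_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_measurements(x)
}

#' @rdname read_tissue_csv
#' @param x A measurement table.
#' @export
write_tissue_csv <- function(x, path) {
  readr::write_csv(validate_measurements(x), path, progress = FALSE)
  invisible(path)
}
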