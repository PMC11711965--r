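meas_row <- function(sample_id = "s1", treatment = "gln_only",
                     organ = "shoot", day = 3, dry_mass_mg = 10,
                     c_conc_pct_dw = 40, n_conc_pct_dw = 5,
                     atom_pct_13c = 1.9078, atom_pct_15n = 0.3663) {
  tibble::tibble(sample_id, treatment, organ, day, dry_mass_mg,
                 c_conc_pct_dw, n_conc_pct_dw, atom_pct_13c, atom_pct_15n)
}

test_that("background correction subtracts matched control means", {
  sample <- meas_row(atom_pct_13c = 1.9078)
  controls <- dplyr::bind_rows(
    meas_row("c1", "control_gln_only", atom_pct_13c = 1.1000),
    meas_row("c2", "control_gln_only", atom_pct_13c = 1.1156)
  )
  ex <- excess_atom_fractions(sample, controls)
  expect_equal(ex$excess_frac_13c, (1.9078 - 1.1078) / 100)
  expect_equal(ex$background_source, "matched_controls")

  # a control cohort corrected against its own mean centres on zero
  exc <- excess_atom_fractions(controls, controls)
  expect_equal(mean(exc$excess_frac_13c), 0)
  expect_equal(mean(exc$excess_frac_15n), 0)
})

test_that("natural-abundance fallback is used when controls are absent", {
  ex <- excess_atom_fractions(meas_row(atom_pct_13c = 1.9078,
                                       atom_pct_15n = 0.4663))
  expect_equal(ex$background_source, "natural_abundance")
  expect_equal(ex$excess_frac_13c, 0.008)
  expect_equal(ex$excess_frac_15n, 0.001)
})

test_that("organ/day-mismatched controls are rejected unless pooled", {
  sample <- meas_row(organ = "root", day = 6)
  controls <- meas_row("c1", "control_gln_only", organ = "shoot", day = 1)
  expect_error(excess_atom_fractions(sample, controls), "matched control")
  ex <- excess_atom_fractions(sample, controls, pool_controls = TRUE)
  expect_equal(ex$background_source, "matched_controls")
})

test_that("generator round-trip: known excess recovered exactly without noise", {
  # one organ pool with 0.5 atom% excess over zero-noise controls
  sample <- meas_row(atom_pct_13c = 1.1078 + 0.5)
  controls <- meas_row("c1", "control_gln_only", atom_pct_13c = 1.1078)
  ex <- excess_atom_fractions(sample, controls)
  expect_equal(ex$excess_frac_13c, 0.005)
})

test_that("excess contents are molar, linear in mass and zero at zero excess", {
  base <- meas_row(dry_mass_mg = 10, c_conc_pct_dw = 40)
  ex <- excess_atom_fractions(base)
  ex$excess_frac_13c <- 0.005
  out <- excess_content(ex)
  # 10 mg DW x 40% C = 4 mg C = 333.0 umol C; x 0.005 = 1.665 umol
  expect_equal(out$excess_13c_umol, 0.005 * 4 / 12.011 * 1000,
               tolerance = 1e-12)
  expect_equal(round(out$excess_13c_umol, 3), 1.665)

  ex2 <- ex; ex2$dry_mass_mg <- 20
  expect_equal(excess_content(ex2)$excess_13c_umol,
               2 * out$excess_13c_umol)

  ex0 <- ex; ex0$excess_frac_13c <- 0
  expect_equal(excess_content(ex0)$excess_13c_umol, 0)
})

test_that("excess contents are additive over pooled samples", {
  m <- dplyr::bind_rows(
    meas_row("a", organ = "shoot", atom_pct_13c = 2.1, dry_mass_mg = 8),
    meas_row("a", organ = "root", atom_pct_13c = 1.6, dry_mass_mg = 3)
  )
  out <- excess_content(excess_atom_fractions(m))
  pooled_mass_c <- sum(m$dry_mass_mg * m$c_conc_pct_dw / 100)
  pooled_frac <- sum(out$excess_frac_13c * m$dry_mass_mg *
                       m$c_conc_pct_dw / 100) / pooled_mass_c
  expect_equal(sum(out$excess_13c_umol),
               pooled_frac * pooled_mass_c / 12.011 * 1000)
})

test_that("fit_line reproduces exact lines and rejects degenerate input", {
  x <- c(0, 1, 2, 3)
  f <- fit_line(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_error(fit_line(rep(1, 5), 1:5), "degenerate")
  expect_error(fit_line(1:2, 1:2, with_intercept = TRUE), "at least 3")
  expect_equal(fit_line(1:2, c(2, 4), with_intercept = FALSE)$slope, 2)
})

test_that("fit_line agrees with the normal-equations oracle", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    x <- rnorm(n)
    y <- rnorm(n, 2 * x)
    for (ic in c(TRUE, FALSE)) {
      f <- fit_line(x, y, with_intercept = ic)
      o <- ols_oracle(x, y, with_intercept = ic)
      expect_equal(f$slope, o$slope, tolerance = 1e-10)
      expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
      expect_equal(f$slope_se, o$slope_se, tolerance = 1e-10)
      expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
    }
  }
})

test_that("slope-to-retention conversion matches the published worked numbers", {
  gln <- glutamine_source()
  expect_equal(round(100 * carbon_retention_fraction(1.017, gln)), 41)
  expect_equal(round(100 * carbon_retention_fraction(1.075, gln)), 43)
  expect_equal(carbon_retention_fraction(2.5, gln), 1)
  # linear in slope
  s <- c(0.5, 1, 1.5)
  expect_equal(carbon_retention_fraction(s, gln), s / 2.5)
  expect_warning(carbon_retention_fraction(2.6, gln), ">100%")
})

test_that("excess-15N slope converts to the fraction of N from the source", {
  gln <- glutamine_source()
  expect_equal(n_fraction_from_source(0.06, gln), 0.60)
  expect_equal(n_fraction_from_source(0.08, gln), 0.80)
  expect_equal(n_fraction_from_source(0.10, gln), 1.0)
  expect_warning(n_fraction_from_source(0.11, gln), ">100%")
})

test_that("source-derived C concentration and share reproduce worked numbers", {
  # shoots: 6.62 %DW N x slope 1.017 -> 6.7 %DW; 17.2% of 39.23 %DW C
  shoot_c <- source_c_conc_pct_dw(6.62, 1.017)
  expect_equal(round(shoot_c, 1), 6.7)
  expect_equal(round(source_c_share(shoot_c, 39.23), 1), 17.2)
  # roots: 3.14 x 1.075 -> 3.4 %DW; 8.4% of 40.24
  root_c <- source_c_conc_pct_dw(3.14, 1.075)
  expect_equal(round(root_c, 1), 3.4)
  expect_equal(round(source_c_share(root_c, 40.24), 1), 8.4)
  # strict mode applies the molar->mass factor
  expect_equal(source_c_conc_pct_dw(6.62, 1.017, mode = "strict"),
               6.62 * 1.017 * 12.011 / 14.007)
  expect_equal(source_c_conc_pct_dw(0, 1.017), 0)
  expect_equal(source_c_share(40, 40), 100)
  expect_error(source_c_share(5, 0), "positive")
})
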