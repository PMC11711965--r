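test_that("observed CUE normalizes the biomass excess ratio by the source ratio", {
  gln <- glutamine_source()
  expect_equal(observed_cue(2.5, 1, gln), 1)       # no C lost
  expect_equal(observed_cue(1.02, 1, gln), 0.408)  # published shoot regime
  expect_warning(out <- observed_cue(1, 0, gln), "non-positive")
  expect_true(is.na(out))
})

test_that("modelled CUE follows the cost model and its limits", {
  expect_equal(modelled_cue(1, 0, 0, cost_params(c_c = 0.2)), 1 / 1.2)
  expect_equal(
    modelled_cue(1, 0.1, 0, cost_params(c_c = 0.2, on_c = 2.63)),
    1 / (0.2 + 0.263 + 1)
  )
  # strictly decreasing in every cost and every N amount
  base <- modelled_cue(1, 0.1, 0.05, cost_params(0.2, 2.63, 4.56))
  expect_lt(modelled_cue(1, 0.1, 0.05, cost_params(0.3, 2.63, 4.56)), base)
  expect_lt(modelled_cue(1, 0.1, 0.05, cost_params(0.2, 3.0, 4.56)), base)
  expect_lt(modelled_cue(1, 0.1, 0.05, cost_params(0.2, 2.63, 5.0)), base)
  expect_lt(modelled_cue(1, 0.15, 0.05, cost_params(0.2, 2.63, 4.56)), base)
  expect_lt(modelled_cue(1, 0.1, 0.08, cost_params(0.2, 2.63, 4.56)), base)
  # bounded in (0, 1]
  set.seed(1)
  cue <- modelled_cue(runif(50, 0.1, 5), runif(50, 0, 1), runif(50, 0, 1))
  expect_true(all(cue > 0 & cue <= 1))
})

test_that("with cheaper organic N, gln-only CUE beats matched mixed-N CUE", {
  p <- cost_params(c_c = 0.2, on_c = 2.63, in_c = 4.56)
  c_b <- 1; n_tot <- 0.12
  expect_gt(modelled_cue(c_b, n_tot, 0, p),
            modelled_cue(c_b, n_tot / 2, n_tot / 2, p))
})

test_that("estimate_costs exactly inverts the forward model without noise", {
  for (costs in list(cost_params(0.2, 2.63, 4.56),
                     cost_params(0.15, 1.2, 6.5),
                     cost_params(0.3, 4.0, 0.8))) {
    s <- small_noiseless_sim(seed = 11, costs = costs)
    parts <- split_labelled(s$sim$measurements)
    b <- build_budgets(parts$labelled, parts$controls, s$baseline)
    f <- suppressWarnings(estimate_costs(b, c_c = costs$c_c,
                                         se_method = "ols"))
    expect_equal(f$on_c_hat, costs$on_c, tolerance = 1e-8)
    expect_equal(f$in_c_hat, costs$in_c, tolerance = 1e-8)
    expect_equal(f$r_squared_model_vs_obs, 1, tolerance = 1e-8)
  }
})

test_that("estimate_costs inverts truth budgets built from the model directly", {
  p <- cost_params(0.2, 3.1, 5.7)
  c_b <- c(1, 2, 1.5); on_b <- c(0.12, 0.10, 0.08); in_b <- c(0, 0.09, 0.05)
  b <- tibble::tibble(
    plant_id = c("a", "b", "c"),
    treatment = c("gln_only", "mixed", "mixed"), day = 6,
    c_b_g = c_b, on_b_g = on_b, in_b_g = in_b,
    c_u_g = NA_real_, root_mass_mg = NA_real_,
    cue_obs = modelled_cue(c_b, on_b, in_b, p)
  )
  f <- suppressWarnings(estimate_costs(b, c_c = 0.2, se_method = "ols"))
  expect_equal(f$on_c_hat, 3.1, tolerance = 1e-10)
  expect_equal(f$in_c_hat, 5.7, tolerance = 1e-10)
})

test_that("gln-only designs leave the inorganic cost non-estimable", {
  costs <- cost_params(0.2, 2.63, 4.56)
  cfg <- noiseless(sim_config(n_gln = 5, n_mixed = 1, n_control = 2,
                              true_costs = costs, seed = 3))
  sim <- generate_experiment2(cfg)
  base <- generate_baseline(cfg)
  parts <- split_labelled(sim$measurements)
  gln_only <- parts$labelled[parts$labelled$treatment == "gln_only", ]
  b <- build_budgets(gln_only, parts$controls, base)
  expect_warning(f <- estimate_costs(b, se_method = "ols"), "not estimable")
  expect_true(is.na(f$in_c_hat))
  expect_equal(f$on_c_hat, 2.63, tolerance = 1e-8)
})

test_that("budgets match the generator truth exactly without noise", {
  s <- small_noiseless_sim(seed = 5)
  parts <- split_labelled(s$sim$measurements)
  b <- build_budgets(parts$labelled, parts$controls, s$baseline)
  tr <- s$sim$truth$budgets
  m <- dplyr::inner_join(b, tr, by = "plant_id", suffix = c("", "_true"))
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$on_b_g, m$on_b_g_true, tolerance = 1e-10)
  expect_equal(m$in_b_g, m$in_b_g_true, tolerance = 1e-10)
  expect_equal(m$c_b_g, m$c_b_g_true, tolerance = 1e-10)
  expect_equal(m$c_u_g, m$c_u_g_true, tolerance = 1e-10)
  expect_equal(m$cue_obs, m$cue, tolerance = 1e-10)
  # gln-only plants acquire no inorganic N by construction
  expect_true(all(m$in_b_g[m$treatment == "gln_only"] == 0))
})

test_that("plants smaller than the baseline mean are floored with a warning", {
  s <- small_noiseless_sim(seed = 9)
  parts <- split_labelled(s$sim$measurements)
  big_base <- s$baseline
  big_base$c_mass_g <- big_base$c_mass_g * 50
  expect_warning(
    b <- build_budgets(parts$labelled, parts$controls, big_base),
    "floored"
  )
  expect_true(all(b$c_b_g == 0))
})

test_that("missing organ records and missing baselines are errors", {
  s <- small_noiseless_sim(seed = 13)
  parts <- split_labelled(s$sim$measurements)
  shoot_only <- parts$labelled[parts$labelled$organ == "shoot", ]
  expect_error(build_budgets(shoot_only, parts$controls, s$baseline),
               "shoot and a root|exactly one")
  base_gln <- s$baseline[s$baseline$treatment == "gln_only", ]
  expect_error(build_budgets(parts$labelled, parts$controls, base_gln),
               "baseline missing")
})

test_that("a noisy default experiment yields a well-formed cost fit", {
  # the statistical recovery guarantees (median error, SE calibration) are
  # established over replicated experiments in the acceptance suite; here
  # we check one noisy fit end to end
  cfg <- sim_config(seed = 2021)
  sim <- generate_experiment2(cfg)
  base <- generate_baseline(cfg)
  parts <- split_labelled(sim$measurements)
  f <- suppressWarnings({
    estimate_costs(build_budgets(parts$labelled, parts$controls, base))
  })
  expect_gt(f$on_c_hat, 0)
  expect_gt(f$in_c_hat, f$on_c_hat)  # inorganic N costs more C
  expect_true(f$on_c_se > 0 && f$on_c_se < f$on_c_hat)
  expect_true(f$in_c_se > 0 && f$in_c_se < f$in_c_hat)
  expect_true(f$r_squared_model_vs_obs >= 0 && f$r_squared_model_vs_obs <= 1)
  expect_equal(f$n_plants, (13 + 26) * 3)
})
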