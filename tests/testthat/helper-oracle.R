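# Brute-force normal-equations OLS oracle, independent of stats::lm.
# Returns slope/intercept/SE/R2 following the usual conventions (uncentered
# total sum of squares for through-origin fits).
ols_oracle <- function(x, y, with_intercept = TRUE) {
  X <- if (with_intercept) cbind(1, x) else cbind(x)
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(xtx)) * sigma2)
  tss <- if (with_intercept) sum((y - mean(y))^2) else sum(y^2)
  list(
    slope = unname(beta[p, 1]),
    intercept = if (with_intercept) unname(beta[1, 1]) else 0,
    slope_se = unname(se[p]),
    r_squared = 1 - sum(res^2) / tss
  )
}

# Small noiseless simulated experiment shared across tests.
small_noiseless_sim <- function(seed = 42, costs = cost_params(),
                                n_gln = 4, n_mixed = 6) {
  cfg <- noiseless(sim_config(n_gln = n_gln, n_mixed = n_mixed,
                              n_control = 2, true_costs = costs,
                              seed = seed))
  list(config = cfg, sim = generate_experiment2(cfg),
       baseline = generate_baseline(cfg))
}

split_labelled <- function(measurements) {
  lab <- measurements[measurements$treatment %in% c("gln_only", "mixed"), ]
  ctl <- measurements[grepl("^control", measurements$treatment), ]
  list(labelled = lab, controls = ctl)
}
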