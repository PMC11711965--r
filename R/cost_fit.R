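#' Estimate organic and inorganic N assimilation costs
#'
#' Inverts the CUE cost model by linearization. With `c_c` fixed, the model
#' `CUE_m = c_b / (c_c*c_b + on_c*on_b + in_c*in_b + c_b)` rearranges to
#' `(1/CUE_o - c_c - 1) * c_b = on_c*on_b + in_c*in_b`,
#' which is linear in the two costs, so they are estimated by ordinary
#' least squares without an intercept (the model has no constant term) of
#' the left-hand side on `(on_b, in_b)`.
#'
#' If no plant has `in_b > 0` (a glutamine-only design) the inorganic cost
#' is not identifiable: the fit drops to `on_b` alone and `in_c` is
#' reported as `NA` with a warning.
#'
#' @param budgets Budget table from [build_budgets()] (or simulator truth).
#' @param c_c Assumed growth respiration cost, g C per g C (default 0.2).
#' @param fit_scope `"all_days"` (default) pools every harvest;
#'   `"final_day"` restricts to the last harvest day, where pre-experiment
#'   differences between plants matter least.
#' @param with_intercept Add a diagnostic intercept to the linearized fit
#'   (off by default; the model itself has none).
#' @param se_method `"bootstrap"` (default) resamples plants with
#'   replacement within treatment to estimate coefficient standard errors;
#'   `"ols"` reports the classical least-squares errors. The bootstrap is
#'   preferred because the linearized response and both regressors are
#'   built from the same noisy measurements, so the classical errors —
#'   which assume error-free regressors and homoscedastic residuals —
#'   understate the sampling spread.
#' @param n_boot_se,boot_seed Bootstrap draws and seed for the standard
#'   errors (deterministic given the seed).
#' @return A `cost_fit` list: `on_c_hat`, `on_c_se`, `in_c_hat`, `in_c_se`,
#'   `r_squared_model_vs_obs` (squared correlation between the modelled CUE
#'   at the fitted costs and the observed CUE), `n_plants`, `c_c_assumed`,
#'   `fit_scope`, plus the underlying `lm` fit.
#' @export
estimate_costs <- function(budgets, c_c = 0.2,
                           fit_scope = c("all_days", "final_day"),
                           with_intercept = FALSE,
                           se_method = c("bootstrap", "ols"),
                           n_boot_se = 400, boot_seed = 1L) {
  fit_scope <- match.arg(fit_scope)
  se_method <- match.arg(se_method)
  b <- tibble::as_tibble(budgets)
  stopifnot(all(c("c_b_g", "on_b_g", "in_b_g", "cue_obs") %in% names(b)))
  if (fit_scope == "final_day") b <- dplyr::filter(b, .data$day == max(.data$day))
  b <- dplyr::filter(b, is.finite(.data$cue_obs), .data$cue_obs > 0,
                     .data$c_b_g >= 0)
  if (nrow(b) < 2) stop("need at least 2 usable plants", call. = FALSE)

  y <- (1 / b$cue_obs - c_c - 1) * b$c_b_g
  on_b <- b$on_b_g
  in_b <- b$in_b_g
  in_identifiable <- sum(in_b > 0) >= 2
  if (!in_identifiable) {
    warning("fewer than 2 plants with in_b > 0: in_c not estimable; ",
            "fitting organic cost only", call. = FALSE)
    fml <- if (with_intercept) y ~ on_b else y ~ 0 + on_b
  } else {
    if (abs(cor(on_b, in_b)) > 0.999) {
      warning("on_b and in_b are nearly collinear; cost estimates unstable",
              call. = FALSE)
    }
    fml <- if (with_intercept) y ~ on_b + in_b else y ~ 0 + on_b + in_b
  }
  fit <- lm(fml)
  cf <- summary(fit)$coefficients

  on_c_hat <- unname(cf["on_b", 1L]); on_c_se <- unname(cf["on_b", 2L])
  if (in_identifiable) {
    in_c_hat <- unname(cf["in_b", 1L]); in_c_se <- unname(cf["in_b", 2L])
  } else {
    in_c_hat <- NA_real_; in_c_se <- NA_real_
  }

  if (se_method == "bootstrap" && !with_intercept) {
    trt <- if ("treatment" %in% names(b)) b$treatment else rep("all", nrow(b))
    idx <- split(seq_len(nrow(b)), trt)
    boot <- withr::with_seed(boot_seed, vapply(seq_len(n_boot_se), function(i) {
      take <- unlist(lapply(idx, function(j) sample(j, length(j),
                                                    replace = TRUE)))
      yb <- y[take]; on_bb <- on_b[take]; in_bb <- in_b[take]
      fb <- if (!in_identifiable || sum(in_bb > 0) < 2) {
        c(coef(lm(yb ~ 0 + on_bb))[["on_bb"]], NA_real_)
      } else {
        cb <- coef(lm(yb ~ 0 + on_bb + in_bb))
        c(cb[["on_bb"]], cb[["in_bb"]])
      }
      fb
    }, numeric(2)))
    on_c_se <- sd(boot[1L, ])
    if (in_identifiable) in_c_se <- sd(boot[2L, ], na.rm = TRUE)
  }

  pars <- cost_params(c_c = c_c, on_c = max(0, on_c_hat),
                      in_c = if (is.na(in_c_hat)) 0 else max(0, in_c_hat))
  cue_m <- modelled_cue(pmax(b$c_b_g, .Machine$double.eps), on_b, in_b, pars)
  r2 <- if (sd(cue_m) > 0 && sd(b$cue_obs) > 0) cor(cue_m, b$cue_obs)^2 else NA_real_

  structure(list(
    on_c_hat = on_c_hat, on_c_se = on_c_se,
    in_c_hat = in_c_hat, in_c_se = in_c_se,
    r_squared_model_vs_obs = r2,
    n_plants = nrow(b), c_c_assumed = c_c, fit_scope = fit_scope,
    with_intercept = with_intercept, fit = fit
  ), class = "cost_fit")
}

#' @export
print.cost_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<cost_fit> n = %d plants, scope = %s, c_c = %.3g (assumed)\n",
           "  organic N cost   on_c = %.3f +/- %.3f g C/g N\n",
           "  inorganic N cost in_c = %s g C/g N\n",
           "  R2 (modelled vs observed CUE) = %.3f\n"),
    x$n_plants, x$fit_scope, x$c_c_assumed, x$on_c_hat, x$on_c_se,
    if (is.na(x$in_c_hat)) "not estimable"
    else sprintf("%.3f +/- %.3f", x$in_c_hat, x$in_c_se),
    x$r_squared_model_vs_obs
  ))
  invisible(x)
}
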