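#' N uptake per unit root mass, by treatment
#'
#' Fits, per treatment, a regression through the origin of total N uptake
#' (`on_b + in_b`) on harvested root dry mass, and reports the
#' mixed-to-glutamine ratio of the two slopes — the uptake premium of the
#' mixed-N treatment — with a seeded nonparametric bootstrap interval
#' (resampling plants within treatment).
#'
#' @param budgets Budget table from [build_budgets()].
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level of the percentile interval.
#' @return List with `slopes` (tibble: treatment, slope g N/mg, n),
#'   `ratio` (mixed/gln_only), `ci` (length-2 percentile interval),
#'   `n_boot`.
#' @export
uptake_per_root_mass <- function(budgets, n_boot = 1000, seed = 1L,
                                 level = 0.95) {
  b <- tibble::as_tibble(budgets)
  trts <- intersect(c("gln_only", "mixed"), unique(b$treatment))
  if (length(trts) < 2) {
    stop("need both gln_only and mixed treatments to form the uptake ratio",
         call. = FALSE)
  }
  counts <- table(b$treatment)[trts]
  if (any(counts < 3)) stop("need >= 3 plants per treatment", call. = FALSE)

  origin_slope <- function(d) {
    sum(d$root_mass_mg * (d$on_b_g + d$in_b_g)) / sum(d$root_mass_mg^2)
  }
  slopes <- vapply(trts, function(t) {
    origin_slope(b[b$treatment == t, ])
  }, numeric(1))
  ratio <- slopes[["mixed"]] / slopes[["gln_only"]]

  idx <- split(seq_len(nrow(b)), b$treatment)
  boot <- withr::with_seed(seed, vapply(seq_len(n_boot), function(i) {
    take <- unlist(lapply(trts, function(t) {
      sample(idx[[t]], length(idx[[t]]), replace = TRUE)
    }))
    d <- b[take, ]
    origin_slope(d[d$treatment == "mixed", ]) /
      origin_slope(d[d$treatment == "gln_only", ])
  }, numeric(1)))
  alpha <- (1 - level) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha)))

  list(
    slopes = tibble::tibble(treatment = trts, slope_g_n_per_mg = unname(slopes),
                            n = as.integer(counts)),
    ratio = ratio, ci = ci, n_boot = n_boot
  )
}
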