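#' Configuration of the synthetic dual-label feeding experiment
#'
#' Parameters of the forward mass-balance simulator emulating the labelled
#' glutamine feeding design: plants on 10 atom%-excess U-13C5,15N2-glutamine
#' alone (`gln_only`) or mixed with unlabelled nitrate (`mixed`), plus
#' unlabelled control plants grown alongside to capture re-fixation of
#' respired 13CO2, harvested at days 1, 3 and 6.
#'
#' Defaults reproduce the study's regime: 13 glutamine-only and 26 mixed
#' plants per harvest day; true assimilation costs 2.63 (organic) and
#' 4.56 g C/g N (inorganic) with growth respiration 0.2 g C/g C; a 20%
#' uptake premium per unit root mass on mixed N; 60%/80% of new shoot/root
#' N from glutamine in the mixed treatment; tissue compositions from the
#' split-root experiment's elemental analysis; 5% multiplicative
#' measurement noise.
#'
#' @param n_gln,n_mixed,n_control Plants per harvest day in the labelled
#'   treatments and in each unlabelled control cohort.
#' @param harvest_days Harvest days (elapsed days on the labelled medium).
#' @param true_costs A [cost_params()]: the generating assimilation costs.
#' @param uptake_g_n_per_mg_root_day N uptake rate per unit root dry mass
#'   for glutamine-only plants (g N / mg / day).
#' @param mixed_premium Relative increase of N uptake per root mass on
#'   mixed N (0.20 = 20% premium).
#' @param organic_fraction_mixed Named vector: fraction of new shoot / root
#'   N acquired from glutamine in the mixed treatment.
#' @param initial_mass List: mean initial shoot and root dry mass (mg) and
#'   the between-plant CV of the initial-mass draws.
#' @param allocation_root Named vector: root fraction of new dry matter per
#'   treatment. The mixed default (0.353) is derived so both treatments
#'   share the same root relative growth rate given the uptake premium, so
#'   the premium surfaces purely as the uptake-per-root-mass contrast.
#' @param composition Tibble with columns `group` (`gln`/`mixed`), `organ`,
#'   `c_pct`, `n_pct`: tissue composition targets, % of dry weight.
#' @param refixation_excess Atom% excess 13C added to every plant sharing
#'   the labelled atmosphere (controls included) by re-fixation of respired
#'   13CO2.
#' @param measurement_cv Relative (lognormal, mean-one) noise on every
#'   measured quantity.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param source The [labelled_source()] being fed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_gln = 13, n_mixed = 26, n_control = 5,
                       harvest_days = c(1, 3, 6),
                       true_costs = cost_params(c_c = 0.2, on_c = 2.63,
                                                in_c = 4.56),
                       uptake_g_n_per_mg_root_day = 4e-5,
                       mixed_premium = 0.20,
                       organic_fraction_mixed = c(shoot = 0.60, root = 0.80),
                       initial_mass = list(shoot_mg = 6, root_mg = 2.5,
                                           cv = 0.10),
                       allocation_root = c(gln_only = 0.40, mixed = 0.353),
                       composition = default_composition(),
                       refixation_excess = 0.01,
                       measurement_cv = 0.05,
                       seed = 1L,
                       source = glutamine_source()) {
  stopifnot(
    n_gln >= 1, n_mixed >= 1, n_control >= 0,
    all(harvest_days >= 1), inherits(true_costs, "cost_params"),
    uptake_g_n_per_mg_root_day > 0, mixed_premium > -1,
    all(organic_fraction_mixed >= 0), all(organic_fraction_mixed <= 1),
    initial_mass$shoot_mg > 0, initial_mass$root_mg > 0, initial_mass$cv >= 0,
    all(allocation_root > 0), all(allocation_root < 1),
    refixation_excess >= 0, measurement_cv >= 0,
    inherits(source, "labelled_source")
  )
  structure(list(
    n_gln = n_gln, n_mixed = n_mixed, n_control = n_control,
    harvest_days = sort(unique(harvest_days)),
    true_costs = true_costs,
    uptake_g_n_per_mg_root_day = uptake_g_n_per_mg_root_day,
    mixed_premium = mixed_premium,
    organic_fraction_mixed = organic_fraction_mixed,
    initial_mass = initial_mass,
    allocation_root = allocation_root,
    composition = composition,
    refixation_excess = refixation_excess,
    measurement_cv = measurement_cv,
    seed = as.integer(seed),
    source = source
  ), class = "sim_config")
}

#' @rdname sim_config
#' @details `default_composition()` returns the shoot/root C and N
#'   concentration targets (% DW): glutamine-only plants from the
#'   glutamine-fed treatment of the split-root elemental analysis, mixed
#'   plants from the mixed treatment (root = mean of the two root sides).
#' @export
default_composition <- function() {
  tibble::tribble(
    ~group,  ~organ,  ~c_pct, ~n_pct,
    "gln",   "shoot", 39.23,  6.62,
    "gln",   "root",  40.24,  3.14,
    "mixed", "shoot", 35.61,  6.54,
    "mixed", "root",  39.955, 3.695
  )
}

# mean-one multiplicative lognormal noise factors
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -s^2 / 2, sd = s))
}

comp_for <- function(config, group) {
  cm <- config$composition[config$composition$group == group, ]
  list(
    c = setNames(cm$c_pct, cm$organ),
    n = setNames(cm$n_pct, cm$organ)
  )
}

# Deterministic daily forward model of one plant; returns organ states and
# cumulative truth. Growth is N-driven: uptake proportional to current root
# mass, new dry matter partitioned by the allocation fraction at the
# treatment's tissue composition; carbon is priced by the cost model, and
# retained glutamine C travels with the glutamine N into organs.
sim_plant <- function(config, group, labelled, n_days, s0_mg, r0_mg) {
  comp <- comp_for(config, group)
  a_r <- config$allocation_root[[if (group == "gln") "gln_only" else "mixed"]]
  a <- c(shoot = 1 - a_r, root = a_r)
  f_org <- if (group == "gln") c(shoot = 1, root = 1)
  else config$organic_fraction_mixed[c("shoot", "root")]
  premium <- if (group == "gln") 1 else 1 + config$mixed_premium
  costs <- config$true_costs
  src <- config$source

  dm <- c(shoot = s0_mg, root = r0_mg)                       # mg
  x13 <- c(shoot = 0, root = 0)                              # mol excess 13C
  x15 <- c(shoot = 0, root = 0)                              # mol excess 15N
  cum <- list(on = 0, inorg = 0, c_b = 0, c_u = 0, c_ctot = 0, ret = 0)
  n_per_dm <- 100 / sum(a * comp$n[names(a)])                # g DM per g N

  for (d in seq_len(n_days)) {
    uptake_n <- config$uptake_g_n_per_mg_root_day * dm[["root"]] * premium
    new_dm_g <- uptake_n * n_per_dm
    new_dm <- a * new_dm_g                                   # g, per organ
    new_n <- new_dm * comp$n[names(a)] / 100
    new_c <- new_dm * comp$c[names(a)] / 100
    on_o <- f_org[names(a)] * new_n
    in_o <- new_n - on_o
    on_d <- sum(on_o); in_d <- sum(in_o); cb_d <- sum(new_c)
    cctot_d <- costs$c_c * cb_d + costs$on_c * on_d + costs$in_c * in_d
    cu_tot <- cb_d + cctot_d
    cu_gln <- on_d * src$c_mass_per_n_mass
    if (cu_tot < cu_gln) {
      stop("config drives negative photosynthetic C: glutamine C uptake ",
           "exceeds total C demand", call. = FALSE)
    }
    cue_d <- cb_d / cu_tot
    retained <- cu_gln * cue_d
    if (labelled) {
      ret_o <- retained * on_o / on_d
      x13 <- x13 + ret_o * (src$excess_13c / 100) / ATOMIC_MASS_C
      x15 <- x15 + on_o * (src$excess_15n / 100) / ATOMIC_MASS_N
    }
    dm <- dm + new_dm * 1000
    cum$on <- cum$on + on_d; cum$inorg <- cum$inorg + in_d
    cum$c_b <- cum$c_b + cb_d; cum$c_u <- cum$c_u + cu_gln
    cum$c_ctot <- cum$c_ctot + cctot_d; cum$ret <- cum$ret + retained
  }

  list(dm = dm, x13 = x13, x15 = x15, cum = cum, comp = comp)
}

measure_plant <- function(plant, config, sample_id, treatment, day) {
  organs <- c("shoot", "root")
  dm <- plant$dm[organs]
  c_pct <- plant$comp$c[organs]
  n_pct <- plant$comp$n[organs]
  c_mol <- (dm / 1000) * c_pct / 100 / ATOMIC_MASS_C
  n_mol <- (dm / 1000) * n_pct / 100 / ATOMIC_MASS_N
  # Measured enrichments: natural abundance plus the labelling (and, for
  # 13C, re-fixation) excess. Measurement noise is relative to the
  # enrichment above the calibrated natural-abundance baseline, not to the
  # absolute atom% — an isotope-ratio instrument resolves natural abundance
  # itself orders of magnitude more precisely than any tracer signal.
  excess13 <- 100 * plant$x13[organs] / c_mol + config$refixation_excess
  excess15 <- 100 * plant$x15[organs] / n_mol
  cv <- config$measurement_cv
  tibble::tibble(
    sample_id = sample_id, treatment = treatment, organ = organs, day = day,
    dry_mass_mg = dm * noise_factor(2, cv),
    c_conc_pct_dw = c_pct * noise_factor(2, cv),
    n_conc_pct_dw = n_pct * noise_factor(2, cv),
    atom_pct_13c = NAT_ABUND_13C + excess13 * noise_factor(2, cv),
    atom_pct_15n = NAT_ABUND_15N + excess15 * noise_factor(2, cv)
  )
}

#' Simulate the dual-label feeding experiment
#'
#' Runs the forward mass-balance model for every plant of every treatment
#' and harvest day of the configured design and emits (1) a measurement
#' table in the standard schema ([measurement-schema]) with measurement
#' noise applied, and (2) the exact generating truth, against which the
#' analysis stages can be validated.
#'
#' Mass balance holds exactly in the truth records: glutamine-C uptake
#' equals retained glutamine C plus respired glutamine C, and the true CUE
#' equals the cost model evaluated at the generating parameters.
#'
#' @param config A [sim_config()].
#' @return List with `measurements` (tibble) and `truth` (list:
#'   `budgets` tibble with per-plant true budgets, CUE, retention and
#'   respired/retained glutamine C; `n_fractions` tibble of the organ-level
#'   organic-N fractions of new growth; `costs`, the generating
#'   [cost_params()]).
#' @export
generate_experiment2 <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- list(
    list(treatment = "gln_only",         group = "gln",   labelled = TRUE,
         n = config$n_gln),
    list(treatment = "mixed",            group = "mixed", labelled = TRUE,
         n = config$n_mixed),
    list(treatment = "control_gln_only", group = "gln",   labelled = FALSE,
         n = config$n_control),
    list(treatment = "control_mixed",    group = "mixed", labelled = FALSE,
         n = config$n_control)
  )
  meas <- list(); truth <- list()
  for (dg in design) {
    if (dg$n == 0) next
    for (day in config$harvest_days) {
      for (i in seq_len(dg$n)) {
        id <- sprintf("%s_d%d_p%02d", dg$treatment, day, i)
        s0 <- config$initial_mass$shoot_mg *
          noise_factor(1, config$initial_mass$cv)
        r0 <- config$initial_mass$root_mg *
          noise_factor(1, config$initial_mass$cv)
        pl <- sim_plant(config, dg$group, dg$labelled, day, s0, r0)
        meas[[id]] <- measure_plant(pl, config, id, dg$treatment, day)
        if (dg$labelled) {
          cum <- pl$cum
          truth[[id]] <- tibble::tibble(
            plant_id = id, treatment = dg$treatment, day = day,
            c_b_g = cum$c_b, on_b_g = cum$on, in_b_g = cum$inorg,
            c_u_g = cum$c_u, c_ctot_g = cum$c_ctot,
            cue = cum$c_b / (cum$c_b + cum$c_ctot),
            retention = cum$ret / cum$c_u,
            c_retained_gln_g = cum$ret,
            c_respired_gln_g = cum$c_u - cum$ret,
            root_mass_mg = pl$dm[["root"]],
            initial_shoot_mg = s0, initial_root_mg = r0
          )
        }
      }
    }
  }
  n_frac <- tibble::tibble(
    treatment = rep(c("gln_only", "mixed"), each = 2),
    organ = rep(c("shoot", "root"), 2),
    organic_fraction_new_n = c(1, 1,
                               config$organic_fraction_mixed[["shoot"]],
                               config$organic_fraction_mixed[["root"]])
  )
  list(
    measurements = validate_measurements(dplyr::bind_rows(meas)),
    truth = list(budgets = dplyr::bind_rows(truth), n_fractions = n_frac,
                 costs = config$true_costs)
  )
}

#' Day-0 baseline cohort summary
#'
#' Simulates a measured day-0 cohort (initial-mass draws plus measurement
#' noise) and returns the mean dry mass and elemental masses per organ for
#' each labelled treatment — the baseline that [build_budgets()] subtracts
#' to form per-plant increments. With all CVs at zero the summary equals
#' the configured means exactly.
#'
#' @param config A [sim_config()].
#' @param n_baseline Plants measured per treatment at day 0.
#' @return Tibble: `treatment`, `organ`, `dry_mass_mg`, `c_mass_g`,
#'   `n_mass_g` (cohort means).
#' @export
generate_baseline <- function(config = sim_config(), n_baseline = 10) {
  stopifnot(inherits(config, "sim_config"), n_baseline >= 1)
  set.seed(config$seed + 1000003L)
  rows <- list()
  for (trt in c("gln_only", "mixed")) {
    comp <- comp_for(config, if (trt == "gln_only") "gln" else "mixed")
    for (organ in c("shoot", "root")) {
      m0 <- if (organ == "shoot") config$initial_mass$shoot_mg
      else config$initial_mass$root_mg
      dm <- m0 * noise_factor(n_baseline, config$initial_mass$cv) *
        noise_factor(n_baseline, config$measurement_cv)
      c_pct <- comp$c[[organ]] * noise_factor(n_baseline, config$measurement_cv)
      n_pct <- comp$n[[organ]] * noise_factor(n_baseline, config$measurement_cv)
      rows[[paste(trt, organ)]] <- tibble::tibble(
        treatment = trt, organ = organ,
        dry_mass_mg = mean(dm),
        c_mass_g = mean(dm / 1000 * c_pct / 100),
        n_mass_g = mean(dm / 1000 * n_pct / 100)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname sim_config
#' @details `noiseless()` returns a copy of a config with every stochastic
#'   component switched off (measurement noise, initial-mass spread,
#'   re-fixation excess) — the regime in which every analysis stage must
#'   invert the generator exactly.
#' @param config A `sim_config` to strip of noise.
#' @export
noiseless <- function(config = sim_config()) {
  config$measurement_cv <- 0
  config$initial_mass$cv <- 0
  config$refixation_excess <- 0
  config
}
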