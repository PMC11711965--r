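# glntrace

Isotope accounting and carbon-use-efficiency (CUE) modelling for plants
fed dual-labelled glutamine (U-¹³C₅,¹⁵N₂-gln), for plant ecophysiologists
working with ¹³C/¹⁵N tracer experiments.

## The science

When plants take up an amino acid they import carbon along with nitrogen,
and they skip the carbon cost of reducing nitrate. Feeding glutamine
labelled at 10 atom% excess on all five carbons and both nitrogens makes
both effects measurable from bulk-tissue EA-IRMS data:

* **Tracer accounting.** After background correction against unlabelled
  control plants (which absorbs re-fixation of respired ¹³CO₂), molar
  excess contents of ¹³C and ¹⁵N are computed per organ. If no glutamine
  carbon were respired, excess ¹³C vs excess ¹⁵N would fall on a line of
  slope `r = (5·e₁₃)/(2·e₁₅) = 2.5`; a fitted slope `b` therefore converts
  to a retained fraction `b / 2.5` of glutamine-derived carbon. Similarly
  the slope of excess ¹⁵N vs total N over the 0.10 enrichment gives the
  fraction of tissue N acquired from glutamine.
* **CUE cost model.** Observed CUE is the biomass excess ¹³C:¹⁵N ratio
  normalized by the source ratio. Modelled CUE prices growth with a
  respiration cost `C_c` (fixed at 0.2 g C/g C) and N assimilation costs
  `oN_c`, `iN_c` (g C per g N from the organic / inorganic source):

  ```
  CUE_m = C_b / (C_c·C_b + oN_c·oN_b + iN_c·iN_b + C_b)
  ```

  which linearizes to `(1/CUE_o − C_c − 1)·C_b = oN_c·oN_b + iN_c·iN_b`
  and is fitted by no-intercept least squares over per-plant budgets, with
  plant-bootstrap standard errors.
* **Forward simulator.** A seeded mass-balance generator emulates the
  whole feeding experiment (13 + 26 labelled plants per harvest day at
  days 1/3/6, unlabelled controls, 20% mixed-N uptake premium, 5%
  measurement noise) and returns the exact generating truth, so the full
  analysis is testable with no external data.

## Worked example

```r
library(glntrace)

gln <- glutamine_source()
molar_excess_ratio(gln)
#> [1] 2.5

# printed regression slopes -> % of glutamine-derived C retained
round(100 * carbon_retention_fraction(c(1.017, 1.075), gln))
#> [1] 41 43

# slope of excess 15N vs total N -> fraction of N from glutamine
n_fraction_from_source(c(0.06, 0.08), gln)
#> [1] 0.6 0.8

# glutamine-derived C: %DW N x slope, then as a share of tissue C
shoot_c <- source_c_conc_pct_dw(6.62, 1.017)   # 6.732 -> "6.7 %DW"
round(source_c_share(shoot_c, 39.23), 1)
#> [1] 17.2
```

A full synthetic analysis (the numbers below are what the bundled
analysis scripts print for seed 1):

```r
cfg <- sim_config(seed = 1)
sim <- generate_experiment2(cfg)
base <- generate_baseline(cfg)
ctl <- grepl("^control", sim$measurements$treatment)
budgets <- build_budgets(sim$measurements[!ctl, ], sim$measurements[ctl, ], base)
estimate_costs(budgets)
#> <cost_fit> n = 117 plants, scope = all_days, c_c = 0.2 (assumed)
#>   organic N cost   on_c = 2.771 +/- 0.202 g C/g N
#>   inorganic N cost in_c = 3.521 +/- 0.591 g C/g N
#>   R2 (modelled vs observed CUE) = 0.295
uptake_per_root_mass(budgets, seed = 1)$ratio
#> [1] 1.207873
```

The generating truth was `on_c = 2.63`, `in_c = 4.56` and a 20% uptake
premium: one noisy experiment recovers the organic cost within its
standard error, the (harder) inorganic cost within two, and the uptake
ratio within 1% of truth. Over 20 replicated experiments
(`analysis/04_parameter_recovery.R`) the median relative error is ~6% for
both costs with 2-SE coverage of 90–95%.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables under `results/`:

1. `01_simulate.R` — generate the experiment and day-0 baseline;
2. `02_tracer_regressions.R` — excess contents, retention and N-source
   regressions, glutamine-derived C tables;
3. `03_budgets_cost_fit.R` — per-plant budgets, cost fits (both scopes),
   uptake-per-root-mass ratio with bootstrap interval;
4. `04_parameter_recovery.R` — replicated recovery experiment.

`run_pipeline()` performs stages 2–3 in one call (optionally simulating
first) and writes byte-deterministic CSVs plus a provenance file.

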