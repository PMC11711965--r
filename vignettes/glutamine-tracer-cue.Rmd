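---
title: "Dual-label glutamine tracing and carbon-use-efficiency modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-label glutamine tracing and carbon-use-efficiency modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glntrace)
```

# The problem

Plants can acquire nitrogen as inorganic ions (nitrate, ammonium) or as
organic molecules such as amino acids. The two routes differ in their
carbon economics twice over: an amino acid brings carbon *with* the
nitrogen, and assimilating reduced organic N costs less carbon than
reducing nitrate. Both effects should show up in carbon use efficiency
(CUE) — the fraction of carbon taken up that ends up in biomass rather
than being respired.

`glntrace` implements the accounting needed to measure these effects in a
dual-label feeding design: plants are grown on glutamine universally
labelled with ^13^C and ^15^N (U-^13^C~5~,^15^N~2~-gln, 10 atom% excess on
each element), either as the sole N source or mixed with unlabelled
nitrate, and harvested at several time points. Because every glutamine
molecule carries five labelled carbons per two labelled nitrogens, and
because (by assumption) nitrogen taken up stays in the biomass while
carbon can be respired away, the ratio of excess ^13^C to excess ^15^N in
tissue reads out the fate of glutamine-derived carbon.

# Tracer accounting

## Backgrounds and excess quantities

Measured atom% values are converted to *excess atom fractions* by
subtracting a background. The preferred background is the mean atom% of
unlabelled control plants grown in the same chamber, matched by organ and
harvest day: these controls capture photosynthetic re-fixation of respired
^13^CO~2~, which raises ^13^C above natural abundance even in plants that
never touched the tracer. When no controls are available the package falls
back to the natural-abundance constants 1.1078 atom% ^13^C and 0.3663
atom% ^15^N and records the fallback. Negative excess values (possible
under noise) are kept, not clipped — clipping would bias regressions near
the origin — but values below a configurable floor are flagged.

Excess *contents* are molar:

$$\mathrm{excess~\mu mol} = \text{excess fraction} \times
  \frac{m_\mathrm{dry} \cdot c/100}{M} \times 1000,$$

with $M$ = 12.011 (C) or 14.007 (N) g mol^-1^. The molar basis is
canonical because it makes the theoretical slope of excess ^13^C against
excess ^15^N for tissue built entirely of glutamine equal the molar excess
ratio of the compound,

$$r = \frac{n_\mathrm{C}\, e_{13}}{n_\mathrm{N}\, e_{15}}
    = \frac{5 \times 10}{2 \times 10} = 2.5 .$$

Elemental (not isotope-specific) atomic masses are used throughout; the
bookkeeping counts excess heavy atoms within elemental pools, so this is
the internally consistent choice.

## Slope conversions

* **Carbon retention.** The fitted slope $b$ of excess ^13^C vs excess
  ^15^N content, divided by $r = 2.5$, is the fraction of glutamine-derived
  carbon retained in biomass; $1 - b/r$ was lost by respiration. Slopes of
  1.017 and 1.075 thus convert to 41% and 43% retention (integers per
  report convention).
* **Nitrogen source.** The slope of excess ^15^N against total N, divided
  by the source enrichment $e_{15}/100 = 0.10$, is the fraction of tissue
  N that came from glutamine; a slope of 0.05 marks equal uptake from a
  50:50 (mol N) glutamine/nitrate mixture.
* **Glutamine-derived C as a concentration.** The product of tissue N
  concentration (%DW) and the retention slope estimates the concentration
  of glutamine-derived carbon. The default `"literal"` mode takes the
  literal product of a molar slope with a mass concentration; a
  `"strict"` mode applies the 12.011/14.007 molar-to-mass factor (a ~14%
  difference). The literal product is the reporting convention this
  package replicates; the flag exists because the two bases are not
  interchangeable and the user should choose knowingly.

A note on the compound's composition: glutamine (C~5~H~10~N~2~O~3~)
carries $5 \times 12.011 / (2 \times 14.007) = 2.144$ g C per g N —
equivalently 0.47 g N per g C. Literature values quoted as "C : N = 0.47
g C g^-1^ N" are this same number with the ratio read in the opposite
direction; all internal arithmetic uses 2.144 g C/g N.

# The CUE cost model

Observed CUE uses the biomass excess ratio normalized by the source ratio:

$$\mathrm{CUE_o} = \frac{(^{13}\mathrm{C}:{}^{15}\mathrm{N})_\text{biomass}}
                        {(^{13}\mathrm{C}:{}^{15}\mathrm{N})_\text{source}},$$

which assumes all N taken up remains in biomass and that glutamine-derived
carbon is respired in proportion to carbon at large (a shared metabolite
pool).

Modelled CUE prices growth with three costs — $C_c$ g C respired per g
biomass C (growth respiration), $oN_c$ and $iN_c$ g C per g N assimilated
from the organic and inorganic source:

$$\mathrm{CUE_m} = \frac{C_b}{C_c C_b + oN_c\, oN_b + iN_c\, iN_b + C_b}.$$

$C_c$ is fixed at 0.2 by assumption: whole-plant growth respiration
including N assimilation has been estimated near 0.43, and $C_c$ excludes
the N costs, so it must be smaller; its exact value shifts the absolute
cost estimates slightly but not the organic/inorganic contrast, which is
the quantity of interest.

## Estimating the costs

With $C_c$ fixed the model linearizes exactly:

$$\left(\frac{1}{\mathrm{CUE_o}} - C_c - 1\right) C_b
  = oN_c\, oN_b + iN_c\, iN_b,$$

so `estimate_costs()` runs ordinary least squares *without an intercept*
(the model has no constant term; an intercept can be added for
diagnostics only) of the left-hand side on $(oN_b, iN_b)$. Designs with no
inorganic-N plants leave $iN_c$ non-estimable; the fit then drops to
$oN_b$ alone with a warning. Two fit scopes are provided — all harvests
pooled, and the final harvest only, where pre-experimental differences
between plants have decayed most.

**Standard errors.** The default SEs come from a seeded bootstrap that
resamples plants with replacement within treatment (400 draws). The
classical least-squares errors assume error-free regressors and
homoscedastic residuals; here the linearized response and both regressors
are constructed from the same noisy measurements, and in simulation the
classical errors understate the sampling spread of the estimates by
roughly 1.5-fold, while the bootstrap errors track it. `se_method = "ols"`
restores the classical errors. Coefficients themselves are always the
plain OLS solution.

The reported $R^2$ is the squared correlation between CUE modelled at the
fitted costs and observed CUE. Note that when CUE varies little between
plants (as in the synthetic default, where each treatment has a nearly
constant true CUE) this statistic is legitimately small even when the
costs are recovered well: it measures spread explained, not estimate
quality.

## Per-plant budgets

The model quantities are not measured directly; `build_budgets()`
estimates them per plant (shoot + root summed):

* $oN_b$ = total excess ^15^N mass / 0.10 — N imported via glutamine;
* $C_b$ = harvest C mass − mean C mass of a measured day-0 cohort;
* $iN_b$ = (harvest N − baseline N) − $oN_b$, floored at 0, and exactly 0
  for glutamine-only plants, whose only N source is the tracer;
* $C_u$ = $oN_b \times 2.144$ — carbon imported with the glutamine;
* $\mathrm{CUE_o}$ from the plant-summed molar excess contents.

The baseline-subtraction construction is this package's own estimator —
a per-plant growth increment cannot be measured destructively any other
way — and the synthetic generator produces data consistent with it, so
recovery is well-posed. Plants smaller than the baseline mean yield
floored increments with a warning.

# The synthetic experiment

`generate_experiment2()` is a forward mass-balance simulator of the
feeding design: 13 glutamine-only and 26 mixed-N labelled plants per
harvest day (1, 3, 6), plus unlabelled control cohorts (default 5 plants
per treatment per day) sharing the labelled atmosphere.

Growth is nitrogen-driven and discretized daily — the simplest law that
produces the observed linear uptake-vs-root-mass pattern:

1. Daily N uptake = rate × current root mass; mixed-N plants take up 20%
   more per unit root mass (the configured premium).
2. New dry matter = uptake / N concentration of new tissue; it is split
   between organs by a fixed allocation fraction, at the treatment's
   tissue composition (C and N %DW from the split-root elemental
   analysis: glutamine-only shoots 39.23/6.62, roots 40.24/3.14; mixed
   shoots 35.61/6.54, roots 39.955/3.695).
3. In the mixed treatment, 60% of new shoot N and 80% of new root N is
   organic; glutamine-only plants are 100% organic by construction.
4. Total C demand follows the cost model: $C_u = C_b(1 + C_c) + oN_c\,
   oN_b + iN_c\, iN_b$ per day; glutamine supplies $oN \times 2.144$ g C
   of it and photosynthesis the rest (a config whose glutamine C exceeds
   total demand is rejected).
5. Retained glutamine C (uptake × CUE, the shared-pool assumption) is
   distributed to organs in proportion to each organ's glutamine-N
   acquisition — the label travels with the glutamine backbone. This
   keeps per-organ excess-^13^C/^15^N slopes equal across organs (as
   observed experimentally, where shoot and root slopes differ by only a
   few percent); a fully well-mixed allocation would push the N-poor root
   above the theoretical 2.5 line.

Default true costs are $oN_c = 2.63$, $iN_c = 4.56$, $C_c = 0.2$.

**Allocation.** New growth is 40% root in the glutamine-only treatment
and 35.3% in the mixed treatment. The mixed value is derived, not free:
it is the allocation at which both treatments share the same root
relative growth rate given the 20% uptake premium and the composition
targets. This choice (i) matches the observation that total biomass is
similar across N treatments while glutamine-fed plants have the higher
root mass fraction, and (ii) makes the uptake premium express itself
purely as the uptake-per-root-mass contrast, so the origin-slope ratio of
the two treatments recovers 1.20 exactly in the noiseless limit.

**Initial state.** Plants start at 6 mg shoot / 2.5 mg root dry mass
(lognormal, CV 0.10 — cohorts are size-selected at transfer), at the
treatment's tissue composition and natural-abundance isotopes. With the
default uptake rate of 4 × 10^-5^ g N mg^-1^ d^-1^ this gives a
whole-plant relative growth rate near 0.2 d^-1^, typical of young
rosette-stage plants.

**Re-fixation.** All plants in the labelled atmosphere — labelled and
control alike — receive a small uniform ^13^C excess (default 0.01 atom%)
representing re-fixed respired ^13^CO~2~. Control-based background
correction therefore removes it exactly; the natural-abundance fallback
would leave it in, which is precisely why the experimental design grows
controls.

**Noise model.** `measurement_cv` (default 5%) applies mean-one
multiplicative lognormal noise to each measured quantity: dry mass, C and
N concentration, and the isotopic *enrichment above the calibrated
natural-abundance baseline*. The last point deserves emphasis: an
isotope-ratio mass spectrometer resolves absolute isotope abundance
orders of magnitude more precisely than any biological tracer signal, so
a relative error on the enrichment is the physically sensible model — 5%
relative noise on an *absolute* atom% (~0.1 atom%) would describe an
instrument unable to distinguish natural abundance from a moderately
labelled sample at all, and would swamp small excesses with background
noise unrelated to the labelling signal.

**Truth records.** The generator returns exact per-plant budgets
alongside the noisy measurements. Mass balance holds to machine
precision: glutamine-C uptake = retained + respired glutamine C, and true
CUE equals the cost model at the generating parameters. In the noiseless
configuration (`noiseless()`) every analysis stage inverts the generator
exactly: budgets equal truth, the cost fit returns the generating costs to
numerical precision, the glutamine-only excess-^15^N/total-N slope is
exactly 0.100, and the excess-^13^C/^15^N regressions pass through the
origin with slope 2.5 × CUE.

## What the generator does and does not emulate

It emulates the design (treatments, replication, harvest days,
enrichment), the cost structure, the uptake premium, the organ-level
N-source split, refixation, and realistic measurement noise. It does
*not* emulate:

* the absolute CUE level of the real experiment. New tissue is assigned
  the bulk Table-style C:N composition, giving a C-rich growth increment
  and true CUE near 0.65 (glutamine-only) and 0.59 (mixed); the
  experimentally observed ~0.41–0.43 implies growth increments
  considerably N-richer than bulk tissue. Relative structure — the
  glutamine-only CUE advantage, the cost contrast, all slope
  conversions — is unaffected, and no validation target depends on the
  absolute synthetic CUE;
* nitrogen remobilization or turnover (all N taken up stays where it
  lands), day-varying composition, technical-replicate structure, or
  explicit ^13^CO~2~ gas exchange.

Passing tests on synthetic data therefore certify the *accounting and
estimation machinery*, not the biology of any particular dataset.

# Numerical and design choices

* Regressions of excess ^13^C on excess ^15^N include an intercept (the
  reporting convention for these figures); N-source regressions likewise.
  The cost fit has no intercept, as dictated by the model.
* Degenerate fits (constant predictor, too few points) raise errors
  rather than propagate `NaN`.
* Retention or N-source fractions above 1 (plus a 2% tolerance) warn —
  they indicate an inconsistent background or basis — and are returned
  unclipped.
* Report rounding: retention percentages to integers, concentrations and
  shares to one decimal; shares are computed from unrounded
  concentrations.
* All randomness (generator, bootstrap SEs, uptake-ratio bootstrap) is
  seeded and reproducible; identical config + seed gives byte-identical
  pipeline output.
* Test problem sizes: unit tests run small designs (2–6 plants per
  treatment-day); the replicated recovery experiment uses the full
  default design (117 labelled plants) over 20 seeded replicates, which
  measured a median relative error near 6% for both costs and 2-SE
  coverage of 90–95%.

# Known limitations

* $C_c$ is assumed, not estimated; mis-specifying it shifts both cost
  estimates (their contrast is robust).
* The error distribution of the inorganic cost estimate is heavy-tailed
  at the default design (occasional replicates miss by >20%); median
  error and bootstrap-SE coverage are the meaningful summaries, and
  single runs should be read with their SEs.
* `observed_cue()` is undefined for plants with non-positive ^15^N
  excess; such plants are dropped from the cost fit with a warning.
* The literal-mode %DW product mixes a molar slope with a mass
  concentration (see above); both modes are provided but results differ
  by the 12/14 factor and should not be mixed across studies.
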