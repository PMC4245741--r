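---
title: "Methods: a within-trial stochastic cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a within-trial stochastic cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospicecua)
```

## The decision problem

A hospice day-therapy unit (DTU) offered a multi-disciplinary outpatient
rehabilitation programme to people with active, progressive, recurrent
cancer. A small wait-list randomised trial (36 three-month completers: 20
intervention, 16 control) measured EQ-5D-3L utilities at baseline and
three months and self-reported health-service use over the window. The
question for a commissioner is whether the extra cost of the service buys
enough quality-adjusted life years (QALYs) to be worthwhile at
conventional willingness-to-pay thresholds, and how certain that
conclusion is given so small a sample.

This package rebuilds that evaluation as a tested pipeline. Everything is
driven by arm-level summary statistics (means and variances per resource
category, utility moments, unit costs), so the analysis is fully
reproducible without access to patient records.

## Parameter uncertainty

Every sampled parameter is a distribution fitted from its reported
summary:

* **Resource-use counts and utilities** — gamma, fitted by the method of
  moments in the shape–scale convention (`fit_gamma_moments()`), which
  reproduces the reported mean and variance exactly. Gammas keep counts
  and utilities non-negative and right-skewed, matching the heavy right
  tail of service-use data. A reported variance of zero yields a point
  mass, giving a deterministic limiting run used in the tests.
* **Unit-cost variability** — national unit-cost compendia report no
  variance, so a market-forces factor (MFF, the NHS regional price
  adjustment) multiplies each simulation's total cost in *both* arms:
  one shared uniform draw per simulation. Perfect between-arm correlation
  is deliberate: both arms face the same local price level, and an
  independent multiplier would inflate the incremental-cost spread beyond
  the reported credible interval.
* **Baseline-adjusted QALY differences** — a single normal draw per
  simulation from the reported (mean, SE) of the covariate-adjusted arm
  coefficient.

The "uninformative prior, Bayesian framework" language of this style of
PSA is operationalised the standard way: the fitted distributions are
sampled directly (no MCMC), and 95% credible intervals are empirical
2.5th/97.5th percentiles of the 10,000 draws.

### Two parameterisation modes

`scenario_config(parameter_mode = ...)` selects how per-arm QALY
distributions are built:

* `"table2-moments"` — utilities sampled from gammas fitted to the
  reported utility means and variances (0.447, s² 0.01 control; 0.654,
  s² 0.002 intervention) and converted to QALYs per draw.
* `"ci-implied"` (default) — per-arm QALY distributions fitted to the
  reported per-scenario means and 95% credible intervals via
  `fit_gamma_from_interval()`, which takes sd = interval width / 3.92.

The second mode exists because the reported utility variances imply
per-arm QALY spreads about four times wider than the credible intervals
reported beside the same results: the source evidently summarised a
tighter quantity (plausibly standard errors rather than standard
deviations of the patient-level utilities). Both readings are available;
the interval-implied mode reproduces the published scenario results and
is therefore the default. The two modes agree on every mean (the
incremental QALY in endpoint mode is (0.654 − 0.447) × 0.25 = 0.05175
either way); they differ only in spread, which moves CEAC tails, not
ICERs.

## Costing

Expected 3-month cost per arm is Σ mean use × unit cost (2010–2011 GBP),
with no discounting (no horizon exceeds one year). Two numerical choices
matter:

* **Bundled hospice services.** The hospice supplied a fee of £139.80 per
  DTU attendance. The intervention arm also recorded physiotherapy and
  "other" service contacts *delivered at the hospice during those
  attendances*. Pricing them on top of the attendance fee double-counts
  about £122 per patient and is irreconcilable with the trial's own
  reported deterministic intervention total (£1,775: we compute £1,780
  without them, £1,901 with). The default category registry therefore
  flags `hospice_physiotherapy` and `other_hospice` as bundled — reported
  in breakdowns as memo rows, excluded from totals and from PSA sampling.
  `load_trial_inputs(bundled = character(0))` restores full pricing.
* **MFF bounds.** Not reported. The defaults U(1.00, 1.17) give a mean
  multiplier of 1.085, the ratio of the probabilistic to the
  deterministic per-arm expected costs (both arms give the same ratio),
  and sit inside the realistic range of English MFF values. They are
  config-overridable; conclusions about means scale linearly in the mean
  multiplier.

Two reported deterministic cells are irreproducible from the same
report's own inputs and are left as discrepancies rather than forced:
the control "combined other" expected cost (reported £101; 1.75 × £66.09
= £115.66) and the control physiotherapist cell (reported £34;
1.81 × £18.50 = £33.49).

## QALY methods and extrapolation

Three months is exactly 0.25 years (the reported tables only reconcile
under this convention: 0.447 × 0.25 = 0.112).

* **Endpoint** (base case) credits the 3-month utility for the whole
  window: an optimistic reading that front-loads all benefit.
* **AUC** assumes linear change from baseline: Q = (u₀ + u₃ₘ)/2 × 0.25.
  Baseline utilities were never reported; in summary mode the package
  uses 0.513 (control) and 0.594 (intervention), back-solved so the
  trapezoid reproduces the reported 3-month AUC QALYs (0.120, 0.156).
  They are labelled derived wherever they appear.
* **Baseline-adjusted** regresses individual QALYs on arm and baseline
  utility (OLS via `stats::lm`, cross-checked in the tests against an
  explicit normal-equations solve). With the trial's baseline imbalance
  this is the most conservative method: the 3-month difference shrinks
  from 0.052 to 0.008 QALYs.

Extrapolation holds each arm at its 3-month utility, so the between-arm
difference observed at 3 months is maintained: QALY(h) = Q₃ₘ + u₃ₘ ×
extra/12, and the difference grows linearly at Δu/12 per month. No
additional cost difference accrues after 3 months. Survival through the
horizon is assumed throughout — there is no mortality model, a real
limitation for this population. Intervention-arm extrapolated AUC QALYs
reported by the source increment by ≈0.157 per quarter rather than
0.654 × 0.25 = 0.1635; whether utilities or QALY draws were extrapolated
there is unknowable, so the interval-implied mode fits each horizon's
reported distribution directly instead of guessing.

## The Monte-Carlo engine

`run_psa()` is a deterministic function of (seed, config, inputs). Each
sampled parameter draws from its own substream whose seed is derived by
hashing the global seed with a stable label (`"cost/control/gp_appointment"`,
`"mff"`, ...), so adding or removing one category never perturbs the
draws of any other — a property the tests assert directly. Draws
persist as one-row-per-simulation CSV with a JSON manifest (config echo,
fixture MD5s, package version); rebuilding the config from the manifest
reproduces the draws bit-for-bit.

Limitations by construction: resource-use draws are independent across
categories and arms (no correlation structure was reported), and plain
Monte-Carlo is used (no variance reduction), matching the described
workflow.

## Decision outputs

The ICER is the ratio of *mean* increments — never the mean of per-draw
ratios, which is unstable when ΔQ draws approach zero. Negative ratios
are uninterpretable, so non-positive mean ΔQ yields a quadrant label
(dominant / dominated / SW) instead of a number. CEAC probabilities use
strict NMB > 0 (a tie counts against the intervention; at the reported
thresholds no draw can sit exactly on the boundary, so the choice is
inconsequential but fixed). The default willingness-to-pay grid runs £0
to £50,000 in £500 steps, covering the £20,000–£30,000 NICE band. EVPI
per person is E[max(NMB, 0)] − max(E[NMB], 0), the standard two-option
form with the comparator as reference.

## The synthetic cohort generator

`generate_cohort()` emulates the trial the analysis assumes: two arms
(16/20 completers by default), baseline and 3-month utilities from beta
distributions moment-matched on the EQ-5D UK tariff range [−0.594, 1]
(betas respect the tariff ceiling where gammas would not), per-category
counts from a Poisson-gamma (negative binomial) matched to the target
mean/variance, and 12% completely-at-random dropout (41 randomised → 36
completers; dropout was reported as independent of the intervention).

What it does *not* emulate: the reported count summaries are all
*under*-dispersed (variance < mean in every category), which a
Poisson-gamma mixture cannot represent, so those categories fall back to
Poisson with a logged message and the generated count variances equal
their means. Mean recovery — the property the costing pipeline actually
consumes — is exact to Monte-Carlo error and is asserted at n = 10,000
per arm. A green generator test therefore establishes that the
summary-statistics path and the patient-level path agree in their
first moments, not that the generator reproduces the trial's full
dispersion structure. At trial scale (16/20) repeated seeds produce
material between-arm baseline imbalance, which is what gives the
baseline-adjustment path real work to do in tests.

## Known irreproducibilities

Carried as documented discrepancies, asserted nowhere:

* The reported gamma (alpha, beta) pairs printed beside the mean/s²
  columns do not reproduce those means under any standard convention
  (e.g. (29.45, 0.02) ⇒ mean 0.589, not 0.447); the moments fit is
  canonical.
* The reported intervention deterministic rows sum to £1,815, not their
  own reported £1,775 total.
* The reported 3-month baseline-adjusted ICER (£94,748) is not the ratio
  of its own reported row (735/0.008 = £91,875); unrounded means were
  presumably used. Adjusted-mode ICERs are checked for order of
  magnitude only.
* The reported AUC 3-month CEAC value at £20,000 (42.9%) is unreachable
  from the same report's printed moments: the implied mean net benefit
  is ≈ −£15 while its standard deviation is at least the incremental-cost
  spread (≈£270) under any correlation structure, forcing a probability
  near 50%. The pipeline computes ≈51% and reports it honestly.

```{r example}
inputs <- load_trial_inputs()
draws <- run_psa(scenario_config("auc", horizon_months = 6,
                                 n_sims = 2000, seed = 1), inputs)
summarise_psa(draws)
```
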