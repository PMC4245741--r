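# hospicecua

Stochastic cost-utility analysis of an outpatient rehabilitation service
for people living with and beyond cancer, delivered in a hospice
day-therapy unit (DTU) and evaluated against usual care in a small two-arm
wait-list randomised trial (36 completers: 20 intervention, 16 control).
The package is for health economists who want to reproduce, probe or
extend a within-trial probabilistic sensitivity analysis (PSA) where every
input is an arm-level summary statistic: no patient-level data are
required, and a synthetic patient-level generator closes the loop for
end-to-end testing.

## The model

Each model parameter is a probability distribution, not a point estimate.
Resource-use counts and utilities with reported mean m and variance s² are
gamma distributions fitted by the method of moments in the shape–scale
convention,

    shape = m² / s²,   scale = s² / m,

so the fitted distribution reproduces both moments exactly. Per
simulation, one count is drawn per resource category per arm, priced at
its national or hospice unit cost (2010–2011 GBP), and the arm totals are
weighted by a single shared market-forces-factor draw
U(1.00, 1.17) representing regional price variation. QALYs over the
3-month trial window come from one of three methods:

- **endpoint** (base case): Q = u₃ₘ × 0.25 — all benefit credited
  immediately;
- **auc**: Q = (u₀ + u₃ₘ)/2 × 0.25 — linear change between baseline and
  3 months;
- **baseline_adjusted**: the between-arm difference is the arm coefficient
  of an OLS regression of individual QALYs on arm and baseline utility,
  sampled as a normal (mean, SE) draw.

Benefit maintained beyond the trial adds u₃ₘ × extra/12 QALYs per arm
(the 3-month difference carried forward); costs are never extended and
never discounted. Decision outputs are the ICER of the mean increments
ΔC̄/ΔQ̄, net monetary benefit λ·ΔQ − ΔC, cost-effectiveness acceptability
curves (fraction of simulations with NMB > 0 across λ), plane quadrant
shares, and per-person EVPI.

## Worked example

```r
library(hospicecua)
inputs <- load_trial_inputs()
draws  <- run_psa(scenario_config("endpoint", n_sims = 10000,
                                  seed = 20140558), inputs)
summarise_psa(draws)
#> PSA summary over 10,000 simulations (95% credible intervals)
#>   control cost: £1,211 (£882 to £1,611)
#>   intervention cost: £1,930 (£1,551 to £2,371)
#>   control QALYs: 0.112 (0.102 to 0.123)
#>   intervention QALYs: 0.164 (0.160 to 0.169)
#>   incremental cost: £718 (£197 to £1,240)
#>   incremental QALYs: 0.052 (0.041 to 0.063)
#>   ICER: £13,787 per QALY
ceac(draws, 20000)
#>     wtp probability
#> 1 20000      0.8694
```

Read: the service costs about £720 more per patient over 3 months and
yields 0.052 extra QALYs, an ICER of about £13,800 per QALY — under the
conventional £20,000 NICE threshold, but with wide uncertainty (87% of
simulations cost-effective at £20,000 under the crude endpoint method,
far fewer under the more conservative QALY methods; see
`analysis/04_scenario_grid.R`).

The `analysis/` scripts run the full workflow in order: parameter
fitting, deterministic costing, the base-case PSA, the 3-method ×
4-horizon scenario grid, CEAC curves and the synthetic-cohort
cross-check, writing tables under `results/`.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from the shipped
summary-statistic fixtures — the 10,000-draw base case, the AUC scenarios
at 3/6/12 months and the baseline-adjusted scenarios at 3/6/12 months —
and writes the recomputed incremental cost, incremental QALYs, ICERs and
CEAC probabilities at £20,000/QALY as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
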