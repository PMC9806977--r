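# trialcea

Trial-based cost-effectiveness analysis for two-arm mental-health service
trials, with bootstrap uncertainty and a fully synthetic trial generator.

## The problem this package addresses

Task-shared depression services in low- and middle-income settings are
typically evaluated in small randomized trials (tens of participants per
arm) that collect item-level instruments — the PHQ-9 for depression
symptoms and the WHODAS-12 for functioning — alongside self-reported
service use and program-level implementation (training and supervision)
costs. Turning those raw inputs into decision-ready economics requires a
chain of steps that are easy to get subtly wrong: disability mapping,
QALY integration, amortized costing, imputation of dropout, ratio
statistics, and resampling uncertainty. `trialcea` packages that chain as
tested, reusable components for health economists and trial statisticians.

## The model at the core

For participant *i* with health status *h_i(t) ∈ [0,1]* measured at months
0, 3 and 12 (status = 1 − disability index, where the disability index is a
preference-weighted linear map of eight WHODAS items plus sociodemographic
covariates, clamped to [0,1]):

- **QALYs**: trapezoidal area under the curve,
  `QALY_i = (1/12) ∫ h_i(t) dt` over the 12-month horizon, so at most 1.
- **Costs**: per-participant cost = amortized per-user implementation cost
  (straight-line over a 5-year horizon across projected annual users) plus
  Σ quantity × unit cost over service-use records, in Int$2020.
- **ICER**: with program totals `C_a`, `E_a` per arm,
  `ICER = ΔC / ΔE = (C_TP − C_ST) / (E_TP − E_ST)`, reported at full
  precision with its cost-effectiveness-plane quadrant. A per-participant
  variant uses median cost differences over mean effect differences.
- **Missing data**: chained equations with predictive mean matching
  (m = 20, 5 donors, 10 sweeps), implemented from scratch; imputed values
  are always observed donor values.
- **Uncertainty**: nonparametric paired bootstrap — participants resampled
  within arm with replacement, (cost, effect) pairs kept intact — with the
  middle 95% of replicate ICERs as the confidence interval, threshold
  fractions at 1× and 3× GDP per capita (Int$4009 / 12,027), and a
  net-monetary-benefit acceptability curve `P(λ·ΔE − ΔC > 0)`.

A synthetic trial generator (`generate_trial()`) emulates the statistical
world such analyses assume — arm-differential latent severity trajectories
discretized to item responses, right-skewed gamma costs coupled to
severity, monotone missing-at-random dropout — with *analytic* ground
truth (`ground_truth()`), so every downstream stage is testable end to end
without any external data.

## Worked example

```r
library(trialcea)

cfg <- trial_config()                       # 60/arm, 15%/23% dropout, seed 2025
ds  <- apply_missingness(generate_trial(cfg), cfg)
an  <- analyze_trial(ds, B = 1000, n_imputations = 20, seed = 2025)

an$results$qaly_total
#> CEA result (program-total, QALY)
#>   delta cost:   12826.66 Int$
#>   delta effect: 2.5477 QALY
#>   ICER:         5034.63 Int$ per QALY (quadrant NE)

round(an$ci_qaly)
#> lower upper
#>  3531  9377

an$threshold_fractions
#>  4009 12027
#> 0.130 0.992

ground_truth(cfg)$implied_icer
#> [1] 4384.023
```

Reading: under the default synthetic world the intervention arm costs
Int$12,827 more in program totals and gains 2.55 QALYs, an ICER of about
Int$5035 per QALY — a noisy estimate (n = 60/arm) of the configuration's
analytic truth of Int$4384. The bootstrap places the ICER between roughly
Int$3500 and Int$9400; 13% of replicates fall under the 1× GDP threshold
and 99% under 3× GDP, so the intervention is very likely cost-effective
but unlikely to be *highly* cost-effective at these thresholds.

`run_pipeline(cfg, out_dir = "out")` additionally writes the cost-profile
and incremental tables (CSV), trajectory/CE-plane/CEAC figures (SVG), the
simulated input CSVs, and a manifest with digests of every output.

## Package layout

- `R/config.R` — configuration objects (trial world, mapping coefficients,
  unit costs, implementation ledger, thresholds)
- `R/synthetic-data.R` — trial generator, MAR dropout, analytic ground truth
- `R/outcomes.R` — PHQ-9/WHODAS scoring, disability mapping, QALY AUC
- `R/costing.R` — service costs, amortization, currency conversion, profiles
- `R/imputation.R` — chained-equation PMM imputation and pooling
- `R/cea.R`, `R/uncertainty.R` — ICERs, bootstrap, CIs, CEAC
- `R/reporting.R` — pipeline orchestration, tables, figures, manifest
- `vignettes/methods.Rmd` — the methods and design-choices vignette
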