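---
title: "Methods: trial-based cost-effectiveness analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## Scope and model

`trialcea` evaluates a two-arm trial of depression services — a standard
treatment (ST) comparator versus standard treatment plus a psychological
intervention (T+P) — from the societal perspective in 2020 international
dollars. The estimand is the incremental cost-effectiveness ratio (ICER)
of T+P over ST, with QALYs as the primary effect measure and 12-month
PHQ-9 change as the secondary one.

**Health effects.** PHQ-9 items (nine items, 0–3) are summed to a 0–27
severity score, with a score of 10 or more flagged as indicative of
depression. WHODAS-12 items (0 "none" to 4 "extreme") plus
sociodemographic covariates enter a linear mapping to a preference-weighted
disability index in [0,1]; health status is one minus that index (1 = full
health, 0 = death). QALYs are the trapezoidal area under the status curve
at months 0, 3 and 12, divided by 12, so a participant can gain at most
one QALY over follow-up. The trapezoid is a deliberate choice: only "area
under the curve" is conventionally specified, and piecewise-linear
interpolation between the three measurement occasions is the standard,
auditable rule. No within-year discounting is applied (horizon ≤ 1 year).

The mapping coefficients shipped by `mapping_coefficients()` are a clearly
labelled **synthetic placeholder** (intercept 0.05, eight equal item
weights of 0.02, a small female-indicator weight). Published
population-specific coefficient sets have exactly this shape — an
intercept, eight of the twelve WHODAS items, covariate weights — and are
accepted verbatim through the same constructor or a YAML config. Because
linear maps can exceed [0,1], the index is clamped and the number of clamp
events is reported (`attr(x, "n_clamped")`); in the default synthetic
world clamping is a rare event, which is also why the generator's analytic
ground truth may ignore it (see below).

**Costs.** Implementation (training and supervision) costs are amortized
straight-line: each ledger line item contributes
`total_cost × arm_share / (horizon_years × users_per_year)` to the
per-user cost of an arm, with a 5-year horizon and a 0% annuitization rate
(no rate is conventionally stated for such programs; the rate is exposed as
an input by giving the ledger explicit horizon and user counts). Service
delivery costs are quantity × unit cost summed within mental and physical
blocks; the societal stance includes traditional healers, transport and
participant time at a configured wage. The default ledger is a synthetic
round-trip fixture calibrated so per-user implementation costs are Int$329
(ST) and Int$617 (T+P); the real administrative ledger behind such numbers
is never public, so the fixture exercises the amortization rule rather than
reproducing source data.

**Missing data.** Analysis-level variables (per-timepoint status and PHQ
total, per-window block costs) are imputed rather than items: imputing the
roughly 40 item columns would be statistically heavier and unverifiable,
while every downstream quantity depends on the data only through these
analysis variables. The imputer is fully conditional specification with
Bayesian-draw predictive mean matching, written from scratch (no `mice`
dependency): per variable, coefficients are drawn from the approximate
posterior of a ridge-stabilized linear regression on all other analysis
variables plus arm, age and sex, and each missing cell borrows the
observed value of one of the 5 nearest predicted-mean donors. Defaults —
m = 20 imputations, 10 sweeps, 5 donors — follow field convention where
the method description leaves them open. Pooled quantities are means
across completed datasets with within/between-imputation variances
reported; the ICER is formed as the ratio of pooled means (not the mean of
per-dataset ratios), because Rubin's rules are ill-defined for ratio
statistics.

**Uncertainty.** The bootstrap resamples participants within arm with
replacement at the original arm sizes, keeping each participant's (cost,
effect) pair intact, and is applied to the ensemble-averaged
per-participant values (whether the original analysis bootstrapped within
each imputed dataset or on pooled values is not knowable from the method
description; the ensemble-average default is cheaper and the bootstrap
input is an explicit argument, so per-dataset bootstrapping remains
available to callers). The 95% interval is the middle 95% of replicate
ICERs by linear interpolation between order statistics (quantile type 7).
When replicates straddle zero incremental effect the ratio's order breaks
down across quadrants, so `percentile_ci()` refuses rather than returning
a misleading interval and directs users to the acceptability curve.
Threshold fractions and the CEAC are computed through net monetary benefit
`λ·ΔE − ΔC > 0`, which coincides with `ICER < λ` in the northeast quadrant
but stays well defined everywhere. The replicate loop consumes one seeded
stream in per-replicate blocks, so enlarging B never changes earlier
replicates.

## The synthetic world

The generator's defaults encode the trial conditions the pipeline was
built around: 60 participants per arm; loss to follow-up of 15% (ST) and
23% (T+P); mean PHQ-9 changes of −5.54 and −9.60 points at 12 months; mean
per-participant QALYs of about 0.776 and 0.826; per-user implementation
costs of Int$329/617; mean mental-health delivery costs of Int$18.7/22.4;
and ST physical-care costs well above T+P's (traditional healing and
physical visits), calibrated so the expected incremental program cost is
Int$12,973 at 60 per arm. The implied analytic ICER of the default world
is Int$4384 per QALY.

Mechanics and the reasoning behind them:

- **Items from latent severity.** Each participant carries normal person
  effects for depression and disability; an item response is the latent
  arm-by-time mean plus person effect plus item noise, rounded and clamped
  to the instrument range. This induces realistic within-scale item
  correlation, which matters because scoring and mapping operate on items.
  The latent means are *solved* (by inverting the expectation of the
  rounded, clamped normal) so configured trajectory means are exact in
  expectation — making the analytic `ground_truth()` genuinely closed-form
  rather than simulation-based.
- **Noise scales.** The PHQ item noise (SD 1.40 on the 0–3 item scale) is
  chosen so the per-person 12-month change SD is about 6 points,
  consistent with arm-level change standard errors of 0.77/0.59 at n = 60;
  the person effect (SD 0.30) is shared across timepoints so change scores
  partly cancel it. WHODAS noise (person SD 0.35, item SD 0.70) yields a
  per-person QALY SD near 0.06, an order of magnitude below the mean — the
  compression one expects from a weighted 8-item map with small weights.
- **Costs.** Service-use quantities are gamma draws (shape 0.8) per
  category and window, giving the right skew typical of health costs
  (medians below means). Quantities are continuous units/hours rather than
  integer counts so expected costs stay exactly analytic. A mean-one
  lognormal multiplier in the participant's disability z-score couples
  severity to cost (sicker ⇒ costlier) without changing any expectation;
  the coupling strength is a config parameter because the true joint
  distribution of costs and effects within person is not characterized
  anywhere.
- **Dropout.** Missing-at-random by construction: the dropout probability
  is logistic in arm and baseline PHQ (log-odds slope 0.08 per point),
  with the arm intercept calibrated on the realized baseline sample so the
  mean probability equals the configured 15%/23%. Dropout is monotone
  (lost at 3 months ⇒ missing at 12), matching the loss-to-follow-up
  framing; baseline is never missing.
- **Reproducibility.** One master seed; each participant draws from a
  deterministically derived sub-stream, so datasets are byte-identical
  under a fixed seed and individual participants can be regenerated.

**What a green test does and does not establish.** The generator emulates
the *statistical structure* the analysis assumes — trajectories,
correlation, skew, MAR dropout — with known truth. Green end-to-end tests
therefore establish that the pipeline is internally correct and unbiased
under that structure. They do not establish anything about real
populations: real WHODAS mappings have unequal weights, real missingness
may be non-random, real service-use is lumpier than gamma draws, and real
implementation ledgers contain allocation judgments the synthetic fixture
sidesteps.

## Numerical choices and degenerate inputs

- ICERs are computed before any rounding and reported at full precision;
  reports additionally print values rounded in the conventional style
  (costs to whole Int$, QALYs to 2 dp). Dividing already-rounded table
  entries can differ from the full-precision ratio in the third
  significant figure, which is why the reporting layer keeps both.
- A zero incremental effect yields an explicit undefined-ICER status, not
  a number. Dominance (more effect, less cost) is labelled rather than
  headline-reported as a negative ICER.
- PHQ-based ICERs keep the native sign (negative = cost per point of
  *change* when change is an improvement), with the positive "per point
  decrease" restatement available in reports.
- Validation errors (out-of-range items, statuses outside [0,1]) are
  classed separately from configuration errors (absent coefficients,
  unpriced categories), and scoring never imputes silently.

## Known limitations

- The percentile interval's refusal when replicates straddle zero effect
  means very small or null effects get no ratio CI by design; coverage
  statements condition on the interval existing.
- With the default effect size (ΔQALY ≈ 0.049 per participant) and
  realistic outcome noise, the Monte-Carlo relative SE of a single
  pipeline ICER is ≈ 4% even at 2000 participants per arm, so tight
  recovery checks on one seed carry residual seed-dependence; the package's
  bias properties are instead pinned by the analytic ground truth and the
  null-world tests.
- Equity subgroup analysis, alternative utility instruments, non-health
  productivity effects and payer-perspective costing are out of scope.
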