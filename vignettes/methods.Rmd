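---
title: "Model and methods: second-line gastric cancer cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling conventions behind `gc2lcea`: what the
Markov cohort model assumes, which knobs matter, how the numerically
ambiguous points were resolved, and what the synthetic-data machinery does
and does not establish.

## States, cycles and event ordering

The cohort starts entirely progression-free (PF) on its second-line
treatment and moves monthly among PF, progressive disease on third-line
best supportive care (PD), and death by cancer, severe treatment toxicity,
or background causes. Within each monthly cycle events are ordered:

1. **Deaths from PF.** Cancer-specific mortality, background (all-cause)
   mortality and — during the toxicity window — treatment-related death
   combine as independent risks:
   `1 − (1 − p_cancer)(1 − p_allcause)(1 − p_trAE)`. Deaths are attributed
   to causes in proportion to the single-cause probabilities.
2. **Progression.** Survivors leave PF with the schedule probability for
   that cycle plus, in the window, the discontinuation probability (capped
   at 1). Discontinuers join PD: after stopping treatment patients receive
   third-line supportive care like progressors.
3. **Deaths from PD.** Patients progressed before this cycle die with
   `1 − (1 − p_cancer,3L)(1 − p_allcause)`; new arrivals join PD at cycle
   end and face death from the next cycle.

Mass conservation is asserted at every step to 1e−12 and the engine fails
loudly on any negative fraction.

**Cycle–month convention.** Transition inputs are quoted per month range
with months counted from 0 at treatment start, so month *m* is simulated by
cycle *m + 1*: a "months 0–1" segment covers cycles 1–2, "months 2–9"
cycles 3–10, "months 10+" cycles 11 to the horizon. We adopted this reading
after checking both candidates against the published outcome table this
package reimplements: mapping "months 0–1" to a single cycle inflates the
pembrolizumab-for-all strategy by roughly 25% of its cost and 0.15 life
years and misorders the efficiency frontier, while the convention used here
reproduces that strategy and the frontier structure almost exactly.

**Toxicity window.** Adverse events, discontinuation and toxicity deaths
are confined to the first 6 cycles (`ae_window`), reflecting the early
onset of most treatment-related events; late-onset toxicity is out of
scope. Event fractions are recorded against end-of-cycle PF occupancy — the
patients actually receiving treatment that month — and are zero afterwards.

## Rewards, discounting, costs

Rewards follow post-transition state occupancy: cycle 0 (everyone PF)
accrues nothing except the one-time biomarker test cost, and no half-cycle
correction is applied. Costs and utilities are discounted at
`(1 + 0.03)^(−cycle/12)`; life years are undiscounted. Discounting is
applied from the first cycle; mid-cycle discounting would change QALYs by
well under 1% and was not adopted.

Per PF cycle a strategy pays drug acquisition + administration + a
follow-up bundle (general practice $179.39, oncology $355.35, radiology
$284.00). In the supportive-care-only arm the "drug" component is the
routine home-care rate ($5,169.60/month) — supportive care is itself the
treatment there, and the published total cost of that strategy is only
reproducible under this reading. Every PD cycle pays the home-care rate.
Grade 3/4 toxicity costs enter through hospitalisation. Two gatings are
implemented (`hospitalization_mode`):

* `grade34` (default): the hospitalised fraction equals the grade 3/4
  event fraction, per arm;
* `claims`: a uniform monthly hospitalisation probability of 0.0440
  replaces the arm-specific grade 3/4 rate.

The default was chosen because it tracks the published strategy costs more
closely (combination-therapy totals within ~3–5% versus ~10% under
`claims`); the report manifest records the active mode.

Utilities are 0.622 (PF) and 0.362 (PD) with per-cycle toxicity decrements
while events occur; per-cycle utility is floored at zero with a warning if
decrements ever exceed state utilities.

## Survival-curve calibration

`fit_piecewise_probs()` converts a Kaplan–Meier curve into per-cycle
probabilities: within each breakpoint segment, survival under a constant
monthly probability *p* declines geometrically, so log-survival is linear
with slope `log(1 − p)`. The slope is estimated by least squares on
log-survival, **weighted by the survival fraction** as a proxy for the
number still at risk — unweighted fitting lets the last few, nearly empty
KM steps dominate the tail segment. With only segment-boundary
observations the estimator reduces to the geometric ratio
`1 − (S_end/S_start)^(1/duration)`. Fitting in survival space instead was
rejected: linear-in-survival fits can cross zero and do not yield
per-cycle probabilities.

Censoring in an input curve is ignored at fitting time (the curve is taken
as the estimate); the synthetic generator produces censoring precisely to
stress this. Degenerate inputs fail with specific errors: rising survival,
curves hitting zero before a segment ends, or segments not covered by the
curve. Beyond the fitted range the last segment's probability is held
constant to the horizon, with background mortality added by the engine —
no parametric tail model.

An irreducible precision bound applies: a segment entered by only *k*
patients cannot have its probability estimated more precisely than the
binomial error of *k* trials. For the supportive-care schedule at n = 5000
the third segment starts with ~25 patients at risk (SE ≈ 0.05), so
recovery to ±0.03 is impossible there for any estimator; the tests assert
±0.03 where the at-risk set is adequate and an SE-scaled bound where it is
not.

## Synthetic data

`simulate_km()` draws discrete event times from the per-cycle hazards
(matching the model's monthly semantics exactly — not a continuous-time
approximation), applies independent geometric censoring, and returns the
product-limit estimate via the `survival` package. `make_life_table()`
builds a Gompertz-like table `q(age) = q_ref · factor^(age − ref_age)`;
the packaged fixture uses q(60) = 0.0112 (men) / 0.0066 (women) with an
8.5%/year increase over ages 55–70, giving the realistic ~1%/year
background mortality near age 60. It is a synthetic stand-in for national
2014 vital statistics, not published data — a small, explicit tolerance
source, since background mortality is an order of magnitude below the
cancer hazards.

What passing tests therefore show: the engine, accrual, frontier and
calibration machinery are internally correct and recover known generating
processes. What they do not show: fidelity to real trial populations —
real KM curves have informative censoring, non-proportional tails and
digitisation error that the generator does not emulate.

## Sensitivity-analysis parameterisation

The sensitivity table drives both the tornado and the probabilistic
analysis (PSA):

* **Costs** (totals per month of PF treatment, i.e. drug + administration
  + follow-up): gamma distributions moment-matched to the base value and
  the quoted SD. Setters rescale the drug + administration component so
  the follow-up bundle stays shared across arms; the pembrolizumab price
  is one parameter across its three biomarker schedules.
* **Probabilities quoted as ±30%:** one multiplier per schedule per draw
  (preserving the piecewise shape), normally distributed with the ±30%
  band read as a 95% interval (SD ≈ 0.153), truncated at zero and capped
  so no probability exceeds 1. The MSI-H progression multiplier is uniform
  on [0.7, 1.3], as quoted.
* **MSI-H prevalence:** beta, moment-matched to mean 0.10, SD 0.05.
* **Utilities/disutilities:** uniform on their printed ranges.

Draws are independent across parameters (no correlation structure is
specified anywhere). Cost-effectiveness per draw is classified by the sign
of the incremental net monetary benefit of the stated pairwise comparison
at $100,000/QALY, not by re-deriving the full frontier per draw. The
tornado varies one table row at a time at its bounds; the "all other
strategies" progression row moves all non-MSI schedules jointly.

`threshold_price()` bisects the monthly drug-acquisition price to $1,
verifying first that the ICER actually increases in price over
[0, base price] and reporting a non-crossing bracket rather than
extrapolating. `prevalence_sweep()` re-evaluates a biomarker strategy over
a prevalence grid; costs and QALYs are exactly linear in prevalence
(mixture linearity), so ICERs stay nearly constant.

## Frontier construction

Strategies are sorted by ascending cost (ties broken by QALYs, then name,
deterministically, with a logged message). Strict dominance removes
strategies beaten on both axes; extended dominance then removes interior
points until ICERs increase strictly along the chain — the standard convex
hull. The implementation is cross-checked in the tests against a
brute-force oracle (pairwise dominance plus two-point blends). The
published outcome table lists scenarios in a different row order; output
here is always cost-ascending.

## Problem sizes

Default analyses run the 60-cycle cohort model per arm (milliseconds), the
PSA at 10,000 draws per comparison (about a minute each), and the
calibration-recovery experiment at 100 seeds × 5,000 patients; the whole
suite completes in a few minutes on one core.

## Known limitations

* The printed monthly inputs cannot fully regenerate the published outcome
  table: the paclitaxel progression probabilities bound mean
  progression-free time at ~4.8 months even with zero mortality, yet the
  published life-year/QALY pair for that strategy implies ~5.8. The
  taxane-based strategies therefore sit ~0.08–0.12 life years below their
  published values here, and three off-frontier dominance labels permute
  (strict vs extended) as a direct consequence of the resulting QALY
  ordering. Frontier membership, the three frontier ICERs, and the
  supportive-care and pembrolizumab-for-all rows reproduce within a few
  percent.
* Under the quoted PSA distributions, the MSI-H-guided strategy's ICER is
  structurally the ratio of monthly drug cost to monthly utility gain and
  essentially never crosses $100,000/QALY; published Monte Carlo results
  with ~13% crossings imply wider survival uncertainty for the MSI-H
  subgroup than the printed ±30% band.
* No late-onset toxicity, no treatment beyond progression, no
  individual-level heterogeneity, US payer perspective only, and utilities
  are taken as given rather than re-derived from performance-status
  distributions.
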