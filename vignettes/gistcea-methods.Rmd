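---
title: "Methods: a Markov cost-utility model of adjuvant imatinib for resected high-risk GIST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-utility model of adjuvant imatinib for resected high-risk GIST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistcea)
```

## The decision problem

Patients whose gastrointestinal stromal tumour (GIST) is completely
resected but classified as high-risk frequently relapse with metastatic
disease within a few years. One year — or, with stronger trial evidence,
three years — of adjuvant imatinib (400 mg/day) delays recurrence, but at a
2014 Thai reference price of 3,659.40 THB per 400 mg tablet the drug cost
is substantial. The package evaluates, from a societal perspective in 2014
THB, six strategies that differ in the adjuvant duration (none, 1 year,
3 years) and in the drug sequence given when disease recurs or progresses
(imatinib, sunitinib, best supportive care, in the combinations labelled
options 1, 2.1, 2.2, 3.1, 3.2 and 4 — see `make_strategy()`), and asks
whether any of them is cost-effective at the Thai willingness-to-pay (WTP)
threshold of 160,000 THB per quality-adjusted life year (QALY).

## Model structure

The engine is a deterministic Markov cohort model with a 1-month cycle and
a lifetime horizon (480 cycles, age 60 to 100; the residual alive mass at
the horizon is below 0.1% in every strategy). The conceptual three states —
no recurrence, recurrence, dead — are expanded to eight, because the
treatment sequence after recurrence depends on the patient's adjuvant
history:

* `NoRec_NoAdj`, `NoRec_OnAdj`, `NoRec_Completed`, `NoRec_Discontinued` —
  recurrence-free, split by adjuvant status;
* `Rec_Imatinib`, `Rec_Sunitinib`, `Rec_BSC` — metastatic recurrence, by
  current treatment line;
* `Dead` — absorbing.

Monthly exits from the recurrence-free states are recurrence (year-banded
baseline probability, hazard-ratio-adjusted while on adjuvant therapy),
adjuvant discontinuation for toxicity (banded), and death (banded
GIST-specific mortality combined multiplicatively with age-specific
background mortality, i.e. independent competing risks within a cycle). At
the last adjuvant cycle the remaining on-treatment mass moves to
`NoRec_Completed`. Recurrence from `NoRec_NoAdj` or `NoRec_Completed`
enters the first line of the strategy's post-adjuvant sequence; recurrence
from `NoRec_OnAdj` or `NoRec_Discontinued` enters the during-adjuvant
sequence. Recurrence-state exits are progression to the next line and
line-specific death.

Two structural choices deserve emphasis:

* **Discontinued patients follow the during-adjuvant pathway on
  recurrence.** They stopped imatinib for toxicity, so re-treatment with
  imatinib is excluded; their recurrence risk reverts to the no-adjuvant
  baseline.
* **The treatment effect exists only while the drug is taken.** The hazard
  ratio (0.29 for the 1-year arm, 0.133 for the 3-year arm) is applied to
  the baseline recurrence probability only for cycles inside the adjuvant
  window, through the constant-hazard transform `1 - (1 - p)^HR`. This is
  deliberately conservative for the adjuvant arms.

## Inputs and their distributions

Every input lives in `inst/extdata/parameters.yaml` with a mean, SE,
distribution family and role; `load_parameters()` validates ranges and
completeness, and `export_parameters()` writes the resolved set for audit.
Probabilities and utilities get Beta distributions, costs and visit rates
Gamma, hazard ratios Lognormal; all are fitted by the method of moments
(`beta_from_moments()`, `gamma_from_moments()`, `lognormal_from_moments()`)
because the sources report mean/SE pairs only, not CIs on transformed
scales. The lognormal is matched on the natural (HR) scale, where the SEs
are reported; the log-scale parameters are derived, not assumed. Inputs
with SE 0 (`family: fixed`) are excluded from probabilistic variation.

The 3-years-vs-none hazard ratio is not directly observed in any trial: it
is a Bucher indirect comparison of the 1-year-vs-none effect with the
3-years-vs-1-year effect (`bucher_combine()`), multiplying the point
estimates and adding log-scale SEs in quadrature. The shipped input
(0.133, SE 0.0543) is treated as authoritative; `bucher_combine()`
reproduces the point estimate (0.29 × 0.46 = 0.1334) and serves as a
cross-check. The SE cannot be recomputed exactly because the per-trial
subgroup SEs behind it are not available.

Year-banded probabilities are read as piecewise-constant: the value
reported "at year k" holds from the month after the previous reported year
through month 12k, and the last value holds for the remaining horizon
(recurrence: months 1–12 / 13–36 / 37+; GIST death: 1–12 / 13–36 / 37–60 /
61–84 / 85+). This is the simplest reading and the one the band labels in
the configuration file document.

Three monitoring-cost cells in the source table are ambiguous concatenated
digit strings; the configuration carries both parses, defaults to the
larger-mean parse, and `load_parameters(cost_parse = "small")` selects the
alternative. Lifetime results move by well under 2% because drug
acquisition dominates costs. The sunitinib monthly cost (82,173 THB, which
embeds a 4-weeks-on/2-weeks-off schedule) is likewise carried as an input;
`monthly_drug_cost()` exists for audit arithmetic (it reproduces the
imatinib 111,306 THB/month exactly and shows the sunitinib figure is not
plain price-times-days).

## Background mortality

The model needs an age-indexed all-cause life table for the Thai general
population, which is not part of the shipped inputs. `make_life_table()`
generates a synthetic Gompertz stand-in, `q(x) = 1 - exp(-a e^{bx})` with
defaults a = 2e-5, b = 0.092 (q(60) ≈ 0.0050, q(80) ≈ 0.031). The
calibration keeps background mortality a secondary influence — switching
it off entirely moves option-1 discounted life expectancy by about 7% —
so that the disease pathway, whose inputs are fully specified, drives the
results. It is labelled synthetic throughout: any real national life table
can be supplied as a CSV via `read_life_table()` and is used identically
(annual probabilities converted to monthly under a constant within-year
hazard). Because the stand-in is not the real Thai table, absolute lifetime
quantities carry that uncertainty; incremental comparisons between
strategies are far less sensitive to it.

## Rewards, discounting and outcomes

Each state has a monthly cost (drug acquisition + monitoring +
adverse-event treatment on adjuvant + direct non-medical visit costs) and
an annual utility weight; `state_rewards()` assembles them and documents
the composition. Rewards accrue to the state occupied at cycle start, with
no half-cycle correction, and are discounted at 3%/year compounded
per month as `(1 + r)^(-t/12)` with t = 0 for the first cycle.
`accumulate()` produces discounted and undiscounted lifetime cost, life
years and QALYs; `efficiency_frontier()` sorts strategies by discounted
cost, removes strict dominance, then iteratively removes extended
dominance until the frontier ICER sequence strictly increases (ties broken
toward inclusion). Discounted life years use the same 3% rate as QALYs.

## Uncertainty and threshold analyses

* **One-way (tornado), `owsa()`:** each uncertain input in turn is set to
  mean ± 1.96 SE on the natural scale, clipped to its support (the source
  material does not state a transformed scale, so the natural scale with
  clipping is used); the discount rate is varied over an explicit 0–6%
  range. The output is the induced ICER range of option 2.2 vs option 1,
  sorted by width.
* **Probabilistic, `run_psa()` / `ceac()`:** 1000 independent draws of all
  uncertain parameters (no correlation structure is imposed, including
  across the bands of one schedule — a documented simplification), each
  pushed through the full cohort model for all six strategies. If a draw
  makes competing exits from a state exceed 1 they are renormalised
  proportionally with a warning; in practice this does not occur at the
  shipped SEs. Acceptability curves report, per WTP value on a default
  grid of 0–3,000,000 by 20,000 THB/QALY, the share of iterations in which
  each strategy has maximal net monetary benefit (`nmb()`), ties split
  equally. A seed is required; there is no silent default.
* **Price threshold, `threshold_price()`:** bisection on the imatinib
  price per 400 mg, rescaling the drug cost of *every* imatinib-dispensing
  state in both strategies (a price cut applies to the drug, not to one
  indication), until the ICER of option 2.2 vs option 1 equals the WTP
  threshold to a relative tolerance of 1e-6. Cohort traces do not depend
  on price, so they are computed once and only reward accumulation is
  repeated; a grid sweep in the test suite confirms the monotonicity the
  bisection relies on, and setting the WTP to the current-price ICER
  recovers the current price to 0.1%.

## Verification strategy

The test suite checks mechanics independently of the engine: miniature
three-state fixtures (`make_mini_fixture()`) carry trace, cost, LY and QALY
oracles written as explicit fractions and are recomputed in the tests by
brute-force loops; short full-model traces are compared against explicit
matrix powers at 1e-12; conservation, monotone death, discounting bounds
and QALY ≤ LY are property-tested over randomly drawn parameter sets; and
neutralising the treatment effect (HR = 1, no discontinuation) makes the
3-year arm reproduce current practice exactly through the adjuvant window.
Distribution fits are verified by moment round-trips at 1e-9 and by
large-sample means. An end-to-end acceptance layer re-derives the headline
quantities (incremental outcomes, frontier ICERs, threshold price, CEAC
probabilities) from scratch; `scripts/acceptance.R` writes them as JSON.

What passing tests do and do not show: the synthetic life table and the
band conventions are this package's own choices where the sources are
silent, so cohort-level absolute quantities (lifetime cost or QALYs of a
single strategy) are reproduced only to within roughly 10–20%, while
closed-form quantities are exact and incremental comparisons are
substantially tighter. The probability that current practice is
cost-effective at 160,000 THB/QALY comes out near 0.9 rather than 1.0
under these conditions: in a minority of draws with high recurrence risk
and a strong treatment effect, the 1-year adjuvant arm's extra drug cost
is offset by avoided recurrence-treatment cost. None of this changes the
decision-level conclusions the model supports: the frontier is
option 1 → 2.2 → 3.2, every adjuvant strategy's ICER is far above the Thai
threshold at the current imatinib price, and cost-effectiveness would
require a price cut of roughly an order of magnitude.

## Problem sizes used in the shipped analyses

The analysis drivers and tests run the full 480-cycle model for all six
strategies, a tornado over all 35 uncertain inputs plus the discount rate,
a 1000-iteration PSA, and bisection to 1e-6 — a few minutes of compute in
total; property tests use shorter horizons (24–120 cycles) and smaller PSA
runs (30–200 iterations) where the property does not require the full
problem size.

## Known limitations

* Cohort-level (no microsimulation); no local-recurrence state; no
  high-dose imatinib line; no budget-impact or equity analysis.
* Background mortality is a synthetic Gompertz stand-in unless a real life
  table is supplied; chart-review GIST mortality and population mortality
  are combined multiplicatively, which may double-count if the former is
  effectively all-cause (a scalar switch disables background mortality for
  sensitivity use).
* PSA draws are independent across all parameters.
* Utilities enter as constant per-state weights; no age adjustment.
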