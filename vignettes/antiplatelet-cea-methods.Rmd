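---
title: "Methods: decision-analytic cost-effectiveness of antiplatelet pretreatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-analytic cost-effectiveness of antiplatelet pretreatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptcea)
```

## The model

`aptcea` implements a three-level decision tree for patients presenting with
unstable angina or non-ST elevation myocardial infarction (UA/NSTEMI) who are
pretreated before coronary angiography with either **DAPT** (aspirin + P2Y12
inhibitor) or **TAPT** (DAPT + GpIIb/IIIa inhibitor):

1. **Strategy** — DAPT or TAPT (the decision node);
2. **Intervention** — PCI, CABG, or medical management, drawn with
   strategy-specific mix weights;
3. **30-day outcome** — no significant event, major bleeding, vascular event
   (stroke or re-infarction), or all-cause death, drawn with
   intervention-specific probabilities.

Each of the 12 terminal pathways per strategy carries two payoffs:

* **QALYs**: life-years extended for the outcome
  (`L = 14.5 / 12.3 / 5.2 / 0` years for no event / bleeding / vascular /
  death) multiplied by an EQ-5D-derived utility coefficient that depends only
  on the intervention's *utility class* — PCI and CABG share one coefficient
  set (0.86 / 0.83 / 0.76 / 0) because the underlying survey data did not
  distinguish them; medical management has its own (0.45 / 0.45 / 0.41 / 0).
* **Cost**: a pathway-specific gamma distribution (or a point mass), sampled
  per patient.

Key structural assumptions, inherited from the source model: no time
discounting (a hook exists in the form of the life-years table, but no
discount rate is applied); patients never move between pathways after
assignment (no Markov extension); heparin is given uniformly in both arms and
therefore cancels; the outcome set is exhaustive, so the no-event probability
is *always* the complement of the three complication probabilities and is
never user-settable.

### A note on the published per-outcome QALY list

The published report quotes per-outcome QALYs of 12.04, 10.31, 3.95 and 0
years. Only the vascular value is consistent with its own inputs
(5.2 × 0.76 = 3.952): 14.5 × 0.86 = 12.47 ≠ 12.04 and
12.3 × 0.83 = 10.21 ≠ 10.31, while 14.5 × 0.83 = 12.035 ≈ 12.04 — which looks
like a transposed coefficient. We compute QALYs from the stated procedure
(life-years × coefficient) rather than hard-coding the internally
inconsistent list; users who want the printed values verbatim can pass them
through the `qaly_override` parameter, which every QALY computation honours.

## What was never published, and how calibration fills it

Two parameter groups the original model must have contained were never
printed: the intervention-mix weights and every cost input (only
strategy-level cost *outputs* appear: DAPT 22,022 ± 18,192 USD, TAPT
49,290 ± 26,588 USD, with effectiveness 11.4 ± 2.1 and 10.4 ± 3.1 QALYs).
Rather than invent clinical numbers, `calibrate_parameters()` reconstructs
both groups by moment matching against those summaries
(`base_case_targets()`):

* **Mix** (`calibrate_mix()`): the per-intervention expected QALYs
  `q_i = Σ_o P(o|s,i) · qaly(i,o)` bound the achievable strategy-level mean;
  one linear constraint on three simplex weights is underdetermined, so we
  return the **maximum-entropy** solution, computed by exponential tilting
  (`w_i ∝ exp(λ q_i)`, with λ solved by root finding so the weighted mean
  hits the target to ≤ 1e-11 years). This is deterministic and reproducible
  without asserting any clinical claim about actual intervention rates.
* **Costs** (`calibrate_costs()`): pathway cost means are severity
  multipliers (CABG > PCI > medical; complications > no event;
  `default_cost_severity()`) rescaled so the probability-weighted mean equals
  the target mean *exactly*. By the law of total variance the mixture
  variance splits into a between-pathway part (fixed once the means are) and
  a within-pathway part; the latter is spread over pathways at a common
  coefficient of variation so the mixture SD also matches exactly. A target
  SD below the between-pathway floor is rejected with the feasible range —
  which is why the default multiplier ratios are modest (1–2.5× across
  interventions, 1–1.8× across outcomes): steeper ratios would put the floor
  above the published TAPT cost SD and make the published targets
  unreachable. Only the ordinal structure of the multipliers is meaningful;
  their scale cancels.

One moment is deliberately **not** matched: the strategy-level QALY SD. Once
the mix reproduces the mean QALY, the QALY spread is fully determined by the
categorical outcome distributions — analytically 2.71 for DAPT (published
2.1) and 3.32 for TAPT (published 3.1). `calibrate_parameters()` and
`verify_calibration()` therefore report this moment with a
`calibrated = FALSE` flag and exclude it from the pass criterion; forcing it
would require distorting the published outcome probabilities.

The headline absolute cost-effectiveness ratios (≈ 1,923 and 4,734 USD/QALY)
are consequently reproduced only *by construction*: the calibrated model
validates the simulation engine against its own analytic moments, not the
original cost inputs, which are unrecoverable.

## The Monte Carlo simulator

`simulate_cohort()` samples patient-level trajectories: intervention ~ mix,
outcome ~ outcome row, cost ~ pathway gamma with
`shape = (mean/sd)²`, `scale = sd²/mean` (point mass when `sd = 0`). The
QALY payoff is deterministic given the pathway, so all QALY variance is
between-pathway — matching the interpretation of the original "10,000 runs"
as patient-level trials rather than parameter draws (the source is ambiguous;
this choice makes the published SDs meaningful). Only costs are stochastic
beyond the categorical draws; probabilities enter through sampling, not as
second-order distributions.

Reproducibility: per-arm (and, in Monte Carlo sensitivity grids, per-cell)
sub-seeds are drawn once from the master seed via `sample.int()` on R's
default Mersenne-Twister, so the two arms are decorrelated and every run is
bit-identical given `(params, n, seed)`. The grouped sampling order
(interventions, then outcomes within intervention, in canonical order) is
part of the determinism contract. The cost-effectiveness ratio is the ratio
of means, not the mean of per-patient ratios — per-patient ratios are
undefined for the death pathway and the published arithmetic is clearly
ratio-of-means. `run_comparison()` adds a Welch two-sample comparison of mean
QALYs, mirroring the original claim of no significant life-expectancy
difference between arms.

## Sensitivity analysis

`two_way_sensitivity()` re-evaluates both strategies on a grid over two
parameters. The source names the varied quantities (bleeding, mortality,
vascular, no-event risks) but publishes no ranges or results, so the defaults
— ±50% around the current value, 21 steps per axis — are this package's own,
fully configurable choice. Renormalization conventions when a probability is
varied (the source is silent): a complication axis moves only the no-event
residual; a no-event axis rescales the three complications proportionally.
Analytic mode uses the exact tree rollback and is deterministic; Monte Carlo
mode uses fixed per-cell sub-seeds.

## The synthetic-data generator

`generate_scenario()` redraws every outcome row from a Dirichlet centered on
the base row (`alpha = concentration × base`), redraws the mix, and jitters
pathway cost means with a unit-mean gamma factor of a given coefficient of
variation. The defaults — concentration 200, cost CV 0.25 — correspond to
the sampling spread of moderately sized (n ≈ a few hundred) clinical trials
and sizeable cost uncertainty; the source gives no interval estimates, so the
concentration parameterizes "how uncertain the literature inputs are" without
asserting a specific CI. `generate_ground_truth_cohort()` emits patient
records from a known truth for end-to-end recovery tests.

What the generator emulates: categorical outcome sampling on valid
simplexes, right-skewed costs, strategy/intervention/outcome structure. What
it does not: patient covariates (age, race — deliberately excluded upstream),
within-pathway QALY heterogeneity, correlation between cost and outcome
severity beyond the pathway means, and non-stationarity of clinical practice.
Passing recovery tests therefore demonstrate statistical self-consistency of
the pipeline, not external clinical validity.

## Numerical choices and problem sizes

* Simplex and mix sums are enforced to 1e-12; mix calibration residual
  ≤ 1e-11 years; interior-vs-vertex decisions in the tilting solver use a
  1e-12 band.
* Full precision is kept internally; rounding happens only in the report
  layer (whole dollars for costs, 1 decimal for QALYs and CERs, 2 for the
  CER ratio) and configs are written at 17 significant digits so they
  round-trip bit-exactly.
* Degenerate inputs are defined, not crashed on: zero mean QALYs flag the
  CER undefined; `n = 1` summaries report zero SDs; a zero incremental QALY
  reports the ICER as undefined rather than erroring.
* Test and verification problem sizes: 10,000 trials per arm for
  summary-level checks (matching the original run count), 100 seeds for the
  oracle-equivalence sweep, 200,000 trials for tight convergence checks,
  50,000 for ground-truth frequency recovery, 1,000 scenarios for
  perturbation unbiasedness, and 21 × 21 analytic grids for monotonicity.

## Limitations

The calibration recovers *a* parameterization consistent with the published
strategy-level moments, not the original one: the mix is identified only up
to its expected-QALY constraint and the cost means only up to the severity
ordering. Absolute CERs inherit this non-identifiability; the CER *ratio* is
much more stable because both arms share the calibration machinery. The
30-day horizon, the lack of discounting and the single-transition structure
are inherited modelling limits, and the QALY-SD mismatch discussed above is
an internal inconsistency of the published summaries that no admissible
parameterization removes.
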