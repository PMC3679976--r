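---
title: "Population stratification of total cardiovascular risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population stratification of total cardiovascular risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdstrat)
```

## The problem and the instrument

National noncommunicable-disease risk-factor surveys (the STEPS family and
its relatives) measure blood pressure, biochemistry, anthropometry and
behaviour on a stratified multistage cluster sample of adults. `cvdstrat`
turns such microdata into the population distribution of *total*
ten-year cardiovascular (CVD) risk: rather than reporting each risk
factor against its own treatment threshold, every individual aged 40 and
over is assigned a predicted probability band for a fatal or non-fatal
cardiovascular event over ten years, and the population shares of the
low (<10%), moderate (10–<20%) and high (≥20%) categories are estimated
with design-based confidence intervals.

The risk instrument is a WHO/ISH-style *chart*: a finite colour-coded
lookup table indexed by sex, decade age band (40–49, 50–59, 60–69, 70+),
current smoking, diabetes, a systolic blood pressure band (<140, 140–159,
160–179, ≥180 mmHg) and — in the with-cholesterol variant — a total
cholesterol column (4–8 mmol/l). Because the instrument is a table, not a
regression equation, the package treats chart content strictly as data: a
chart file is validated against the full key cross-product (2 × 4 × 2 × 2
× 4 = 128 cells without cholesterol; × 5 = 640 with) and any missing,
duplicate or mislabelled cell is reported by key. Published chart values
are not redistributed with the package; deterministic fixture charts
(`make_fixture_chart()`) stand in for tests and demonstrations.

### Assumptions inherited from the instrument

* The charts apply from age 40; younger ages are a hard error in the
  engine. The analysis window (default 40–64, both inclusive) is enforced
  by the pipeline, which records under- and over-age records as excluded
  rather than silently dropping them. Survey samples are commonly capped
  at 64, which is why 64 rather than 69 is the default upper bound.
* One survey visit stands in for "persistent" blood pressure. A single
  visit tends to overestimate the share with persistently raised
  pressure; we document rather than model this.
* Individuals with missing total cholesterol are scored on the
  without-cholesterol chart variant (per-record fallback), so cholesterol
  missingness changes the instrument, not the denominator.

## Derived inputs and thresholds

All clinical thresholds follow the standard survey definitions. Every
"≥"-style threshold is inclusive and every ">"/"<" strict; the test suite
audits all of them at `x − ε, x, x + ε`.

| quantity | rule | units |
|---|---|---|
| analysis SBP/DBP | mean of last two of three seated readings | mmHg |
| smoker | current smoking, or quit < 1 year before survey | – |
| diabetes | glucose ≥ 6.1 (whole blood) / ≥ 7.0 (plasma), or medication | mmol/l |
| hypertension | SBP ≥ 140 or DBP ≥ 90, or medication | mmHg |
| hypercholesterolemia | TC ≥ 6.2, or medication | mmol/l |
| obesity | BMI ≥ 30 | kg/m² |
| sedentary | MET-minutes < 600 | MET-min/week |
| raised pulse | > 90 (strict) | bpm |
| raised triglycerides | > 2.00 (strict) | mmol/l |
| low HDL | < 1.0 (male) / < 1.3 (female) | mmol/l |

The discard-the-first-reading rule is specified for systolic pressure;
applying the same rule to diastolic pressure is this package's stated
extension (the two are measured simultaneously, and the first-reading
alerting effect applies to both).

Missing inputs never default to "not exposed": strict scalar functions
raise a missing-input error, and the vectorised pipeline propagates `NA`,
counts missingness per variable, and excludes records only when a
*chart-required* input (blood pressure, smoking, diabetes status) is
undeterminable. Elevating-factor flags stay undefined individually;
`any_elevating` is the OR restricted to observed flags and is undefined
only when all six are missing.

## The reclassification cascade

Practice notes accompanying the charts promote individuals to high risk
irrespective of the chart cell: blood pressure ≥ 160/100 mmHg, total
cholesterol ≥ 8.0 mmol/l, and (for population monitoring of treatment
need) current antihypertensive therapy. The package exposes these as four
cumulative scenarios — `CHART_ONLY`, `CHART_BP`, `CHART_BP_CHOL`,
`CHART_BP_CHOL_MED` — applied per person with `max(chart category, high)`
so promotion can never demote. Two consequences are testable invariants:
the high-risk sets are nested across scenarios for every input, and the
low+moderate share is non-increasing.

Design choices that the notation leaves open:

* **"160/100" is read as SBP ≥ 160 OR DBP ≥ 100**, the standard clinical
  reading of the slash; an `"and"` switch is provided
  (`bp_rule = "and"`) for sensitivity analysis.
* **Missing cholesterol under `CHART_BP_CHOL`** is a logged no-op for
  that record, not an error: surveys that did not measure cholesterol
  simply cannot apply that criterion, and the scenario still evaluates
  the blood-pressure clause.
* Proximity-to-next-band practice points ("risk may be higher than
  indicated") are *flagged* via the elevating factors, never
  reclassified: the notes give no quantitative rule to reclassify by.

## Design-based estimation

Let `w_i` be the combined survey weight (sample × non-response ×
post-stratification; a pre-multiplied single column is accepted). The
prevalence estimator is the ratio `p̂ = Σ w_i x_i / Σ w_i`. Variance is by
Taylor linearization with clusters as primary sampling units within
strata, using the with-replacement approximation and no finite-population
correction: with linearized scores `e_i = w_i (x_i − p̂) / Σw`, cluster
totals are summed within strata with the usual `n_h/(n_h − 1)` factor.
Degrees of freedom are `#PSUs − #strata`, and subgroup (domain) estimates
retain every cluster of the full design, as in standard survey practice.

Confidence intervals default to a symmetric t-interval **on the logit
scale**, back-transformed. The motivation is behaviour at the tail:
high-risk prevalences of 1–2% with modest effective sample sizes give
Wald intervals that cross zero, and a reported interval like
"2.3 (−0.7–5.4)" is not a probability statement. The logit interval
respects (0, 1) by construction; `ci_method = "wald"` restores the
symmetric interval (clamped to [0, 1]) for comparability with legacy
reports. Degenerate cases are explicit: `p̂ ∈ {0, 1}` or zero variance
yields a collapsed interval at the point estimate; a stratum with a
single PSU leaves the point estimate intact and marks the variance
undefined rather than guessing; an empty domain reports `n = 0` with an
undefined estimate.

The estimator is validated three ways in the test suite: closed-form
agreement with the binomial logit interval in the iid equal-weight limit;
endpoint agreement (within 0.015) with an independently coded Rao–Wu
rescaled cluster bootstrap (10,000 replicates) on a 200-record stratified
design; and empirical 95% coverage within [0.92, 0.98] over 500 simulated
designs at planted prevalences of 2%, 15% and 45%.

## The synthetic survey generator

`generate_cohort()` draws a full participant table under a documented
`generator_config()`. It emulates the *measurement structure* of a
STEPS-like survey — not any country's values:

* **Design**: strata × clusters × persons, cluster selection
  probabilities spread over a configured range (weights ∝ 1/probability),
  binomial person-level non-response with per-cluster reweighting, and
  post-stratification of weights to a target sex split. Defaults: 3
  strata, 10 clusters each, 40 sampled per cluster, 10% non-response.
* **Blood pressure**: a person-level latent mean (baseline 124/77 mmHg at
  age 40, slopes 0.55/0.2 mmHg per year, male shifts +3/+2, between-person
  SD 15/9) with three readings at within-person SD 4/3 mmHg — so the
  discard-the-first-reading rule has non-trivial behaviour and setting the
  reading SD to zero collapses the readings onto the latent value exactly.
* **Biochemistry**: lognormal whole-blood glucose (median ≈ 5.1 mmol/l)
  with a 50/50 whole-blood/plasma specimen mix (plasma ≈ 11% higher) and
  5% missingness; normal cholesterol (5.2 ± 1.05 mmol/l) with 25%
  missingness to exercise the chart-variant fallback; lognormal
  triglycerides, sex-specific normal HDL, both with 10% missingness
  mimicking biochemical subsampling.
* **Behaviour and treatment**: sex-specific smoking (50%/8%), recent
  quitting 3%; antihypertensive medication at 30% among latently
  hypertensive people and 3% otherwise, with analogous rules for glucose-
  and lipid-lowering drugs — enough correlation structure to make the
  medication clauses and the scenario-D promotion consequential.

Correlations are induced only through age and sex effects (no copulas):
sufficient to exercise every code path while keeping the truth
computable. **Truth is realized-sample**: the generator applies the
clinical definitions directly to the values it drew (and the documented
closed-form rule of the `threshold` fixture chart) and reports finite-
sample prevalences, so recovery tests measure estimator error without
conflating it with sampling error. What the generator does *not* emulate:
real covariance between risk factors beyond age/sex, informative
non-response, measurement rounding, and any country's actual
distributions — passing recovery tests therefore demonstrates correctness
of the pipeline, not realism of any particular prevalence level.

## Numerical and interface choices

* **Band edges are lower-inclusive** (140 → "140-159", 160 → "160-179",
  180 → ">=180"), matching the inclusive "≥" style of all clinical
  thresholds. Chart sources do not state a rounding rule.
* **Cholesterol maps to the nearest printed column** (4–8 mmol/l), exact
  midpoints rounding up and out-of-range values clamped — the
  least-biased convention for a printed-column instrument, implemented as
  `floor(tc + 0.5)` with clamping.
* **Non-positive measurements are errors, not missing values**: a
  cholesterol of 0 must not silently reroute a record to the
  no-cholesterol chart.
* **Exclusion reasons are single and prioritised** (age scope, then blood
  pressure, smoking, diabetes) so every record carries exactly one reason
  and tallies reconcile.
* Output CSVs carry full precision; the human-readable summary prints
  percentages to one decimal. Nothing in the pipeline reads the clock or
  the RNG at analysis time, so identical inputs give byte-identical
  outputs (tested).

## Problem sizes used by the test suite

The suite runs at sizes chosen to make the statistical checks sharp yet
quick: cascade nesting on 1,000 randomized profiles × 3 fixture charts;
the bootstrap oracle on a 200-record, 20-PSU design with 10,000
replicates; coverage over 500 replicates × 3 planted prevalences on
1,200-record designs; and parameter recovery at roughly 500 versus 5,000
respondents from a fixed seed, requiring every planted prevalence within
three design-based standard errors and the mean absolute error to shrink
with size. The acceptance script simulates ≈3,000 respondents, the scale
of one country's 40–64 analysis sample.

## Known limitations

* The package ships no published chart values; analyses of real surveys
  require the user to supply their region's chart file in the documented
  schema.
* Inputs are mmol/l only; no mg/dl conversion and no imputation of
  missing biochemistry.
* No age-standardisation to an external population and no multi-survey
  trend machinery; the unit of analysis is one survey.
* The Taylor/with-replacement variance omits finite-population
  correction; for the small sampling fractions typical of national
  surveys this is conservative and standard.
* "Persistent" blood pressure and practice points that require
  unmeasured history (family history, premature menopause, socioeconomic
  deprivation) are out of scope by construction.
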