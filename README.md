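# cvdstrat

**Total cardiovascular risk stratification for complex survey data.**

`cvdstrat` estimates the population distribution of ten-year total
cardiovascular disease (CVD) risk from cross-sectional risk-factor survey
microdata, for epidemiologists and health planners working with
STEPS-style national surveys. It is built around the WHO/ISH approach to
total risk: instead of treating each elevated risk factor in isolation
("vertical" approach), every individual is assigned a predicted ten-year
probability band for a fatal or non-fatal cardiovascular event from a
colour-coded chart, and treatment need is assessed from the population
share in each risk band.

## What it implements

1. **Chart engine.** WHO/ISH-style charts are lookup tables over
   `(sex, age band, smoking, diabetes, SBP band[, cholesterol column])`,
   published in two variants (with and without total cholesterol). Chart
   content ships as *data* (CSV or JSON), never as code; the engine
   validates exhaustiveness (640 cells with cholesterol, 128 without — the
   full key cross-product), uniqueness and label admissibility, and
   performs deterministic single-cell lookup. Risk bands
   `<10, 10-<20, 20-<30, 30-<40, >=40` (% over ten years) map to the
   categories low / moderate / high / very high, with `high (>=20%)` as the
   collapsed reporting category.

2. **Risk definitions.** Derivation of chart inputs and single-risk-factor
   indicators from raw survey records, with the field's standard
   thresholds: analysis blood pressure = mean of the last two of three
   seated readings; smoker = current smoking or quit < 1 year;
   diabetes = fasting glucose ≥ 6.1 mmol/l (whole blood) / ≥ 7.0 mmol/l
   (plasma) or glucose-lowering medication; hypertension = SBP ≥ 140 or
   DBP ≥ 90 mmHg or antihypertensive medication; hypercholesterolemia =
   total cholesterol ≥ 6.2 mmol/l or lipid-lowering medication. Elevating
   factors not captured by the charts: obesity (BMI ≥ 30 kg/m²), sedentary
   lifestyle (< 600 MET-min/week), pulse > 90 bpm, triglycerides
   > 2.00 mmol/l, low HDL (< 1.0 male / < 1.3 female mmol/l), current
   antihypertensive treatment.

3. **Reclassification cascade.** Four nested inclusion-criteria scenarios:
   chart only; + blood pressure ≥ 160/100 mmHg; + cholesterol ≥ 8 mmol/l;
   + antihypertensive medication. Promotion to high risk never demotes, so
   high-risk sets are provably nested across scenarios.

4. **Survey estimation.** Design-based weighted prevalence
   `p = Σwx / Σw` with Taylor-linearized variance under stratified
   multistage cluster sampling (clusters as PSUs within strata,
   `df = #PSUs − #strata`), 95% CIs on the logit scale by default (a Wald
   switch is provided), and proper domain estimation for subgroups.

5. **Synthetic survey generator.** STEPS-like microdata with known
   realized ground truth — unequal cluster selection probabilities,
   non-response, sex post-stratification, three-reading blood pressure,
   specimen-specific glucose and cholesterol missingness — so the whole
   pipeline is testable end to end without any external data.

## Worked example

```r
library(cvdstrat)

# deterministic fixture charts (replace with your region's chart files)
chart_with    <- make_fixture_chart("threshold", "with_cholesterol")
chart_without <- make_fixture_chart("threshold", "without_cholesterol")

gen <- generate_cohort(generator_config(seed = 7))
bundle <- run_analysis(gen$records, chart_with, chart_without)
print(bundle)
#> <cvd_result_bundle> 1072 records: 1008 classified, 64 excluded
#> high risk (>=20%) by scenario:
#>   CHART_ONLY          47.5% (95% CI 45.3-49.7)
#>   CHART_BP            48.1% (95% CI 45.8-50.4)
#>   CHART_BP_CHOL       48.2% (95% CI 45.9-50.5)
#>   CHART_BP_CHOL_MED   53.8% (95% CI 51.3-56.3)
```

Each line is the design-based weighted share of the 40–64 population in
the collapsed high-risk (≥20% ten-year risk) category under progressively
more inclusive criteria; the proportions can only rise along the cascade.
(The `threshold` fixture chart is deliberately aggressive so that all five
risk bands are populated; absolute levels reflect that fixture, not any
published chart.) `write_result_bundle(bundle, "out/")` writes the four
report tables, the per-participant classification, the exclusion report
and a provenance sidecar.

The same workflow is available from a shell:

```sh
Rscript inst/cli/cvdstrat.R make-chart --style threshold --variant with_cholesterol --out cw.csv
Rscript inst/cli/cvdstrat.R make-chart --style threshold --variant without_cholesterol --out cwo.csv
Rscript inst/cli/cvdstrat.R simulate --seed 7 --out sim/
Rscript inst/cli/cvdstrat.R analyze --records sim/participants.csv \
    --chart cw.csv --chart-nochol cwo.csv --out results/
```

## Documentation

The methods vignette (`vignettes/total-cvd-risk.Rmd`) describes the model
and its assumptions, every threshold and tunable parameter, the synthetic
generator's design, numerical choices and known limitations.
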