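Package: cvdstrat
Title: Total Cardiovascular Risk Stratification for Complex Survey Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the population distribution of total
    cardiovascular disease (CVD) risk from cross-sectional risk-factor
    survey microdata. Implements a validated lookup engine for WHO/ISH-style
    ten-year risk prediction charts (with and without total cholesterol),
    derivation of chart inputs and single-risk-factor definitions from raw
    survey records (three-reading blood pressure, specimen-specific glucose
    thresholds, smoking and medication self-report), the practice-note
    reclassification cascade that promotes individuals with blood pressure
    >= 160/100 mmHg, total cholesterol >= 8 mmol/l or antihypertensive
    treatment to the high-risk category, flags for risk-elevating factors
    not captured by the charts, and design-based weighted prevalence
    estimation with Taylor-linearized confidence intervals under stratified
    multistage cluster sampling. A reproducible synthetic survey generator
    with known ground truth supports end-to-end testing, and a command-line
    interface orchestrates simulation, classification and analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
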