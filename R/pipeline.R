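# Orchestration: ingest -> derivation -> classification -> design-based
# estimation, emitting the four standard report table shapes (single-factor
# prevalence, chart risk-category distribution, the scenario cascade, and
# elevating flags by category), plus the exclusion report and a provenance
# block. Deterministic given inputs: no clocks, no RNG.

.AGE_GROUPS <- c("40-49", "50-59", "60-64")

.age_group <- function(age) {
  as.character(cut(age, breaks = c(40, 50, 60, 65), labels = .AGE_GROUPS,
                   right = FALSE))
}

.md5_of_chart <- function(chart) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_chart(chart, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full population risk analysis
#'
#' Classifies every record (see [classify_all()]) and derives the four
#' report tables on the retained 40--64 population:
#' * `risk_factors` -- weighted prevalence of hypertension, diabetes,
#'   hypercholesterolemia and smoking by sex and age group (with margins);
#' * `risk_categories` -- the chart-only low/moderate/high (>=20%)
#'   distribution by sex and age group;
#' * `scenarios` -- the low/moderate/high distribution under each of the
#'   four inclusion-criteria scenarios (overall population);
#' * `flags` -- elevating-factor prevalence by risk category under
#'   `flags_scenario`.
#'
#' Proportions in any partition share one weighted denominator and so sum
#' to 1; every table row carries its unweighted n, and the exclusion report
#' reconciles input and analysis denominators.
#'
#' @inheritParams classify_all
#' @param flags_scenario Scenario defining the categories of the flags
#'   table (default `"CHART_ONLY"`, the chart-only categorisation).
#' @param ci_method Confidence interval method, `"logit"` (default) or
#'   `"wald"`.
#' @param chart_paths Optional named list/vector with elements `with` and
#'   `without`, recorded in provenance.
#' @return A `cvd_result_bundle`: list with `classification`,
#'   `risk_factors`, `risk_categories`, `scenarios`, `flags`,
#'   `exclusions` and `provenance`.
#' @export
run_analysis <- function(records, chart_with, chart_without,
                         flags_scenario = "CHART_ONLY",
                         bp_rule = c("or", "and"),
                         ci_method = c("logit", "wald"),
                         age_range = c(40, 64), chart_paths = NULL) {
  bp_rule <- match.arg(bp_rule)
  ci_method <- match.arg(ci_method)
  flags_scenario <- match.arg(flags_scenario, .SCENARIOS)

  classification <- classify_all(records, chart_with, chart_without,
                                 age_range = age_range, bp_rule = bp_rule)
  cls <- classification[!classification$excluded, , drop = FALSE]
  if (nrow(cls) == 0) stop("no records remain after exclusions")
  cls$age_group <- .age_group(cls$age)

  risk_factors <- prevalence_table(
    cls,
    outcomes = c(hypertension = "hypertension", diabetes = "diabetic",
                 hypercholesterolemia = "hypercholesterolemia",
                 smoking = "smoker"),
    by = c("sex", "age_group"), ci_method = ci_method)

  for (rc in .REPORTING) {
    cls[[paste0("cat_", rc)]] <-
      reporting_category(cls$category_chart_only) == rc
  }
  risk_categories <- prevalence_table(
    cls,
    outcomes = c(low = "cat_low", moderate = "cat_moderate",
                 high_ge20 = "cat_high_ge20"),
    by = c("sex", "age_group"), ci_method = ci_method)

  scen_rows <- list()
  for (sc in .SCENARIOS) {
    rep_cat <- reporting_category(cls[[paste0("category_", tolower(sc))]])
    for (rc in .REPORTING) {
      est <- weighted_proportion(
        rep_cat == rc, cls$weight, stratum = cls$stratum_id,
        cluster = cls$cluster_id, ci_method = ci_method)
      scen_rows[[length(scen_rows) + 1L]] <-
        cbind(data.frame(scenario = sc, category = rc,
                         stringsAsFactors = FALSE), est)
    }
  }
  scenarios <- do.call(rbind, scen_rows)
  rownames(scenarios) <- NULL

  flags <- flags_by_category(classification, scenario = flags_scenario,
                             ci_method = ci_method)

  excl <- classification[classification$excluded, , drop = FALSE]
  exclusions <- as.data.frame(
    table(reason = factor(excl$exclusion_reason, levels = .EXCLUSION_REASONS)),
    stringsAsFactors = FALSE)
  names(exclusions) <- c("reason", "n")

  provenance <- list(
    package = "cvdstrat",
    package_version = as.character(utils::packageVersion("cvdstrat")),
    chart_with = list(region_id = chart_with$region_id,
                      n_cells = nrow(chart_with$cells),
                      md5 = .md5_of_chart(chart_with),
                      path = chart_paths$with %||% NA),
    chart_without = list(region_id = chart_without$region_id,
                         n_cells = nrow(chart_without$cells),
                         md5 = .md5_of_chart(chart_without),
                         path = chart_paths$without %||% NA),
    parameters = list(flags_scenario = flags_scenario, bp_rule = bp_rule,
                      ci_method = ci_method, age_range = age_range),
    n_input = nrow(classification), n_classified = nrow(cls),
    n_excluded = nrow(excl)
  )

  structure(
    list(classification = classification, risk_factors = risk_factors,
         risk_categories = risk_categories, scenarios = scenarios,
         flags = flags, exclusions = exclusions, provenance = provenance),
    class = "cvd_result_bundle"
  )
}

#' @export
print.cvd_result_bundle <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<cvd_result_bundle> %d records: %d classified, %d excluded\n",
              p$n_input, p$n_classified, p$n_excluded))
  ov <- x$scenarios[x$scenarios$category == "high_ge20", ]
  cat("high risk (>=20%) by scenario:\n")
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-18s %5.1f%% (95%% CI %.1f-%.1f)\n", ov$scenario[i],
                100 * ov$proportion[i], 100 * ov$ci_low[i], 100 * ov$ci_high[i]))
  }
  invisible(x)
}

.fmt_pct <- function(p) sprintf("%.1f", 100 * p)

#' Write a result bundle to disk
#'
#' Machine CSVs at full precision (`risk_factors.csv`,
#' `risk_categories.csv`, `scenarios.csv`, `flags_by_category.csv`,
#' `classification.csv`, `exclusions.csv`), a JSON provenance sidecar and a
#' human-readable `summary.txt` with percentages to one decimal.
#'
#' @param bundle A `cvd_result_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cvd_result_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    out <- df
    for (col in names(out)) {
      if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
    }
    utils::write.csv(out, file.path(dir, name), row.names = FALSE, na = "")
  }
  w(bundle$risk_factors, "risk_factors.csv")
  w(bundle$risk_categories, "risk_categories.csv")
  w(bundle$scenarios, "scenarios.csv")
  w(bundle$flags, "flags_by_category.csv")
  w(bundle$classification, "classification.csv")
  w(bundle$exclusions, "exclusions.csv")
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  p <- bundle$provenance
  lines <- c(
    "Total CVD risk stratification summary",
    sprintf("records: %d input, %d classified, %d excluded",
            p$n_input, p$n_classified, p$n_excluded),
    "",
    "High risk (>=20%) by inclusion criteria [% (95% CI)]:"
  )
  hi <- bundle$scenarios[bundle$scenarios$category == "high_ge20", ]
  for (i in seq_len(nrow(hi))) {
    lines <- c(lines, sprintf(
      "  %-18s %s (%s-%s)", hi$scenario[i], .fmt_pct(hi$proportion[i]),
      .fmt_pct(hi$ci_low[i]), .fmt_pct(hi$ci_high[i])))
  }
  lines <- c(lines, "", "Single risk factors, overall 40-64 [% (95% CI)]:")
  ov <- bundle$risk_factors[bundle$risk_factors$sex == "(all)" &
                              bundle$risk_factors$age_group == "(all)", ]
  for (i in seq_len(nrow(ov))) {
    lines <- c(lines, sprintf(
      "  %-22s %s (%s-%s)  n=%d", ov$outcome[i], .fmt_pct(ov$proportion[i]),
      .fmt_pct(ov$ci_low[i]), .fmt_pct(ov$ci_high[i]), ov$n_unweighted[i]))
  }
  any_fl <- bundle$flags[bundle$flags$flag == "any_elevating" &
                           bundle$flags$category != "total", ]
  lines <- c(lines, "", ">=1 risk-elevating factor by chart category [%]:")
  for (i in seq_len(nrow(any_fl))) {
    lines <- c(lines, sprintf("  %-10s %s", any_fl$category[i],
                              .fmt_pct(any_fl$proportion[i])))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
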