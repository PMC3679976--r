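# The reclassification cascade: four nested inclusion-criteria scenarios
# that progressively attribute individuals to the high-risk category per
# the practice notes accompanying the charts. Promotion never demotes, so
# high-risk sets are nested across scenarios by construction.

.SCENARIOS <- c("CHART_ONLY", "CHART_BP", "CHART_BP_CHOL", "CHART_BP_CHOL_MED")
.SCENARIO_DESCRIPTIONS <- c(
  CHART_ONLY = "simple application of the chart",
  CHART_BP = "chart + blood pressure >= 160/100 mmHg",
  CHART_BP_CHOL = "chart + BP >= 160/100 + total cholesterol >= 8 mmol/l",
  CHART_BP_CHOL_MED = "chart + BP >= 160/100 + cholesterol >= 8 + on antihypertensive medication"
)

#' Reclassification scenarios
#'
#' Identifiers of the four inclusion-criteria scenarios, strictly ordered by
#' inclusiveness: each later scenario can only promote more people to the
#' high-risk category than the one before.
#'
#' @return Named character vector of scenario descriptions, in cascade
#'   order.
#' @export
cvd_scenarios <- function() .SCENARIO_DESCRIPTIONS

#' Apply an inclusion-criteria scenario to chart categories
#'
#' Starting from the chart-derived risk category, promotes individuals to
#' at least the high-risk (>=20%) category when the scenario's criteria are
#' met: blood pressure >= 160/100 mmHg (`CHART_BP` and later), total
#' cholesterol >= 8.0 mmol/l (`CHART_BP_CHOL` and later; records with
#' missing cholesterol are skipped with a logged notice), and current
#' antihypertensive medication (`CHART_BP_CHOL_MED`). Promotion never
#' demotes: someone already at `very_high` stays there.
#'
#' @param chart_category Character vector of chart-derived categories (see
#'   [band_to_category()]).
#' @param profile Data frame with columns `sbp`, `dbp`,
#'   `total_cholesterol` and `on_ht_medication`, aligned with
#'   `chart_category`.
#' @param scenario One of `names(cvd_scenarios())`.
#' @param bp_rule How to read the 160/100 threshold: `"or"` (default,
#'   SBP >= 160 or DBP >= 100 -- the standard clinical reading of the slash
#'   notation) or `"and"`.
#' @return Character vector of categories after promotion.
#' @export
apply_scenario <- function(chart_category, profile, scenario,
                           bp_rule = c("or", "and")) {
  scenario <- match.arg(scenario, .SCENARIOS)
  bp_rule <- match.arg(bp_rule)
  unknown <- !is.na(chart_category) & !chart_category %in% .CATEGORIES
  if (any(unknown)) {
    stop("unknown risk category: ",
         paste(unique(chart_category[unknown]), collapse = ", "))
  }
  profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  n <- length(chart_category)
  promote <- rep(FALSE, n)
  if (scenario %in% c("CHART_BP", "CHART_BP_CHOL", "CHART_BP_CHOL_MED")) {
    bp_high <- if (bp_rule == "or") {
      (profile$sbp >= 160) | (profile$dbp >= 100)
    } else {
      (profile$sbp >= 160) & (profile$dbp >= 100)
    }
    promote <- promote | (!is.na(bp_high) & bp_high)
  }
  if (scenario %in% c("CHART_BP_CHOL", "CHART_BP_CHOL_MED")) {
    tc <- profile$total_cholesterol
    n_miss <- sum(is.na(tc))
    if (n_miss > 0) {
      cvd_log("scenario %s: cholesterol criterion skipped for %d record(s) with missing cholesterol",
              scenario, n_miss, level = "INFO")
    }
    promote <- promote | (!is.na(tc) & tc >= 8.0)
  }
  if (scenario == "CHART_BP_CHOL_MED") {
    med <- as.logical(profile$on_ht_medication)
    promote <- promote | (!is.na(med) & med)
  }
  rank <- match(chart_category, .CATEGORIES)
  rank <- pmax(rank, ifelse(promote, match("high", .CATEGORIES), 1L))
  out <- .CATEGORIES[rank]
  out[is.na(chart_category)] <- NA_character_
  out
}

.EXCLUSION_REASONS <- c("age_out_of_scope", "missing_bp_readings",
                        "missing_smoking_status", "missing_diabetes_status")

#' Classify every participant record
#'
#' End-to-end per-person classification: restricts to the analysis age
#' range (default 40--64 inclusive), derives the chart inputs, selects the
#' chart variant per record (without-cholesterol fallback when cholesterol
#' is missing), looks up the chart risk band, applies all four scenarios,
#' and computes single-risk-factor and risk-elevating flags. Records that
#' cannot be classified are retained with `excluded = TRUE` and a reason,
#' so every input row is exactly once in \{classified, excluded\} and table
#' denominators reconcile.
#'
#' @param records Participant records (see [read_participants()] for the
#'   schema); validated on entry.
#' @param chart_with,chart_without Validated `chart_spec` objects for the
#'   two variants.
#' @param age_range Inclusive analysis age bounds, default `c(40, 64)`.
#' @param bp_rule Passed to [apply_scenario()].
#' @return Data frame, one row per input record: identifiers and design
#'   variables, `excluded`/`exclusion_reason`, derived inputs (`sbp`,
#'   `dbp`, `smoker`, `diabetic`), `variant_used`, `chart_band`, one
#'   `category_*` column per scenario, single-factor indicators
#'   (`hypertension`, `hypercholesterolemia`) and the elevating flags.
#' @export
classify_all <- function(records, chart_with, chart_without,
                         age_range = c(40, 64), bp_rule = c("or", "and")) {
  bp_rule <- match.arg(bp_rule)
  stopifnot(inherits(chart_with, "chart_spec"),
            inherits(chart_without, "chart_spec"))
  if (chart_with$variant != "with_cholesterol" ||
      chart_without$variant != "without_cholesterol") {
    stop("chart_with must be the with_cholesterol variant and chart_without ",
         "the without_cholesterol variant")
  }
  records <- validate_records(records)
  n <- nrow(records)

  sbp <- .bp_mean_last_two(records$sbp2, records$sbp3)
  dbp <- .bp_mean_last_two(records$dbp2, records$dbp3)
  smoker <- is_smoker(records$current_smoker, records$quit_lt_1yr)
  diabetic <- is_diabetic(records$fasting_glucose, records$glucose_specimen,
                          records$on_dm_medication, strict = FALSE)

  reason <- rep(NA_character_, n)
  reason[is.na(diabetic)] <- "missing_diabetes_status"
  reason[is.na(smoker)] <- "missing_smoking_status"
  reason[is.na(sbp) | is.na(dbp)] <- "missing_bp_readings"
  out_of_age <- records$age < age_range[1] | records$age > age_range[2]
  reason[out_of_age] <- "age_out_of_scope"
  excluded <- !is.na(reason)

  variant_used <- rep(NA_character_, n)
  chart_band <- rep(NA_character_, n)
  keep <- !excluded
  if (any(keep)) {
    variant_used[keep] <- select_variant(records[keep, , drop = FALSE])
    prof <- data.frame(
      sex = records$sex, age = records$age, smoker = smoker,
      diabetic = diabetic, sbp = sbp,
      total_cholesterol = records$total_cholesterol,
      stringsAsFactors = FALSE
    )
    for (v in c("with_cholesterol", "without_cholesterol")) {
      sel <- keep & variant_used == v
      if (any(sel)) {
        chart <- if (v == "with_cholesterol") chart_with else chart_without
        chart_band[sel] <- chart_lookup(chart, prof[sel, , drop = FALSE])
      }
    }
  }
  chart_category <- band_to_category(chart_band)

  scen_prof <- data.frame(
    sbp = sbp, dbp = dbp, total_cholesterol = records$total_cholesterol,
    on_ht_medication = records$on_ht_medication, stringsAsFactors = FALSE
  )
  categories <- lapply(.SCENARIOS, function(s) {
    apply_scenario(chart_category, scen_prof, s, bp_rule = bp_rule)
  })
  names(categories) <- paste0("category_", tolower(.SCENARIOS))

  flags <- elevating_flags(records)
  flags[excluded, ] <- NA

  out <- data.frame(
    participant_id = records$participant_id,
    stratum_id = records$stratum_id,
    cluster_id = records$cluster_id,
    weight = records$weight,
    sex = records$sex,
    age = records$age,
    excluded = excluded,
    exclusion_reason = reason,
    sbp = sbp, dbp = dbp, smoker = smoker, diabetic = diabetic,
    variant_used = variant_used,
    chart_band = chart_band,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(categories, stringsAsFactors = FALSE))
  out$hypertension <- has_hypertension(sbp, dbp, records$on_ht_medication)
  out$hypercholesterolemia <- has_hypercholesterolemia(
    records$total_cholesterol, records$on_chol_medication, strict = FALSE)
  out$hypertension[excluded] <- NA
  out$hypercholesterolemia[excluded] <- NA
  out[excluded, c("sbp", "dbp", "smoker", "diabetic")] <- NA
  out <- cbind(out, flags)

  tallied <- table(factor(reason[excluded], levels = .EXCLUSION_REASONS))
  cvd_log("classified %d of %d record(s); excluded: %s",
          sum(!excluded), n,
          paste(sprintf("%s=%d", names(tallied), as.integer(tallied)),
                collapse = ", "))
  out
}

#' Cross-tabulate elevating flags by risk category
#'
#' For each reporting category (`low`, `moderate`, `high_ge20`) under the
#' chosen scenario, estimates the weighted and unweighted prevalence of
#' every risk-elevating flag and of `any_elevating`, with per-flag
#' missingness counts. Weighted estimates use the design-based estimator of
#' [weighted_proportion()] with the full design retained (domain
#' estimation), so confidence intervals reflect the survey design.
#'
#' @param classified Output of [classify_all()].
#' @param scenario Scenario whose categories define the strata of the
#'   table; default `"CHART_ONLY"`.
#' @param ci_method Passed to [weighted_proportion()].
#' @return Long data frame: `category`, `flag`, `n_unweighted`,
#'   `n_missing`, `proportion`, `ci_low`, `ci_high`,
#'   `unweighted_proportion`.
#' @export
flags_by_category <- function(classified, scenario = "CHART_ONLY",
                              ci_method = c("logit", "wald")) {
  scenario <- match.arg(scenario, .SCENARIOS)
  ci_method <- match.arg(ci_method)
  cls <- classified[!classified$excluded, , drop = FALSE]
  cat_col <- paste0("category_", tolower(scenario))
  rep_cat <- reporting_category(cls[[cat_col]])
  flag_cols <- c(.ELEVATING_FLAGS, "any_elevating")
  rows <- list()
  for (cat in c(.REPORTING, "total")) {
    domain <- if (cat == "total") rep(TRUE, nrow(cls)) else rep_cat == cat
    for (fl in flag_cols) {
      est <- weighted_proportion(
        cls[[fl]], cls$weight, stratum = cls$stratum_id,
        cluster = cls$cluster_id, domain = domain, ci_method = ci_method)
      x <- cls[[fl]][domain]
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, flag = fl,
        n_unweighted = est$n_unweighted, n_missing = est$n_missing,
        proportion = est$proportion, ci_low = est$ci_low,
        ci_high = est$ci_high,
        unweighted_proportion = mean(x, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
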