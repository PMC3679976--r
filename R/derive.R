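# Derivation of chart inputs and single-risk-factor / risk-elevating flags
# from raw survey records. Thresholds follow the clinical definitions:
# every ">=" comparison is inclusive, every ">" or "<" strict. Missing
# inputs never silently default to FALSE flags: strict functions raise a
# missing-input error, the vectorised pipeline propagates NA and counts
# missingness per variable.

#' Derive analysis blood pressure from three seated readings
#'
#' Survey protocol takes three seated readings in rested participants; the
#' analysis value is the mean of the last two. The same rule is applied to
#' systolic and diastolic pressure (the diastolic rule is this package's
#' stated extension of the systolic convention).
#'
#' @param r1,r2,r3 Numeric vectors, first/second/third reading in mmHg.
#'   Readings 2 and 3 are required; the first is ignored by design.
#' @return `(r2 + r3) / 2`, in mmHg.
#' @export
#' @examples
#' derive_sbp(150, 142, 138) # 140
derive_sbp <- function(r1, r2, r3) {
  miss <- is.na(r2) | is.na(r3)
  if (any(miss)) {
    stop("missing input: blood pressure readings 2 and 3 are both required ",
         "(records with incomplete readings are excluded, not imputed)")
  }
  bad <- r2 <= 0 | r3 <= 0
  if (any(bad)) stop("blood pressure readings must be positive")
  (r2 + r3) / 2
}

#' @rdname derive_sbp
#' @export
derive_dbp <- derive_sbp

# NA-propagating version used by classify_all(); missing readings become NA.
.bp_mean_last_two <- function(r2, r3) {
  out <- (r2 + r3) / 2
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

#' Smoking status for chart scoring
#'
#' A person counts as a smoker if they currently smoke or quit less than a
#' year before the survey.
#'
#' @param current_smoker,quit_lt_1yr Logical vectors. Three-valued logic
#'   applies: `NA | TRUE` is `TRUE`, `NA | FALSE` is `NA`.
#' @return Logical vector.
#' @export
is_smoker <- function(current_smoker, quit_lt_1yr) {
  as.logical(current_smoker) | as.logical(quit_lt_1yr)
}

#' Diabetes status from fasting glucose and medication self-report
#'
#' Diabetic if fasting glucose is at or above the specimen-specific
#' threshold -- 6.1 mmol/l for whole blood, 7.0 mmol/l for plasma -- or if
#' the person reports insulin or oral hypoglycemic drugs despite a
#' below-threshold (or missing) measurement.
#'
#' @param fasting_glucose Numeric vector, mmol/l; `NA` = not measured.
#' @param glucose_specimen `"whole_blood"` or `"plasma"`, per record.
#' @param on_dm_medication Logical vector.
#' @param strict If `TRUE` (default), an undeterminable status (glucose
#'   missing and no medication) is a missing-input error; if `FALSE` it is
#'   returned as `NA`.
#' @return Logical vector.
#' @export
#' @examples
#' is_diabetic(6.1, "whole_blood", FALSE) # TRUE (inclusive threshold)
#' is_diabetic(6.9, "plasma", FALSE)      # FALSE (plasma threshold is 7.0)
is_diabetic <- function(fasting_glucose, glucose_specimen, on_dm_medication,
                        strict = TRUE) {
  ok <- is.na(glucose_specimen) | glucose_specimen %in% c("whole_blood", "plasma")
  if (!all(ok)) {
    stop("glucose_specimen must be 'whole_blood' or 'plasma'; got: ",
         paste(unique(glucose_specimen[!ok]), collapse = ", "))
  }
  if (any(!is.na(fasting_glucose) & is.na(glucose_specimen))) {
    stop("glucose_specimen is required wherever fasting_glucose is measured")
  }
  thr <- ifelse(glucose_specimen == "plasma", 7.0, 6.1)
  res <- (fasting_glucose >= thr) | as.logical(on_dm_medication)
  if (strict && anyNA(res)) {
    stop("missing input: diabetes status is undeterminable without a ",
         "glucose measurement or a medication report")
  }
  res
}

#' Hypertension as a single risk factor
#'
#' Systolic >= 140 mmHg or diastolic >= 90 mmHg, or below-threshold
#' measurements with self-reported antihypertensive medication.
#'
#' @param sbp,dbp Derived analysis blood pressures, mmHg (see
#'   [derive_sbp()]).
#' @param on_ht_medication Logical vector.
#' @return Logical vector.
#' @export
has_hypertension <- function(sbp, dbp, on_ht_medication) {
  (sbp >= 140) | (dbp >= 90) | as.logical(on_ht_medication)
}

#' Hypercholesterolemia as a single risk factor
#'
#' Total cholesterol >= 6.2 mmol/l, or a below-threshold measurement with
#' self-reported cholesterol-lowering medication.
#'
#' @param total_cholesterol Numeric vector, mmol/l; `NA` = not measured.
#' @param on_chol_medication Logical vector.
#' @inheritParams is_diabetic
#' @return Logical vector.
#' @export
has_hypercholesterolemia <- function(total_cholesterol, on_chol_medication,
                                     strict = TRUE) {
  res <- (total_cholesterol >= 6.2) | as.logical(on_chol_medication)
  if (strict && anyNA(res)) {
    stop("missing input: hypercholesterolemia status is undeterminable ",
         "without a cholesterol measurement or a medication report")
  }
  res
}

.ELEVATING_FLAGS <- c("obesity", "low_physical_activity", "high_pulse",
                      "on_ht_medication", "high_triglycerides", "low_hdl")

#' Risk-elevating factors not captured by the charts
#'
#' Flags the measurable practice-point factors under which chart-estimated
#' risk "may be higher than indicated": obesity (BMI >= 30 kg/m2),
#' sedentary lifestyle (< 600 MET-minutes/week), elevated resting pulse
#' (> 90 bpm, strict), current antihypertensive medication (self-report,
#' taken verbatim with no blood-pressure gating), raised triglycerides
#' (> 2.00 mmol/l, strict) and low HDL cholesterol (< 1.0 mmol/l in males,
#' < 1.3 mmol/l in females).
#'
#' Missing inputs leave the corresponding flag `NA` (undefined): it is
#' excluded from `any_elevating` and counted as missing in tabulations.
#' `any_elevating` is the OR of the six flags restricted to non-missing
#' ones, and `NA` only when all six are missing.
#'
#' @param profile Data frame with columns `sex`, `bmi`, `met_minutes`,
#'   `pulse`, `on_ht_medication`, `triglycerides`, `hdl`.
#' @return Data frame of logical columns
#'   `r paste(.ELEVATING_FLAGS, collapse = ", ")` and `any_elevating`.
#' @export
elevating_flags <- function(profile) {
  profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  bad_sex <- !is.na(profile$sex) & !profile$sex %in% .SEXES
  if (any(bad_sex)) {
    stop("sex must be one of ", paste(.SEXES, collapse = ", "))
  }
  flags <- data.frame(
    obesity = profile$bmi >= 30,
    low_physical_activity = profile$met_minutes < 600,
    high_pulse = profile$pulse > 90,
    on_ht_medication = as.logical(profile$on_ht_medication),
    high_triglycerides = profile$triglycerides > 2.00,
    low_hdl = profile$hdl < ifelse(profile$sex == "male", 1.0, 1.3)
  )
  m <- as.matrix(flags)
  any_true <- rowSums(m, na.rm = TRUE) > 0
  all_na <- rowSums(!is.na(m)) == 0
  flags$any_elevating <- ifelse(any_true, TRUE, ifelse(all_na, NA, FALSE))
  flags
}
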