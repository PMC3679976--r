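# Participant record schema and CSV ingest. Missingness is an empty field
# in CSV (never a numeric sentinel); booleans travel as 0/1.

.PARTICIPANT_COLUMNS <- c(
  "participant_id", "stratum_id", "cluster_id", "weight", "sex", "age",
  "sbp1", "sbp2", "sbp3", "dbp1", "dbp2", "dbp3",
  "current_smoker", "quit_lt_1yr",
  "fasting_glucose", "glucose_specimen", "on_dm_medication",
  "total_cholesterol", "on_chol_medication", "on_ht_medication",
  "bmi", "met_minutes", "pulse", "triglycerides", "hdl"
)
.BOOL_COLUMNS <- c("current_smoker", "quit_lt_1yr", "on_dm_medication",
                   "on_chol_medication", "on_ht_medication")
.NUMERIC_COLUMNS <- c("weight", "age", "sbp1", "sbp2", "sbp3", "dbp1", "dbp2",
                      "dbp3", "fasting_glucose", "total_cholesterol", "bmi",
                      "met_minutes", "pulse", "triglycerides", "hdl")

#' Validate participant records
#'
#' Enforces the participant schema at ingest: all columns present, unique
#' participant identifiers, positive weights, non-missing sex/age/design
#' variables, positive measurement readings where present, 0/1 (or logical)
#' flags, and an admissible glucose specimen type wherever glucose is
#' measured. Scope filtering (the 40--64 analysis window) is deliberately
#' not done here; see [classify_all()].
#'
#' @param records Data frame in the participant schema (see
#'   [read_participants()]).
#' @return The records with flag columns normalized to logical, invisibly
#'   usable downstream.
#' @export
validate_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.PARTICIPANT_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("participant data is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- unique(records$participant_id[duplicated(records$participant_id)])
  if (length(dup)) {
    stop("duplicate participant_id: ", paste(utils::head(dup, 20), collapse = ", "))
  }
  for (col in .NUMERIC_COLUMNS) {
    if (!is.numeric(records[[col]])) {
      suppressWarnings(records[[col]] <- as.numeric(records[[col]]))
    }
  }
  for (col in .BOOL_COLUMNS) {
    v <- records[[col]]
    if (!is.logical(v)) {
      if (!all(is.na(v) | v %in% c(0, 1, "0", "1"))) {
        stop("column ", col, " must be 0/1 or logical")
      }
      records[[col]] <- as.logical(as.integer(as.character(v)))
    }
  }
  if (anyNA(records$weight) || any(records$weight <= 0)) {
    stop("weight must be strictly positive for every record")
  }
  if (anyNA(records$age) || any(records$age < 0)) {
    stop("age must be present and non-negative for every record")
  }
  bad_sex <- !records$sex %in% .SEXES
  if (any(bad_sex)) {
    stop("sex must be one of ", paste(.SEXES, collapse = ", "), "; offending id(s): ",
         paste(utils::head(records$participant_id[bad_sex], 20), collapse = ", "))
  }
  if (anyNA(records$stratum_id) || anyNA(records$cluster_id)) {
    stop("stratum_id and cluster_id are required for every record")
  }
  spec <- records$glucose_specimen
  spec[!is.na(spec) & spec == ""] <- NA_character_
  records$glucose_specimen <- spec
  bad_spec <- !is.na(spec) & !spec %in% c("whole_blood", "plasma")
  if (any(bad_spec)) {
    stop("glucose_specimen must be 'whole_blood' or 'plasma'")
  }
  if (any(!is.na(records$fasting_glucose) & is.na(spec))) {
    stop("glucose_specimen is required wherever fasting_glucose is measured")
  }
  for (col in c("sbp1", "sbp2", "sbp3", "dbp1", "dbp2", "dbp3",
                "fasting_glucose", "total_cholesterol", "bmi", "pulse",
                "triglycerides", "hdl")) {
    bad <- !is.na(records[[col]]) & records[[col]] <= 0
    if (any(bad)) {
      stop("column ", col, " must be positive where present; offending id(s): ",
           paste(utils::head(records$participant_id[bad], 20), collapse = ", "))
    }
  }
  bad_met <- !is.na(records$met_minutes) & records$met_minutes < 0
  if (any(bad_met)) stop("met_minutes must be non-negative where present")
  records[, .PARTICIPANT_COLUMNS]
}

#' Read and write participant CSV files
#'
#' The participant CSV schema has exactly the columns of the participant
#' record (`participant_id`, design variables `stratum_id`, `cluster_id`,
#' `weight`, demographics, the three seated blood-pressure readings
#' `sbp1..3`/`dbp1..3`, behavioural and biochemical variables and
#' medication flags). Empty string means missing; flags are 0/1.
#'
#' @param path CSV file path.
#' @return `read_participants()` returns a validated data frame;
#'   `write_participants()` returns `path` invisibly.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("participant file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.PARTICIPANT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("participant CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in names(raw)) raw[[col]][raw[[col]] == ""] <- NA
  validate_records(raw)
}

#' @rdname read_participants
#' @param records Participant records data frame.
#' @export
write_participants <- function(records, path) {
  records <- validate_records(records)
  out <- records
  for (col in .BOOL_COLUMNS) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
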