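# Chart specification objects: an exhaustive lookup table from
# (sex, age band, smoking, diabetes, SBP band[, cholesterol band]) to a
# ten-year total CVD risk band. Chart content is data, never code: the
# engine validates and evaluates whatever chart file it is given.

.CHART_VARIANTS <- c("with_cholesterol", "without_cholesterol")

# Canonical cell key. chol_band is "" for the without-cholesterol variant.
.chart_key <- function(sex, age_band, smoker, diabetic, sbp_band, chol_band = NULL) {
  chol <- if (is.null(chol_band)) "" else ifelse(is.na(chol_band), "", as.character(as.integer(chol_band)))
  paste(sex, age_band, as.integer(smoker), as.integer(diabetic), sbp_band, chol, sep = "|")
}

.expected_cells <- function(variant) {
  grid <- expand.grid(
    chol_band = if (variant == "with_cholesterol") .CHOL_BANDS else NA_integer_,
    sbp_band = .SBP_BANDS, diabetic = 0:1, smoker = 0:1,
    age_band = .AGE_BANDS, sex = .SEXES,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid[, c("sex", "age_band", "smoker", "diabetic", "sbp_band", "chol_band")]
}

.fmt_keys <- function(keys) paste(keys, collapse = ", ")

#' Construct and validate a chart specification
#'
#' A `chart_spec` is the package's in-memory form of one chart variant: a
#' complete set of cells mapping every combination of sex (2), age band (4),
#' smoking (2), diabetes (2), SBP band (4) and, for the with-cholesterol
#' variant, cholesterol column (5) to a risk band. Validation enforces
#' exhaustiveness (640 cells with cholesterol, 128 without), uniqueness and
#' label admissibility, and reports every offending cell key.
#'
#' @param cells Data frame with columns `sex`, `age_band`, `smoker`,
#'   `diabetic`, `sbp_band`, `chol_band` (ignored/absent for the
#'   without-cholesterol variant) and `risk_band`.
#' @param variant `"with_cholesterol"` or `"without_cholesterol"`.
#' @param region_id Free-text chart region identifier.
#' @return An object of class `chart_spec`.
#' @seealso [load_chart()], [make_fixture_chart()]
#' @export
chart_spec <- function(cells, variant, region_id = "unspecified") {
  if (!variant %in% .CHART_VARIANTS) {
    stop("unknown chart variant: ", variant, " (expected one of ",
         paste(.CHART_VARIANTS, collapse = ", "), ")")
  }
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  needed <- c("sex", "age_band", "smoker", "diabetic", "sbp_band", "risk_band")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols)) {
    stop("chart cells are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"chol_band" %in% names(cells)) cells$chol_band <- NA_integer_
  suppressWarnings(cells$chol_band <- as.integer(cells$chol_band))
  cells$smoker <- as.integer(cells$smoker)
  cells$diabetic <- as.integer(cells$diabetic)

  problems <- character(0)

  bad_flag <- !cells$smoker %in% 0:1 | !cells$diabetic %in% 0:1
  if (any(bad_flag, na.rm = TRUE) || anyNA(cells$smoker) || anyNA(cells$diabetic)) {
    problems <- c(problems, "smoker/diabetic must be 0 or 1 in every row")
  }
  bad_band <- !cells$risk_band %in% .RISK_BANDS
  if (any(bad_band)) {
    problems <- c(problems, paste0(
      "unknown risk band label ",
      .fmt_keys(unique(cells$risk_band[bad_band])), " at cell(s) ",
      .fmt_keys(.chart_key(cells$sex[bad_band], cells$age_band[bad_band],
                           ifelse(is.na(cells$smoker[bad_band]), 0, cells$smoker[bad_band]),
                           ifelse(is.na(cells$diabetic[bad_band]), 0, cells$diabetic[bad_band]),
                           cells$sbp_band[bad_band], cells$chol_band[bad_band]))
    ))
  }
  if (variant == "without_cholesterol" && any(!is.na(cells$chol_band))) {
    problems <- c(problems, "chol_band must be empty in a without_cholesterol chart")
  }
  if (variant == "with_cholesterol" && any(is.na(cells$chol_band))) {
    problems <- c(problems, "chol_band is required in every with_cholesterol row")
  }

  keys <- .chart_key(cells$sex, cells$age_band, cells$smoker, cells$diabetic,
                     cells$sbp_band, cells$chol_band)
  expected <- .expected_cells(variant)
  expected_keys <- .chart_key(expected$sex, expected$age_band, expected$smoker,
                              expected$diabetic, expected$sbp_band, expected$chol_band)
  dup <- unique(keys[duplicated(keys)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate cell key(s): ", .fmt_keys(dup)))
  }
  absent <- setdiff(expected_keys, keys)
  if (length(absent)) {
    problems <- c(problems, paste0("missing cell key(s): ", .fmt_keys(absent)))
  }
  extra <- setdiff(keys, expected_keys)
  if (length(extra)) {
    problems <- c(problems, paste0("unrecognised cell key(s): ", .fmt_keys(extra)))
  }

  if (length(problems)) {
    cvd_log("chart validation failed (%d problem group(s))", length(problems),
            level = "ERROR")
    stop("invalid chart specification:\n  - ",
         paste(problems, collapse = "\n  - "))
  }

  structure(
    list(
      region_id = region_id,
      variant = variant,
      cells = cells[match(expected_keys, keys),
                    c("sex", "age_band", "smoker", "diabetic", "sbp_band",
                      "chol_band", "risk_band")],
      index = stats::setNames(cells$risk_band[match(expected_keys, keys)],
                              expected_keys)
    ),
    class = "chart_spec"
  )
}

#' @export
print.chart_spec <- function(x, ...) {
  cat(sprintf("<chart_spec> region %s, variant %s, %d cells\n",
              x$region_id, x$variant, nrow(x$cells)))
  cat("risk band distribution:\n")
  print(table(factor(x$cells$risk_band, levels = .RISK_BANDS)))
  invisible(x)
}

#' Read a chart definition file
#'
#' Accepts the documented CSV schema (header
#' `region_id,variant,sex,age_band,smoker,diabetic,sbp_band,chol_band,risk_band`,
#' one cell per row, `chol_band` empty for without-cholesterol rows) or the
#' equivalent JSON schema (object with `region_id`, `variant` and a `cells`
#' array). A file must contain exactly one chart variant; the result is
#' validated with [chart_spec()].
#'
#' @param path Path to a `.csv` or `.json` chart file.
#' @return A validated `chart_spec`.
#' @export
load_chart <- function(path) {
  if (!file.exists(path)) stop("chart file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- jsonlite::fromJSON(path)
    if (is.null(doc$cells) || is.null(doc$variant)) {
      stop("chart JSON must contain 'variant' and a 'cells' array: ", path)
    }
    cells <- as.data.frame(doc$cells, stringsAsFactors = FALSE)
    variant <- doc$variant
    region <- doc$region_id %||% "unspecified"
  } else {
    raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    needed <- c("region_id", "variant", "sex", "age_band", "smoker", "diabetic",
                "sbp_band", "chol_band", "risk_band")
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols)) {
      stop("chart CSV is missing columns: ", paste(missing_cols, collapse = ", "))
    }
    raw$chol_band[raw$chol_band == ""] <- NA_character_
    variant <- unique(raw$variant)
    region <- paste(unique(raw$region_id), collapse = "+")
    cells <- raw
  }
  if (length(variant) != 1) {
    stop("chart file must contain exactly one variant, found: ",
         paste(variant, collapse = ", "))
  }
  spec <- chart_spec(cells, variant = variant, region_id = region)
  cvd_log("loaded chart '%s' (%s, %d cells) from %s", spec$region_id,
          spec$variant, nrow(spec$cells), path)
  spec
}

#' Write a chart specification to file
#'
#' Inverse of [load_chart()]; the format is chosen by file extension
#' (`.csv` or `.json`).
#'
#' @param chart A `chart_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chart <- function(chart, path) {
  stopifnot(inherits(chart, "chart_spec"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- list(region_id = chart$region_id, variant = chart$variant,
                cells = chart$cells)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    out <- cbind(region_id = chart$region_id, variant = chart$variant,
                 chart$cells)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Choose the chart variant for a profile
#'
#' Individuals with a measured total cholesterol are scored on the
#' with-cholesterol charts; individuals whose cholesterol is missing fall
#' back to the without-cholesterol charts. A non-positive cholesterol value
#' is an input error, never a silent fallback.
#'
#' @param profile Data frame (or list) with at least a `total_cholesterol`
#'   element in mmol/l, `NA` meaning not measured.
#' @return Character vector of `"with_cholesterol"` /
#'   `"without_cholesterol"`, one per profile row.
#' @export
select_variant <- function(profile) {
  tc <- profile$total_cholesterol
  if (is.null(tc)) stop("profile lacks a total_cholesterol field")
  bad <- !is.na(tc) & tc <= 0
  if (any(bad)) {
    stop("non-positive total cholesterol is an invalid measurement, ",
         "not a missing value: ", paste(unique(tc[bad]), collapse = ", "))
  }
  ifelse(is.na(tc), "without_cholesterol", "with_cholesterol")
}

#' Look up the chart risk band for derived profiles
#'
#' Pure, deterministic single-cell lookup: each profile row is banded with
#' [to_age_band()], [to_sbp_band()] and (for the with-cholesterol variant)
#' [to_chol_band()], combined with the smoking and diabetes indicators, and
#' matched against the chart.
#'
#' @param chart A validated `chart_spec`.
#' @param profile Data frame with columns `sex`, `age`, `smoker`,
#'   `diabetic`, `sbp` and `total_cholesterol` (mmol/l, `NA` = not
#'   measured). Every row must require the chart's variant (see
#'   [select_variant()]); a mismatch is an error.
#' @return Character vector of risk band labels.
#' @export
chart_lookup <- function(chart, profile) {
  stopifnot(inherits(chart, "chart_spec"))
  profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  want <- select_variant(profile)
  mism <- want != chart$variant
  if (any(mism)) {
    stop(sprintf(
      "variant mismatch: %d profile(s) require the %s chart but a %s chart was given",
      sum(mism), paste(unique(want[mism]), collapse = "/"), chart$variant))
  }
  bad_sex <- !profile$sex %in% .SEXES
  if (any(bad_sex)) {
    stop("sex must be one of ", paste(.SEXES, collapse = ", "), "; got: ",
         paste(unique(profile$sex[bad_sex]), collapse = ", "))
  }
  if (anyNA(profile$smoker) || anyNA(profile$diabetic) ||
      anyNA(profile$age) || anyNA(profile$sbp)) {
    stop("chart lookup requires non-missing age, sbp, smoker and diabetic")
  }
  chol <- if (chart$variant == "with_cholesterol") {
    to_chol_band(profile$total_cholesterol)
  } else NULL
  keys <- .chart_key(profile$sex, to_age_band(profile$age), profile$smoker,
                     profile$diabetic, to_sbp_band(profile$sbp), chol)
  band <- chart$index[keys]
  if (anyNA(band)) {
    stop("no chart cell for key(s): ", .fmt_keys(unique(keys[is.na(band)])))
  }
  unname(band)
}
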