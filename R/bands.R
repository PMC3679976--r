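# Band structure of WHO/ISH-style risk prediction charts. The charts are
# lookup tables, not equations: every continuous input is mapped onto a fixed
# row/column band before lookup. Band edges are lower-inclusive throughout,
# consistent with the ">="-style thresholds used by the clinical definitions.

.AGE_BANDS  <- c("40-49", "50-59", "60-69", "70+")
.SBP_BANDS  <- c("<140", "140-159", "160-179", ">=180")
.CHOL_BANDS <- 4:8
.RISK_BANDS <- c("<10", "10-<20", "20-<30", "30-<40", ">=40")
.CATEGORIES <- c("low", "moderate", "high", "very_high")
.REPORTING  <- c("low", "moderate", "high_ge20")
.SEXES      <- c("male", "female")

.BAND_TO_CATEGORY <- c(
  "<10" = "low", "10-<20" = "moderate", "20-<30" = "high",
  "30-<40" = "very_high", ">=40" = "very_high"
)
.CATEGORY_TO_REPORTING <- c(
  low = "low", moderate = "moderate", high = "high_ge20", very_high = "high_ge20"
)

#' Admissible chart labels
#'
#' The closed label sets used by the chart engine: five ten-year total CVD
#' risk bands (`%` probability of a fatal or non-fatal cardiovascular event),
#' four clinical risk categories, and the three collapsed reporting
#' categories in which everything at or above 20% ten-year risk is pooled
#' into `high_ge20`.
#'
#' @return A character vector of labels, in increasing risk order.
#' @export
risk_bands <- function() .RISK_BANDS

#' @rdname risk_bands
#' @export
risk_categories <- function() .CATEGORIES

#' @rdname risk_bands
#' @export
reporting_categories <- function() .REPORTING

#' Map age in years to a chart age band
#'
#' The charts cover ages 40 and above in decade bands. Ages below 40 are an
#' error here (the instrument is not defined for them); dropping under-age
#' records is the pipeline's responsibility, not the chart engine's.
#'
#' @param age Numeric vector of ages in years. `NA` propagates.
#' @return Character vector with levels `r toString(.AGE_BANDS)`.
#' @export
#' @examples
#' to_age_band(c(40, 64, 71))
to_age_band <- function(age) {
  stopifnot(is.numeric(age))
  bad <- !is.na(age) & age < 40
  if (any(bad)) {
    stop("age below 40 is outside chart scope: ",
         paste(unique(age[bad]), collapse = ", "))
  }
  as.character(cut(age, breaks = c(40, 50, 60, 70, Inf),
                   labels = .AGE_BANDS, right = FALSE))
}

#' Map systolic blood pressure to a chart SBP band
#'
#' Band edges are lower-inclusive: 140 mmHg falls in `140-159`, 160 in
#' `160-179`, 180 in `>=180`.
#'
#' @param sbp Numeric vector, mmHg. Must be strictly positive; `NA`
#'   propagates.
#' @return Character vector with levels `r toString(.SBP_BANDS)`.
#' @export
#' @examples
#' to_sbp_band(c(139.9, 140, 160, 200))
to_sbp_band <- function(sbp) {
  stopifnot(is.numeric(sbp))
  bad <- !is.na(sbp) & sbp <= 0
  if (any(bad)) {
    stop("systolic blood pressure must be positive: ",
         paste(unique(sbp[bad]), collapse = ", "))
  }
  as.character(cut(sbp, breaks = c(-Inf, 140, 160, 180, Inf),
                   labels = .SBP_BANDS, right = FALSE))
}

#' Map total cholesterol to the nearest chart column
#'
#' The with-cholesterol charts print integer columns 4 to 8 mmol/l. Values
#' map to the nearest column, exact midpoints (x.5) round up, and values
#' outside 4--8 clamp to the boundary columns.
#'
#' @param tc Numeric vector, total cholesterol in mmol/l. Must be strictly
#'   positive; `NA` propagates.
#' @return Integer vector in `4:8`.
#' @export
#' @examples
#' to_chol_band(c(3.2, 5.5, 9.1))
to_chol_band <- function(tc) {
  stopifnot(is.numeric(tc))
  bad <- !is.na(tc) & tc <= 0
  if (any(bad)) {
    stop("total cholesterol must be positive: ",
         paste(unique(tc[bad]), collapse = ", "))
  }
  as.integer(pmin(pmax(floor(tc + 0.5), 4L), 8L))
}

#' Convert a chart risk band to its clinical and reporting categories
#'
#' Ten-year total CVD risk below 10% is "low", 10 to <20% "moderate", 20 to
#' <30% "high" and >=30% "very high". For population reporting, `high` and
#' `very_high` collapse into the single `high_ge20` category (>=20%).
#'
#' @param band Character vector of risk band labels (see [risk_bands()]).
#' @return Character vector of category labels.
#' @export
#' @examples
#' band_to_category(c("<10", "20-<30", ">=40"))
band_to_category <- function(band) {
  unknown <- !is.na(band) & !band %in% .RISK_BANDS
  if (any(unknown)) {
    stop("unknown risk band label: ", paste(unique(band[unknown]), collapse = ", "))
  }
  unname(.BAND_TO_CATEGORY[band])
}

#' @rdname band_to_category
#' @param category Character vector of category labels (see
#'   [risk_categories()]).
#' @export
reporting_category <- function(category) {
  unknown <- !is.na(category) & !category %in% .CATEGORIES
  if (any(unknown)) {
    stop("unknown risk category: ", paste(unique(category[unknown]), collapse = ", "))
  }
  unname(.CATEGORY_TO_REPORTING[category])
}
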