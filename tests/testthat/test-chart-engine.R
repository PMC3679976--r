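# Chart engine: band mappings, chart validation, variant selection, lookup.

test_that("band mappings honour lower-inclusive edges and clamp correctly", {
  expect_identical(to_age_band(c(40, 49, 50, 64, 69, 70, 85)),
                   c("40-49", "40-49", "50-59", "60-69", "60-69", "70+", "70+"))
  expect_error(to_age_band(39), "outside chart scope")
  expect_identical(to_sbp_band(c(139.9, 140, 159.99, 160, 179.5, 180, 200)),
                   c("<140", "140-159", "140-159", "160-179", "160-179",
                     ">=180", ">=180"))
  expect_error(to_sbp_band(0), "positive")
  expect_identical(to_chol_band(c(3.2, 4.49, 4.5, 5.5, 6.49, 8, 9.1)),
                   c(4L, 4L, 5L, 6L, 6L, 8L, 8L))
  expect_error(to_chol_band(-1), "positive")
  # NA propagates rather than erroring
  expect_true(is.na(to_age_band(NA_real_)))
  expect_true(is.na(to_sbp_band(NA_real_)))
  expect_true(is.na(to_chol_band(NA_real_)))
})

test_that("band mappings are total and monotone on their domains", {
  ages <- sort(runif(200, 40, 90))
  sbps <- sort(runif(200, 60, 240))
  tcs <- sort(runif(200, 1, 12))
  expect_true(all(!is.na(to_age_band(ages))))
  expect_true(all(diff(match(to_age_band(ages), c("40-49", "50-59", "60-69", "70+"))) >= 0))
  expect_true(all(diff(match(to_sbp_band(sbps),
                             c("<140", "140-159", "160-179", ">=180"))) >= 0))
  expect_true(all(diff(to_chol_band(tcs)) >= 0))
})

test_that("risk bands collapse to the documented categories", {
  expect_identical(band_to_category(risk_bands()),
                   c("low", "moderate", "high", "very_high", "very_high"))
  expect_identical(reporting_category(c("low", "moderate", "high", "very_high")),
                   c("low", "moderate", "high_ge20", "high_ge20"))
  expect_error(band_to_category("15%"), "unknown risk band")
  expect_error(reporting_category("extreme"), "unknown risk category")
})

test_that("chart validation accepts exactly the full cross-product", {
  without <- make_fixture_chart("uniform", "without_cholesterol")
  with <- make_fixture_chart("uniform", "with_cholesterol")
  expect_identical(nrow(without$cells), 128L)
  expect_identical(nrow(with$cells), 640L)
  # independent enumeration of the expected cell count
  expect_identical(nrow(with$cells), 2L * 4L * 2L * 2L * 4L * 5L)
  expect_identical(nrow(without$cells), 2L * 4L * 2L * 2L * 4L)

  cells <- without$cells
  expect_error(chart_spec(cells[-17, ], "without_cholesterol"),
               "missing cell key")
  expect_error(chart_spec(rbind(cells, cells[5, ]), "without_cholesterol"),
               "duplicate cell key")
  bad <- cells
  bad$risk_band[3] <- "15%"
  expect_error(chart_spec(bad, "without_cholesterol"), "unknown risk band label")
})

test_that("validation errors name every offending cell key", {
  chart <- make_fixture_chart("uniform", "without_cholesterol")
  drop <- c(1L, 100L, 128L)
  dropped_keys <- with(chart$cells[drop, ], paste(
    sex, age_band, smoker, diabetic, sbp_band, "", sep = "|"))
  err <- tryCatch(chart_spec(chart$cells[-drop, ], "without_cholesterol"),
                  error = conditionMessage)
  for (k in dropped_keys) expect_match(err, k, fixed = TRUE)
})

test_that("chart files round-trip through CSV and JSON", {
  chart <- make_fixture_chart("threshold", "with_cholesterol")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_chart(chart, csv)
  write_chart(chart, js)
  expect_identical(load_chart(csv)$index, chart$index)
  expect_identical(load_chart(js)$index, chart$index)
  expect_identical(load_chart(csv)$variant, "with_cholesterol")

  # file minus one row is rejected naming the lost key
  mut <- chart$cells[-40, ]
  lost <- with(chart$cells[40, ],
               paste(sex, age_band, smoker, diabetic, sbp_band, chol_band,
                     sep = "|"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_chart_cells(mut, "with_cholesterol", path)
  expect_error(load_chart(path), lost, fixed = TRUE)

  # a file mixing variants is not a single chart
  both <- rbind(
    cbind(region_id = "X", variant = "with_cholesterol",
          make_fixture_chart("uniform", "with_cholesterol")$cells),
    cbind(region_id = "X", variant = "without_cholesterol",
          make_fixture_chart("uniform", "without_cholesterol")$cells))
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(both, p2, row.names = FALSE, na = "")
  expect_error(load_chart(p2), "exactly one variant")
})

test_that("variant selection follows cholesterol availability, sentinels error", {
  expect_identical(select_variant(list(total_cholesterol = c(5.1, NA))),
                   c("with_cholesterol", "without_cholesterol"))
  expect_error(select_variant(list(total_cholesterol = 0)),
               "invalid measurement")
})

test_that("chart lookup is a pure single-cell map", {
  charts <- fixture_charts("uniform")
  prof <- random_profiles(50, seed = 11)
  prof_with <- prof[!is.na(prof$total_cholesterol), ]
  prof_without <- prof[is.na(prof$total_cholesterol), ]
  expect_true(all(chart_lookup(charts$with, prof_with) == "<10"))
  expect_true(all(chart_lookup(charts$without, prof_without) == "<10"))
  # purity: identical calls give identical results
  expect_identical(chart_lookup(charts$with, prof_with),
                   chart_lookup(charts$with, prof_with))
  # variant mismatch is an error, not a silent fallback
  expect_error(chart_lookup(charts$with, prof_without), "variant mismatch")
  expect_error(chart_lookup(charts$without, prof_with), "variant mismatch")
})

test_that("adversarial chart: exactly one profile key maps to the deviant band", {
  chart <- make_fixture_chart("adversarial", "with_cholesterol")
  prof <- profiles_for_cells(chart$cells)
  bands <- chart_lookup(chart, prof)
  hot <- which(bands == ">=40")
  expect_length(hot, 1L)
  cell <- chart$cells[hot, ]
  expect_identical(cell$sex, "male")
  expect_identical(cell$age_band, "60-69")
  expect_identical(cell$sbp_band, ">=180")
  expect_identical(cell$chol_band, 8L)
  expect_true(all(bands[-hot] == "<10"))
})

test_that("threshold fixture chart follows its documented score rule", {
  chart <- make_fixture_chart("threshold", "without_cholesterol")
  cells <- chart$cells
  score <- (match(cells$age_band, c("40-49", "50-59", "60-69", "70+")) - 1L) +
    (match(cells$sbp_band, c("<140", "140-159", "160-179", ">=180")) - 1L) +
    cells$smoker + cells$diabetic
  expect_identical(cells$risk_band, risk_bands()[pmin(score + 1L, 5L)])
})
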