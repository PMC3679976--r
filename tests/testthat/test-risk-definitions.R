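# Derivation of chart inputs and threshold-based flags.

test_that("analysis blood pressure is the mean of the last two readings", {
  expect_identical(derive_sbp(150, 142, 138), 140)
  expect_identical(derive_sbp(120, 120, 120), 120)
  expect_identical(derive_dbp(95, 91, 89), 90)
  expect_error(derive_sbp(130, 128, NA), "missing input")
  expect_error(derive_sbp(130, NA, 126), "missing input")
  expect_error(derive_sbp(130, -5, 126), "positive")
})

test_that("smoking combines current use with recent quitting", {
  expect_true(is_smoker(TRUE, FALSE))
  expect_true(is_smoker(FALSE, TRUE))
  expect_false(is_smoker(FALSE, FALSE))
  expect_true(is_smoker(NA, TRUE))       # medication-style OR semantics
  expect_true(is.na(is_smoker(NA, FALSE)))
})

test_that("diabetes uses specimen-specific thresholds plus medication", {
  expect_true(is_diabetic(6.1, "whole_blood", FALSE))
  expect_false(is_diabetic(6.09, "whole_blood", FALSE))
  expect_false(is_diabetic(6.9, "plasma", FALSE))
  expect_true(is_diabetic(7.0, "plasma", FALSE))
  expect_true(is_diabetic(5.0, "plasma", TRUE))
  expect_true(is_diabetic(NA, NA, TRUE))
  expect_error(is_diabetic(NA, NA, FALSE), "missing input")
  expect_true(is.na(is_diabetic(NA, NA, FALSE, strict = FALSE)))
  expect_error(is_diabetic(6.0, "serum", FALSE), "glucose_specimen")
  expect_error(is_diabetic(6.0, NA, FALSE), "glucose_specimen is required")
})

test_that("single-risk-factor definitions match the clinical thresholds", {
  expect_false(has_hypertension(139, 89, FALSE))
  expect_true(has_hypertension(120, 92, FALSE))
  expect_true(has_hypertension(118, 76, TRUE))
  expect_true(has_hypercholesterolemia(6.2, FALSE))
  expect_false(has_hypercholesterolemia(6.19, FALSE))
  expect_true(has_hypercholesterolemia(4.0, TRUE))
  expect_error(has_hypercholesterolemia(NA, FALSE), "missing input")
  expect_true(is.na(has_hypercholesterolemia(NA, FALSE, strict = FALSE)))
})

test_that("all nine thresholds follow the stated inclusive/strict pattern", {
  eps <- 1e-3
  probe <- function(x0) c(x0 - eps, x0, x0 + eps)
  # each row: values below / at / above the threshold -> expected flags
  expect_identical(has_hypertension(probe(140), 80, FALSE), c(FALSE, TRUE, TRUE))
  expect_identical(has_hypertension(120, probe(90), FALSE), c(FALSE, TRUE, TRUE))
  expect_identical(is_diabetic(probe(6.1), "whole_blood", FALSE), c(FALSE, TRUE, TRUE))
  expect_identical(is_diabetic(probe(7.0), "plasma", FALSE), c(FALSE, TRUE, TRUE))
  expect_identical(has_hypercholesterolemia(probe(6.2), FALSE), c(FALSE, TRUE, TRUE))
  # promotion thresholds (160/100 and cholesterol 8) are inclusive
  low3 <- rep("low", 3)
  expect_identical(
    apply_scenario(low3, data.frame(sbp = probe(160), dbp = 80,
                                    total_cholesterol = 5,
                                    on_ht_medication = FALSE), "CHART_BP"),
    c("low", "high", "high"))
  expect_identical(
    apply_scenario(low3, data.frame(sbp = 120, dbp = probe(100),
                                    total_cholesterol = 5,
                                    on_ht_medication = FALSE), "CHART_BP"),
    c("low", "high", "high"))
  expect_identical(
    apply_scenario(low3, data.frame(sbp = 120, dbp = 80,
                                    total_cholesterol = probe(8),
                                    on_ht_medication = FALSE), "CHART_BP_CHOL"),
    c("low", "high", "high"))
  # elevating flags: BMI inclusive, MET/pulse/TG/HDL strict
  fl <- function(...) {
    args <- list(sex = "male", bmi = NA_real_, met_minutes = NA_real_,
                 pulse = NA_real_, on_ht_medication = FALSE,
                 triglycerides = NA_real_, hdl = NA_real_)
    over <- list(...)
    args[names(over)] <- over
    elevating_flags(as.data.frame(args))
  }
  expect_identical(fl(bmi = probe(30))$obesity, c(FALSE, TRUE, TRUE))
  expect_identical(fl(met_minutes = probe(600))$low_physical_activity,
                   c(TRUE, FALSE, FALSE))
  expect_identical(fl(pulse = probe(90))$high_pulse, c(FALSE, FALSE, TRUE))
  expect_identical(fl(triglycerides = probe(2))$high_triglycerides,
                   c(FALSE, FALSE, TRUE))
  expect_identical(fl(hdl = probe(1))$low_hdl, c(TRUE, FALSE, FALSE))
  fem <- elevating_flags(data.frame(
    sex = "female", bmi = NA, met_minutes = NA, pulse = NA,
    on_ht_medication = FALSE, triglycerides = NA, hdl = probe(1.3)))
  expect_identical(fem$low_hdl, c(TRUE, FALSE, FALSE))
})

test_that("threshold flags agree with a brute-force re-check on a random grid", {
  set.seed(314)
  n <- 4000
  g <- data.frame(
    sex = sample(c("male", "female"), n, TRUE),
    sbp = runif(n, 130, 150), dbp = runif(n, 80, 100),
    glucose = runif(n, 5.5, 7.5),
    specimen = sample(c("whole_blood", "plasma"), n, TRUE),
    tc = runif(n, 5.5, 8.5),
    bmi = runif(n, 28, 32), met = runif(n, 400, 800),
    pulse = runif(n, 85, 95), tg = runif(n, 1.5, 2.5),
    hdl = runif(n, 0.8, 1.5),
    med_ht = sample(c(TRUE, FALSE), n, TRUE),
    med_dm = sample(c(TRUE, FALSE), n, TRUE),
    med_ch = sample(c(TRUE, FALSE), n, TRUE)
  )
  # independent re-statement of each definition
  expect_identical(has_hypertension(g$sbp, g$dbp, g$med_ht),
                   ifelse(g$sbp >= 140, TRUE,
                          ifelse(g$dbp >= 90, TRUE, g$med_ht)))
  expect_identical(is_diabetic(g$glucose, g$specimen, g$med_dm),
                   ifelse(g$specimen == "whole_blood", g$glucose >= 6.1,
                          g$glucose >= 7.0) | g$med_dm)
  expect_identical(has_hypercholesterolemia(g$tc, g$med_ch),
                   ifelse(g$tc >= 6.2, TRUE, g$med_ch))
  fl <- elevating_flags(data.frame(
    sex = g$sex, bmi = g$bmi, met_minutes = g$met, pulse = g$pulse,
    on_ht_medication = g$med_ht, triglycerides = g$tg, hdl = g$hdl))
  expect_identical(fl$obesity, !(g$bmi < 30))
  expect_identical(fl$low_physical_activity, !(g$met >= 600))
  expect_identical(fl$high_pulse, !(g$pulse <= 90))
  expect_identical(fl$high_triglycerides, !(g$tg <= 2))
  expect_identical(fl$low_hdl,
                   ifelse(g$sex == "male", g$hdl < 1.0, g$hdl < 1.3))
  expect_identical(fl$on_ht_medication, g$med_ht)
})

test_that("hypertension is monotone non-decreasing in each BP reading", {
  set.seed(99)
  for (i in 1:50) {
    r <- runif(6, 70, 180)
    base <- has_hypertension(derive_sbp(r[1], r[2], r[3]),
                             derive_dbp(r[4], r[5], r[6]), FALSE)
    bumped <- has_hypertension(derive_sbp(r[1], r[2] + 20, r[3] + 20),
                               derive_dbp(r[4], r[5] + 20, r[6] + 20), FALSE)
    expect_true(bumped >= base)
  }
})

test_that("missing inputs leave flags undefined, not falsely negative", {
  fl <- elevating_flags(data.frame(
    sex = c("male", "male", "female"),
    bmi = c(NA, 35, NA), met_minutes = NA_real_, pulse = NA_real_,
    on_ht_medication = c(NA, FALSE, FALSE),
    triglycerides = NA_real_, hdl = c(NA, NA, 1.0)))
  expect_true(is.na(fl$obesity[1]))
  # all six inputs missing -> any_elevating undefined
  expect_true(is.na(fl$any_elevating[1]))
  # one TRUE among missings -> TRUE
  expect_true(fl$any_elevating[2])
  # female hdl 1.0 < 1.3 -> TRUE regardless of other missings
  expect_true(fl$low_hdl[3])
  expect_true(fl$any_elevating[3])
  # all-FALSE observed with some missing -> FALSE (restricted OR)
  fl2 <- elevating_flags(data.frame(
    sex = "male", bmi = 22, met_minutes = NA_real_, pulse = 70,
    on_ht_medication = FALSE, triglycerides = NA_real_, hdl = 1.5))
  expect_false(fl2$any_elevating)
})
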