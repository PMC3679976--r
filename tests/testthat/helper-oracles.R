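# Shared fixtures and independently coded oracles.

# Random derived profiles spanning every band and threshold region.
random_profiles <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = sample(40:79, n, replace = TRUE),
    smoker = sample(c(TRUE, FALSE), n, replace = TRUE),
    diabetic = sample(c(TRUE, FALSE), n, replace = TRUE),
    sbp = runif(n, 90, 220),
    dbp = runif(n, 50, 130),
    total_cholesterol = ifelse(runif(n) < 0.3, NA, runif(n, 3, 10)),
    on_ht_medication = sample(c(TRUE, FALSE), n, replace = TRUE),
    bmi = runif(n, 18, 40),
    met_minutes = runif(n, 0, 3000),
    pulse = runif(n, 50, 110),
    triglycerides = runif(n, 0.5, 4),
    hdl = runif(n, 0.5, 2.2),
    stringsAsFactors = FALSE
  )
}

# Chart-category per profile using the per-record variant fallback.
chart_categories <- function(profiles, chart_with, chart_without) {
  v <- select_variant(profiles)
  band <- rep(NA_character_, nrow(profiles))
  if (any(v == "with_cholesterol")) {
    band[v == "with_cholesterol"] <-
      chart_lookup(chart_with, profiles[v == "with_cholesterol", ])
  }
  if (any(v == "without_cholesterol")) {
    band[v == "without_cholesterol"] <-
      chart_lookup(chart_without, profiles[v == "without_cholesterol", ])
  }
  band_to_category(band)
}

# One representative derived profile per chart cell, for exhaustive
# enumeration of the lookup.
profiles_for_cells <- function(cells) {
  age_rep <- c("40-49" = 45, "50-59" = 55, "60-69" = 65, "70+" = 75)
  sbp_rep <- c("<140" = 120, "140-159" = 150, "160-179" = 170, ">=180" = 190)
  data.frame(
    sex = cells$sex,
    age = unname(age_rep[cells$age_band]),
    smoker = cells$smoker == 1,
    diabetic = cells$diabetic == 1,
    sbp = unname(sbp_rep[cells$sbp_band]),
    total_cholesterol = as.numeric(cells$chol_band),
    stringsAsFactors = FALSE
  )
}

# Rao-Wu rescaled cluster bootstrap for a weighted proportion under
# stratified cluster sampling: per replicate, resample n_h - 1 clusters
# with replacement within each stratum, upweighting by n_h / (n_h - 1), so
# the bootstrap variance is unbiased for the linearization target.
boot_cluster_ci <- function(x, weight, stratum, cluster, reps = 10000,
                            conf = 0.95, seed = 1) {
  set.seed(seed)
  key <- paste(stratum, cluster, sep = "\x1f")
  swx <- rowsum(weight * x, key)[, 1]
  sw <- rowsum(weight, key)[, 1]
  cl_stratum <- sub("\x1f.*$", "", names(swx))
  idx_by <- split(seq_along(swx), cl_stratum)
  ps <- vapply(seq_len(reps), function(r) {
    num <- 0; den <- 0
    for (ii in idx_by) {
      nh <- length(ii)
      take <- ii[sample.int(nh, nh - 1L, replace = TRUE)]
      f <- nh / (nh - 1)
      num <- num + f * sum(swx[take])
      den <- den + f * sum(sw[take])
    }
    num / den
  }, numeric(1))
  stats::quantile(ps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
}

# Minimal complete participant record(s) for ingest-level tests.
make_record <- function(id = "P1", stratum = "S1", cluster = "S1-C1",
                        weight = 1, sex = "male", age = 50,
                        sbp = c(130, 128, 126), dbp = c(84, 82, 80),
                        current_smoker = FALSE, quit_lt_1yr = FALSE,
                        fasting_glucose = 5.0,
                        glucose_specimen = "whole_blood",
                        on_dm_medication = FALSE, total_cholesterol = 5.0,
                        on_chol_medication = FALSE, on_ht_medication = FALSE,
                        bmi = 24, met_minutes = 1200, pulse = 70,
                        triglycerides = 1.2, hdl = 1.4) {
  data.frame(
    participant_id = id, stratum_id = stratum, cluster_id = cluster,
    weight = weight, sex = sex, age = age,
    sbp1 = sbp[1], sbp2 = sbp[2], sbp3 = sbp[3],
    dbp1 = dbp[1], dbp2 = dbp[2], dbp3 = dbp[3],
    current_smoker = current_smoker, quit_lt_1yr = quit_lt_1yr,
    fasting_glucose = fasting_glucose, glucose_specimen = glucose_specimen,
    on_dm_medication = on_dm_medication,
    total_cholesterol = total_cholesterol,
    on_chol_medication = on_chol_medication,
    on_ht_medication = on_ht_medication, bmi = bmi,
    met_minutes = met_minutes, pulse = pulse,
    triglycerides = triglycerides, hdl = hdl,
    stringsAsFactors = FALSE
  )
}

fixture_charts <- function(style) {
  list(with = make_fixture_chart(style, "with_cholesterol"),
       without = make_fixture_chart(style, "without_cholesterol"))
}

# Write a chart's cells (possibly mutated) to a CSV in the documented schema.
write_chart_cells <- function(cells, variant, path, region = "FIXTURE") {
  out <- cbind(region_id = region, variant = variant, cells)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  path
}
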