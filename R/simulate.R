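# Synthetic survey generator: STEPS-like microdata with known ground truth.
# The generator emulates the measurement structure of a national NCD
# risk-factor survey -- stratified multistage cluster sampling with unequal
# cluster selection probabilities, per-cluster non-response, sex
# post-stratification, three seated blood-pressure readings around a
# person-level latent mean, specimen-specific fasting glucose and partial
# biochemistry missingness -- while keeping every planted prevalence
# recoverable. Correlations are induced only through age and sex covariate
# effects, which keeps the realized truth computable directly.

#' Generator configuration
#'
#' All parameters of the synthetic survey, each defaulted to a plausible
#' value for an adult (40--64) general population in a middle-income
#' setting. The seed fully determines the output.
#'
#' @param n_strata Number of design strata (e.g. regions).
#' @param clusters_per_stratum Primary sampling units per stratum.
#' @param persons_per_cluster Persons sampled per cluster (before
#'   non-response).
#' @param seed Integer RNG seed.
#' @param age_range Inclusive age bounds of the sampled population.
#' @param male_share Probability a sampled person is male.
#' @param smoking_prob Named vector `c(male=, female=)`: probability of
#'   current smoking.
#' @param quit_lt_1yr_prob Probability a current non-smoker quit less than
#'   one year before the survey.
#' @param sbp,dbp Blood pressure models: `mean40` (mmHg at age 40),
#'   `age_slope` (mmHg/year), `male_shift` (mmHg), `sd_between`
#'   (between-person SD), `sd_reading` (within-person SD of each of the
#'   three readings).
#' @param glucose Fasting glucose model: lognormal `meanlog`/`sdlog` on the
#'   whole-blood scale, `plasma_share` of specimens, `plasma_factor`
#'   (plasma values exceed whole-blood by ~11%), `missing_prob`, and
#'   medication probabilities given above-/below-threshold glucose.
#' @param cholesterol Normal `mean`/`sd` (mmol/l), `missing_prob`
#'   (exercises the without-cholesterol chart fallback), medication
#'   probabilities given high/normal cholesterol.
#' @param triglycerides,hdl,bmi,met,pulse Models for the elevating-factor
#'   inputs (lognormal or normal parameters plus a missingness
#'   probability; `hdl` has sex-specific means).
#' @param ht_med_prob Named vector `c(hypertensive=, other=)`: probability
#'   of self-reported antihypertensive medication given latent hypertensive
#'   status.
#' @param design Sampling design: `cluster_prob_range` (cluster selection
#'   probabilities, spread evenly across clusters within each stratum),
#'   `person_sampling_prob` (within-cluster selection probability),
#'   `nonresponse_rate`, and `poststrat_male_share` (target male share the
#'   weights are post-stratified to).
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_strata = 3, clusters_per_stratum = 10, persons_per_cluster = 40,
    seed = 1L, age_range = c(40, 64), male_share = 0.5,
    smoking_prob = c(male = 0.5, female = 0.08), quit_lt_1yr_prob = 0.03,
    sbp = list(mean40 = 124, age_slope = 0.55, male_shift = 3,
               sd_between = 15, sd_reading = 4),
    dbp = list(mean40 = 77, age_slope = 0.2, male_shift = 2,
               sd_between = 9, sd_reading = 3),
    glucose = list(meanlog = log(5.1), sdlog = 0.16, plasma_share = 0.5,
                   plasma_factor = 1.11, missing_prob = 0.05,
                   med_prob_diabetic = 0.35, med_prob_other = 0.01),
    cholesterol = list(mean = 5.2, sd = 1.05, missing_prob = 0.25,
                       med_prob_high = 0.2, med_prob_other = 0.02),
    triglycerides = list(meanlog = log(1.5), sdlog = 0.45, missing_prob = 0.1),
    hdl = list(mean_male = 1.15, mean_female = 1.35, sd = 0.28,
               missing_prob = 0.1),
    bmi = list(mean = 24.5, sd = 4, missing_prob = 0.02),
    met = list(meanlog = log(1200), sdlog = 1.1, missing_prob = 0.05),
    pulse = list(mean = 76, sd = 11, missing_prob = 0.02),
    ht_med_prob = c(hypertensive = 0.3, other = 0.03),
    design = list(cluster_prob_range = c(0.1, 0.9),
                  person_sampling_prob = 0.1, nonresponse_rate = 0.1,
                  poststrat_male_share = 0.5)) {
  config <- list(
    n_strata = n_strata, clusters_per_stratum = clusters_per_stratum,
    persons_per_cluster = persons_per_cluster, seed = seed,
    age_range = age_range, male_share = male_share,
    smoking_prob = smoking_prob, quit_lt_1yr_prob = quit_lt_1yr_prob,
    sbp = sbp, dbp = dbp, glucose = glucose, cholesterol = cholesterol,
    triglycerides = triglycerides, hdl = hdl, bmi = bmi, met = met,
    pulse = pulse, ht_med_prob = ht_med_prob, design = design
  )
  validate_generator_config(config)
}

validate_generator_config <- function(config) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid generator config: ", msg)
  chk(config$n_strata >= 1 && config$clusters_per_stratum >= 1 &&
        config$persons_per_cluster >= 1, "design sizes must be >= 1")
  chk(is.numeric(config$seed) && length(config$seed) == 1 &&
        !is.na(config$seed), "seed must be a single number")
  chk(config$age_range[1] >= 0 && config$age_range[2] >= config$age_range[1],
      "age_range must be a non-decreasing pair")
  probs <- c(config$male_share, config$smoking_prob, config$quit_lt_1yr_prob,
             config$glucose$plasma_share, config$glucose$missing_prob,
             config$glucose$med_prob_diabetic, config$glucose$med_prob_other,
             config$cholesterol$missing_prob, config$cholesterol$med_prob_high,
             config$cholesterol$med_prob_other,
             config$triglycerides$missing_prob, config$hdl$missing_prob,
             config$bmi$missing_prob, config$met$missing_prob,
             config$pulse$missing_prob, config$ht_med_prob,
             config$design$person_sampling_prob,
             config$design$nonresponse_rate,
             config$design$poststrat_male_share)
  chk(all(probs >= 0 & probs <= 1), "all probabilities must lie in [0, 1]")
  sds <- c(config$sbp$sd_between, config$sbp$sd_reading,
           config$dbp$sd_between, config$dbp$sd_reading,
           config$glucose$sdlog, config$cholesterol$sd,
           config$triglycerides$sdlog, config$hdl$sd, config$bmi$sd,
           config$met$sdlog, config$pulse$sd)
  chk(all(sds >= 0), "all standard deviations must be >= 0")
  pr <- config$design$cluster_prob_range
  chk(all(pr > 0 & pr <= 1) && pr[2] >= pr[1],
      "cluster_prob_range must lie in (0, 1]")
  structure(config, class = "generator_config")
}

.rbern <- function(n, p) stats::rbinom(n, 1L, p) == 1L
.mask_na <- function(x, p) { x[.rbern(length(x), p)] <- NA; x }

# Deterministic rule behind the "threshold" fixture chart: risk increases
# with the age band, the SBP band, smoking and diabetes. Cholesterol is
# deliberately ignored so both variants agree and expected band
# distributions are computable in closed form.
.threshold_chart_band <- function(age, sbp, smoker, diabetic) {
  score <- (pmin(findInterval(age, c(40, 50, 60, 70)), 4L) - 1L) +
    findInterval(sbp, c(140, 160, 180)) +
    as.integer(smoker) + as.integer(diabetic)
  .RISK_BANDS[pmin(score + 1L, 5L)]
}

#' Generate a synthetic survey cohort with known truth
#'
#' Draws a full participant table under `config` together with a
#' `TruthRecord`: the realized (finite-sample) prevalence of every planted
#' factor, computed directly from the generated values, and the expected
#' chart-band distribution under the deterministic `"threshold"` fixture
#' chart rule. Truth is realized-sample, not model-parameter, so recovery
#' tests measure estimator error without conflating it with sampling
#' error. The RNG state of the session is left untouched.
#'
#' @param config A [generator_config()].
#' @return List with elements `records` (participant data frame, see
#'   [read_participants()]), `truth` (list of `prevalence` entries, each
#'   `value` + `n`, plus `chart_bands` and `n_records`) and `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(as.integer(config$seed))

  S <- config$n_strata; K <- config$clusters_per_stratum
  n0 <- config$persons_per_cluster
  des <- config$design
  p_sel <- if (K == 1) mean(des$cluster_prob_range) else {
    seq(des$cluster_prob_range[1], des$cluster_prob_range[2], length.out = K)
  }

  cl <- expand.grid(cluster = seq_len(K), stratum = seq_len(S),
                    KEEP.OUT.ATTRS = FALSE)
  cl$p_sel <- p_sel[cl$cluster]
  cl$n_resp <- stats::rbinom(nrow(cl), n0, 1 - des$nonresponse_rate)
  cl <- cl[cl$n_resp > 0, , drop = FALSE]

  N <- sum(cl$n_resp)
  idx <- rep(seq_len(nrow(cl)), cl$n_resp)
  stratum_id <- sprintf("S%02d", cl$stratum[idx])
  cluster_id <- sprintf("S%02d-C%03d", cl$stratum[idx], cl$cluster[idx])
  base_w <- 1 / (cl$p_sel[idx] * des$person_sampling_prob)
  nr_w <- n0 / cl$n_resp[idx]
  weight <- base_w * nr_w

  male <- .rbern(N, config$male_share)
  sex <- ifelse(male, "male", "female")
  age <- sample(seq(config$age_range[1], config$age_range[2]), N, replace = TRUE)

  # post-stratification of weights to the target sex distribution
  t_m <- des$poststrat_male_share
  share_m <- sum(weight[male]) / sum(weight)
  if (share_m > 0 && share_m < 1) {
    weight <- weight * ifelse(male, t_m / share_m, (1 - t_m) / (1 - share_m))
  }

  latent_bp <- function(m) {
    m$mean40 + m$age_slope * (age - 40) + ifelse(male, m$male_shift, 0) +
      stats::rnorm(N, 0, m$sd_between)
  }
  sbp_lat <- pmax(latent_bp(config$sbp), 70)
  dbp_lat <- pmax(latent_bp(config$dbp), 40)
  readings <- function(lat, sd) {
    replicate(3, pmax(lat + stats::rnorm(N, 0, sd), 30))
  }
  sbp_r <- readings(sbp_lat, config$sbp$sd_reading)
  dbp_r <- readings(dbp_lat, config$dbp$sd_reading)

  current_smoker <- .rbern(N, ifelse(male, config$smoking_prob[["male"]],
                                     config$smoking_prob[["female"]]))
  quit_lt_1yr <- !current_smoker & .rbern(N, config$quit_lt_1yr_prob)

  g <- config$glucose
  plasma <- .rbern(N, g$plasma_share)
  glucose_specimen <- ifelse(plasma, "plasma", "whole_blood")
  g0 <- stats::rlnorm(N, g$meanlog, g$sdlog)
  fasting_glucose <- ifelse(plasma, g0 * g$plasma_factor, g0)
  diabetic_by_glucose <- fasting_glucose >= ifelse(plasma, 7.0, 6.1)
  on_dm_medication <- .rbern(N, ifelse(diabetic_by_glucose,
                                       g$med_prob_diabetic, g$med_prob_other))
  fasting_glucose <- .mask_na(fasting_glucose, g$missing_prob)
  glucose_specimen[is.na(fasting_glucose)] <- NA_character_

  ch <- config$cholesterol
  tc_full <- pmax(stats::rnorm(N, ch$mean, ch$sd), 2)
  on_chol_medication <- .rbern(N, ifelse(tc_full >= 6.2, ch$med_prob_high,
                                         ch$med_prob_other))
  total_cholesterol <- .mask_na(tc_full, ch$missing_prob)

  triglycerides <- .mask_na(
    stats::rlnorm(N, config$triglycerides$meanlog, config$triglycerides$sdlog),
    config$triglycerides$missing_prob)
  hdl <- .mask_na(
    pmax(stats::rnorm(N, ifelse(male, config$hdl$mean_male,
                                config$hdl$mean_female), config$hdl$sd), 0.3),
    config$hdl$missing_prob)
  bmi <- .mask_na(pmax(stats::rnorm(N, config$bmi$mean, config$bmi$sd), 14),
                  config$bmi$missing_prob)
  met_minutes <- .mask_na(stats::rlnorm(N, config$met$meanlog, config$met$sdlog),
                          config$met$missing_prob)
  pulse <- .mask_na(pmax(stats::rnorm(N, config$pulse$mean, config$pulse$sd), 40),
                    config$pulse$missing_prob)

  ht_latent <- sbp_lat >= 140 | dbp_lat >= 90
  on_ht_medication <- .rbern(N, ifelse(ht_latent,
                                       config$ht_med_prob[["hypertensive"]],
                                       config$ht_med_prob[["other"]]))

  records <- data.frame(
    participant_id = sprintf("P%06d", seq_len(N)),
    stratum_id = stratum_id, cluster_id = cluster_id, weight = weight,
    sex = sex, age = age,
    sbp1 = sbp_r[, 1], sbp2 = sbp_r[, 2], sbp3 = sbp_r[, 3],
    dbp1 = dbp_r[, 1], dbp2 = dbp_r[, 2], dbp3 = dbp_r[, 3],
    current_smoker = current_smoker, quit_lt_1yr = quit_lt_1yr,
    fasting_glucose = fasting_glucose, glucose_specimen = glucose_specimen,
    on_dm_medication = on_dm_medication,
    total_cholesterol = total_cholesterol,
    on_chol_medication = on_chol_medication,
    on_ht_medication = on_ht_medication,
    bmi = bmi, met_minutes = met_minutes, pulse = pulse,
    triglycerides = triglycerides, hdl = hdl,
    stringsAsFactors = FALSE
  )

  # Realized (finite-sample) truth, computed directly from generated values.
  sbp_d <- (records$sbp2 + records$sbp3) / 2
  dbp_d <- (records$dbp2 + records$dbp3) / 2
  smoker_t <- current_smoker | quit_lt_1yr
  thr <- ifelse(plasma, 7.0, 6.1)
  diabetic_t <- (records$fasting_glucose >= thr) | on_dm_medication
  diabetic_t[is.na(records$fasting_glucose) & !on_dm_medication] <- NA
  hchol_t <- (records$total_cholesterol >= 6.2) | on_chol_medication
  hchol_t[is.na(records$total_cholesterol) & !on_chol_medication] <- NA

  prev <- function(x) list(value = mean(x, na.rm = TRUE), n = sum(!is.na(x)))
  truth <- list(
    prevalence = list(
      smoking = prev(smoker_t),
      hypertension = prev(sbp_d >= 140 | dbp_d >= 90 | on_ht_medication),
      diabetes = prev(diabetic_t),
      hypercholesterolemia = prev(hchol_t),
      obesity = prev(bmi >= 30),
      low_physical_activity = prev(met_minutes < 600),
      high_pulse = prev(pulse > 90),
      on_ht_medication = prev(on_ht_medication),
      high_triglycerides = prev(triglycerides > 2.00),
      low_hdl = prev(hdl < ifelse(male, 1.0, 1.3))
    ),
    n_records = N
  )
  complete <- age >= 40 & !is.na(diabetic_t)
  bands <- .threshold_chart_band(age[complete], sbp_d[complete],
                                 smoker_t[complete], diabetic_t[complete])
  truth$chart_bands <- as.list(
    table(factor(bands, levels = .RISK_BANDS)) / length(bands))

  list(records = records, truth = truth, config = config)
}

#' Build a fixture chart
#'
#' Deterministic chart specifications used for testing and demonstration
#' (published chart values are shipped as user data, never hard-coded):
#' * `uniform` -- every cell `<10`;
#' * `threshold` -- the band index is `min(age band index + SBP band index
#'   + smoker + diabetic, 4)` counting from zero, so expected category
#'   distributions are computable by enumeration (cholesterol does not
#'   enter, making the two variants agree);
#' * `adversarial` -- uniform except exactly one deviant cell
#'   (male, 60--69, smoker, diabetic, SBP >=180, cholesterol column 8) set
#'   to `>=40`, for lookup sensitivity tests.
#'
#' @param style `"uniform"`, `"threshold"` or `"adversarial"`.
#' @param variant Chart variant to build.
#' @param region_id Region label for the resulting spec.
#' @return A validated `chart_spec`.
#' @export
make_fixture_chart <- function(style = c("uniform", "threshold", "adversarial"),
                               variant = c("without_cholesterol",
                                           "with_cholesterol"),
                               region_id = NULL) {
  style <- match.arg(style)
  variant <- match.arg(variant)
  cells <- .expected_cells(variant)
  cells$risk_band <- switch(style,
    uniform = "<10",
    threshold = {
      score <- (match(cells$age_band, .AGE_BANDS) - 1L) +
        (match(cells$sbp_band, .SBP_BANDS) - 1L) +
        cells$smoker + cells$diabetic
      .RISK_BANDS[pmin(score + 1L, 5L)]
    },
    adversarial = {
      rb <- rep("<10", nrow(cells))
      deviant <- cells$sex == "male" & cells$age_band == "60-69" &
        cells$smoker == 1L & cells$diabetic == 1L & cells$sbp_band == ">=180" &
        (is.na(cells$chol_band) | cells$chol_band == 8L)
      rb[deviant] <- ">=40"
      rb
    }
  )
  chart_spec(cells, variant = variant,
             region_id = region_id %||% paste0("FIXTURE-", toupper(style)))
}

#' Write the truth sidecar of a generated cohort
#'
#' @param truth The `truth` element of [generate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
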