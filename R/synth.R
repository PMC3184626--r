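# Synthetic cohorts with the statistical structure the analysis assumes:
# covariates drawn per sex, item-level inventory responses generated by
# thresholding a latent severity, employment status drawn from a logistic
# model on the (rescaled) true scores, and missingness applied afterwards
# (MCAR by default). A matching external duration-of-unemployment sample
# draws per-record fractions from a Beta law by sex.

CENTRE_LABELS <- c("bristol", "somerset", "leeds", "london", "surrey")
YEAR_LABELS <- 2006:2009

#' Simulation configuration for the synthetic cohort generator
#'
#' Defaults emulate the assessed referral cohort: n = 2,170 with 76.9%
#' women; mean ages 41.4 (men) and 38.6 (women); skewed (log-normal) illness
#' durations; about half of those with a recorded status having discontinued
#' employment under a logistic model whose covariate effects are of the
#' magnitudes seen in practice; status recorded for 91.8% of patients and
#' roughly three-quarters of each employment group having complete
#' questionnaire data.
#'
#' @param n_patients Cohort size.
#' @param prob_female Probability a patient is female.
#' @param age_mean Named vector `c(male=, female=)` of mean ages (years).
#' @param age_sd Common age standard deviation (years); ages are truncated to
#'   18-64 and rounded to whole years.
#' @param illness_meanlog,illness_sdlog Named vectors by sex: log-normal
#'   parameters of illness duration in months.
#' @param coefficients Named log-odds vector of the discontinuation model:
#'   `intercept`, `age_decade` (per 10 years of age), `sex_female`,
#'   `duration_years`, and the four rescaled (0-10) inventory scores
#'   `fatigue`, `phys_function`, `anxiety`, `depression`, plus `pain`
#'   (rescaled VAS).
#' @param centre_effects,year_effects Named log-odds offsets per centre and
#'   assessment year (first entry is the reference, 0).
#' @param status_recorded_prob Probability employment status is recorded.
#' @param prob_other Probability a recorded status is "other" (not entering
#'   the employed/discontinued outcome).
#' @param prob_temp_given_disc Probability a discontinuation is temporary
#'   rather than indefinite.
#' @param questionnaire_prob Probability the inventory booklet was returned at
#'   all; when it was, each instrument independently has exactly one item
#'   missing with `item_miss1_prob` (still scored, pro-rated) or two items
#'   missing with `item_miss2_prob` (total coded missing).
#' @param item_miss1_prob,item_miss2_prob See `questionnaire_prob`.
#' @param duration_missing_prob Probability illness duration is unrecorded.
#' @param status_missing_model `"mcar"` (default) or `"age_fatigue"`, under
#'   which the probability that status is missing increases with age and
#'   fatigue (missing-data patients slightly older and more fatigued).
#' @param score_p Named per-item endorsement targets (proportion of the item
#'   maximum) for the four inventories.
#' @param severity_loading Correlation of items with the latent severity.
#' @param unemployment_fraction_mean Named vector by sex: mean of the
#'   per-record (duration unemployed)/(duration ill) fraction.
#' @param unemployment_concentration Beta concentration of that fraction.
#' @param n_external External sample size.
#' @param prob_male_external Probability an external record is male.
#' @param external_meanlog,external_sdlog Log-normal parameters of external
#'   illness duration (months).
#' @return Object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(
    n_patients = 2170,
    prob_female = 0.769,
    age_mean = c(male = 41.4, female = 38.6),
    age_sd = 11.5,
    illness_meanlog = c(male = log(42), female = log(42)),
    illness_sdlog = c(male = 1.05, female = 1.05),
    coefficients = c(
      intercept = 0.60,
      age_decade = 0.16,
      sex_female = -0.45,
      duration_years = 0.07,
      fatigue = 0.03,
      phys_function = -0.35,
      anxiety = -0.02,
      depression = 0.05,
      pain = 0.01
    ),
    centre_effects = c(bristol = 0, somerset = 0.10, leeds = -0.10,
                       london = 0.05, surrey = -0.05),
    year_effects = c("2006" = 0, "2007" = 0.05, "2008" = -0.05, "2009" = 0),
    status_recorded_prob = 0.918,
    prob_other = 182 / 1991,
    prob_temp_given_disc = 322 / 998,
    questionnaire_prob = 0.93,
    item_miss1_prob = 0.02,
    item_miss2_prob = 0.015,
    duration_missing_prob = 0.09,
    status_missing_model = c("mcar", "age_fatigue"),
    score_p = c(chalder = 0.78, sf36pf = 0.40, hadsA = 0.50, hadsD = 0.45),
    severity_loading = 0.6,
    unemployment_fraction_mean = c(male = 0.52, female = 0.47),
    unemployment_concentration = 10,
    n_external = 60,
    prob_male_external = 22 / 60,
    external_meanlog = log(26),
    external_sdlog = 1.1) {
  status_missing_model <- match.arg(status_missing_model)
  cfg <- list(
    n_patients = n_patients, prob_female = prob_female,
    age_mean = age_mean, age_sd = age_sd,
    illness_meanlog = illness_meanlog, illness_sdlog = illness_sdlog,
    coefficients = coefficients,
    centre_effects = centre_effects, year_effects = year_effects,
    status_recorded_prob = status_recorded_prob, prob_other = prob_other,
    prob_temp_given_disc = prob_temp_given_disc,
    questionnaire_prob = questionnaire_prob,
    item_miss1_prob = item_miss1_prob, item_miss2_prob = item_miss2_prob,
    duration_missing_prob = duration_missing_prob,
    status_missing_model = status_missing_model,
    score_p = score_p, severity_loading = severity_loading,
    unemployment_fraction_mean = unemployment_fraction_mean,
    unemployment_concentration = unemployment_concentration,
    n_external = n_external, prob_male_external = prob_male_external,
    external_meanlog = external_meanlog, external_sdlog = external_sdlog
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$prob_female, cfg$status_recorded_prob, cfg$prob_other,
             cfg$prob_temp_given_disc, cfg$questionnaire_prob,
             cfg$item_miss1_prob, cfg$item_miss2_prob,
             cfg$duration_missing_prob, cfg$prob_male_external,
             cfg$unemployment_fraction_mean, cfg$score_p)
  if (any(probs < 0 | probs > 1)) stop("config probabilities must lie in [0, 1]")
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (cfg$unemployment_concentration <= 0) stop("concentration must be > 0")
  if (abs(cfg$severity_loading) >= 1) stop("severity_loading must lie in (-1, 1)")
  invisible(cfg)
}

#' True generative parameters of a simulation run
#'
#' Pure projection of the configuration: the logistic coefficients, centre
#' and year offsets, and the Beta-fraction parameters a run actually uses,
#' for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return Named list of the truth parameters.
#' @export
true_parameters <- function(config) {
  list(
    coefficients = config$coefficients,
    centre_effects = config$centre_effects,
    year_effects = config$year_effects,
    unemployment_fraction_mean = config$unemployment_fraction_mean,
    unemployment_concentration = config$unemployment_concentration
  )
}

# Correlated ordinal items: u_ij = Phi(lambda z_i + sqrt(1-lambda^2) e_ij),
# item = qbinom(u, levels - 1, p) * step. Latent z is shared across the four
# instruments so totals are positively correlated within patient.
draw_items <- function(z, n_items, n_levels, p, step, loading) {
  n <- length(z)
  e <- matrix(rnorm(n * n_items), n, n_items)
  u <- pnorm(loading * z + sqrt(1 - loading^2) * e)
  matrix(qbinom(u, n_levels - 1, p), n, n_items) * step
}

#' Simulate a synthetic assessment cohort
#'
#' Draws sex, age, centre, assessment year, illness duration and item-level
#' inventory responses, generates the 4-category employment status from the
#' configured logistic model on the true (pre-missingness) rescaled scores,
#' then applies status, duration and inventory missingness. Reproducible for
#' a fixed `(config, seed)` pair.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the single pseudo-random stream.
#' @return Patient-record tibble (schema of [load_patient_table()]) with the
#'   latent discontinuation indicator retained as attribute `"truth"`.
#' @export
simulate_cohort <- function(config, seed) {
  validate_sim_config(config)
  set.seed(seed)
  n <- config$n_patients

  sex <- ifelse(runif(n) < config$prob_female, "female", "male")
  age <- round(rnorm(n, config$age_mean[sex], config$age_sd))
  age <- pmin(pmax(age, 18L), 64L)
  centre <- sample(names(config$centre_effects), n, replace = TRUE)
  year <- sample(names(config$year_effects), n, replace = TRUE)
  duration <- rlnorm(n, config$illness_meanlog[sex], config$illness_sdlog[sex])
  duration <- round(duration, 1)

  z <- rnorm(n)
  lam <- config$severity_loading
  p <- config$score_p
  chalder <- draw_items(z, 11L, 4L, p[["chalder"]], 1, lam)
  sf36 <- draw_items(-z, 10L, 3L, p[["sf36pf"]], 5, lam)  # disability mirrors severity
  hadsA <- draw_items(z, 7L, 4L, p[["hadsA"]], 1, lam)
  hadsD <- draw_items(z, 7L, 4L, p[["hadsD"]], 1, lam)
  vas <- pmin(pmax(round(50 + 18 * (lam * z + sqrt(1 - lam^2) * rnorm(n))), 0), 100)

  # True totals before any missingness, rescaled 0-10 as in the analysis
  # Age enters as the banded per-decade term, the same covariate the
  # regression models use
  b <- config$coefficients
  lp <- b[["intercept"]] +
    b[["age_decade"]] * age_band_midpoint(assign_age_band(age)) / 10 +
    b[["sex_female"]] * (sex == "female") +
    b[["duration_years"]] * duration / 12 +
    b[["fatigue"]] * rescale_for_regression(rowSums(chalder), 33) +
    b[["phys_function"]] * rescale_for_regression(rowSums(sf36), 100) +
    b[["anxiety"]] * rescale_for_regression(rowSums(hadsA), 21) +
    b[["depression"]] * rescale_for_regression(rowSums(hadsD), 21) +
    b[["pain"]] * rescale_for_regression(vas, 100) +
    config$centre_effects[centre] + config$year_effects[year]
  discontinued <- runif(n) < plogis(lp)

  status <- ifelse(
    runif(n) < config$prob_other, "other",
    ifelse(discontinued,
           ifelse(runif(n) < config$prob_temp_given_disc,
                  "temporarily_discontinued", "indefinitely_discontinued"),
           "currently_employed"))

  # Status missingness: MCAR, or increasing with age and fatigue
  if (config$status_missing_model == "age_fatigue") {
    base <- qlogis(1 - config$status_recorded_prob)
    p_miss <- plogis(base + 0.04 * (age - mean(age)) +
                       0.08 * (rowSums(chalder) - mean(rowSums(chalder))) / 3.3)
  } else {
    p_miss <- 1 - config$status_recorded_prob
  }
  status[runif(n) < p_miss] <- NA_character_
  duration[runif(n) < config$duration_missing_prob] <- NA_real_

  # Inventory missingness: whole booklet (one draw per patient, shared by all
  # instruments), or 1-2 items per instrument
  booklet_missing <- runif(n) >= config$questionnaire_prob
  knock_out <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    m[booklet_missing, ] <- NA_real_
    u <- runif(nr)
    one <- !booklet_missing & u < config$item_miss1_prob
    two <- !booklet_missing & !one &
      u < config$item_miss1_prob + config$item_miss2_prob
    for (i in which(one)) m[i, sample.int(nc, 1)] <- NA_real_
    for (i in which(two)) m[i, sample.int(nc, 2)] <- NA_real_
    m
  }
  chalder <- knock_out(chalder)
  sf36 <- knock_out(sf36)
  hadsA <- knock_out(hadsA)
  hadsD <- knock_out(hadsD)
  vas[booklet_missing] <- NA_real_

  out <- tibble::tibble(
    patient_id = sprintf("S%05d", seq_len(n)),
    centre = centre,
    assessment_year = as.integer(year),
    age = as.integer(age),
    sex = factor(sex, levels = SEX_LEVELS),
    duration_illness = duration,
    employment_status = factor(status, levels = EMPLOYMENT_LEVELS)
  )
  cols <- item_columns()
  out[cols$chalder] <- as.data.frame(chalder)
  out[cols$sf36pf] <- as.data.frame(sf36)
  out[cols$hadsA] <- as.data.frame(hadsA)
  out[cols$hadsD] <- as.data.frame(hadsD)
  out$vas <- vas
  attr(out, "truth") <- list(discontinued = discontinued,
                             parameters = true_parameters(config))
  out
}

#' Simulate an external duration-of-unemployment sample
#'
#' Per-record fractions (duration unemployed)/(duration ill) are drawn from a
#' Beta law with the configured mean and concentration by sex; unemployment
#' duration is the fraction times a log-normal illness duration.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Tibble with `sex`, `duration_illness_months`,
#'   `duration_unemployment_months`.
#' @export
simulate_external_sample <- function(config, seed) {
  validate_sim_config(config)
  set.seed(seed)
  n <- config$n_external
  sex <- ifelse(runif(n) < config$prob_male_external, "male", "female")
  illness <- rlnorm(n, config$external_meanlog, config$external_sdlog)
  mu <- config$unemployment_fraction_mean[sex]
  k <- config$unemployment_concentration
  frac <- rbeta(n, mu * k, (1 - mu) * k)
  tibble::tibble(
    sex = factor(sex, levels = SEX_LEVELS),
    duration_illness_months = round(illness, 1),
    duration_unemployment_months = round(frac * illness, 1)
  )
}
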