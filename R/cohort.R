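#' Simulation configuration for the virtual cohort
#'
#' Generator moments mirror the enrolled cohort's baseline characteristics:
#' HbA1c 8.6 (SD 0.7) %, total daily insulin dose 0.73 (SD 0.31) units/kg/day,
#' BMI 29.0 (SD 3.6) kg/m^2, and a body weight distribution centred on the
#' 78.5 kg implied by 57.3 units/day at 0.73 units/kg/day. Eligibility (HbA1c
#' 7.5-9.9%, TDD < 1 unit/kg, BMI <= 40) is enforced by rejection sampling.
#'
#' Each patient carries a latent linear dose-response: the expected reading in
#' a slot is the slot setpoint minus `sensitivity` times the governing dose in
#' units/kg, plus Gaussian within-day noise. Slot setpoints sit at the
#' ADAG-estimated average glucose of the baseline HbA1c, offset by
#' `-slot_offset` (prebreakfast, fasting runs lower) and `+slot_offset`
#' (predinner); the offset default 2.4 mmol/L reproduces the gap between the
#' cohort's baseline fasting plasma glucose (8.7 mmol/L) and the eAG of
#' HbA1c 8.6% (11.1 mmol/L). HbA1c kinetics are an exponentially weighted
#' moving average of daily mean latent glucose with time constant `tau_days`.
#'
#' @param n_patients Cohort size (default 25).
#' @param weeks Trial length in weeks (default 24).
#' @param seed Integer seed; every stochastic path derives from it.
#' @param hba1c_mean,hba1c_sd Baseline HbA1c moments, NGSP %.
#' @param tdd_per_kg_mean,tdd_per_kg_sd Baseline total-daily-dose moments,
#'   units/kg/day.
#' @param bmi_mean,bmi_sd BMI moments, kg/m^2.
#' @param weight_mean,weight_sd Body-weight moments, kg.
#' @param morning_fraction Fraction of the total daily dose given as the
#'   morning premix (default 0.6).
#' @param sensitivity_mean,sensitivity_sd Insulin-sensitivity moments, mmol/L
#'   glucose reduction per (unit/kg) of governing dose (truncated > 0.5).
#' @param within_day_sd Within-day Gaussian reading noise, mmol/L.
#' @param adherence_min,adherence_max Uniform range of the per-patient
#'   probability that a prescribed reading is performed.
#' @param slot_offset Half-separation of the two slot setpoints, mmol/L.
#' @param tau_days Time constant of the HbA1c EWMA state, days (default 35).
#' @param lab_sd_hba1c,lab_sd_fpg Laboratory measurement noise SDs (% HbA1c
#'   and mmol/L).
#' @param setpoint_drift Optional linear drift of both slot setpoints,
#'   mmol/L per day (negative = behavioural improvement); default 0.
#' @param titration Logical: run the weekly titration loop (default `TRUE`).
#' @param rules A [titrationConfig()].
#' @return An object of class `sim_config`.
#' @examples
#' simConfig(n_patients = 5, weeks = 4, seed = 42)
#' @export
simConfig <- function(n_patients = 25,
                      weeks = 24,
                      seed = 1L,
                      hba1c_mean = 8.6, hba1c_sd = 0.7,
                      tdd_per_kg_mean = 0.73, tdd_per_kg_sd = 0.31,
                      bmi_mean = 29.0, bmi_sd = 3.6,
                      weight_mean = 78.5, weight_sd = 12,
                      morning_fraction = 0.6,
                      sensitivity_mean = 5, sensitivity_sd = 1.5,
                      within_day_sd = 1.0,
                      adherence_min = 0.94, adherence_max = 1.0,
                      slot_offset = 2.4,
                      tau_days = 35,
                      lab_sd_hba1c = 0.1, lab_sd_fpg = 0.3,
                      setpoint_drift = 0,
                      titration = TRUE,
                      rules = titrationConfig()) {
  stopifnot(
    n_patients >= 1, weeks >= 1,
    hba1c_sd >= 0, tdd_per_kg_sd >= 0, bmi_sd >= 0, weight_sd >= 0,
    sensitivity_sd >= 0, within_day_sd >= 0,
    lab_sd_hba1c >= 0, lab_sd_fpg >= 0,
    morning_fraction > 0, morning_fraction < 1,
    adherence_min > 0.0, adherence_min <= adherence_max, adherence_max <= 1,
    slot_offset >= 0, tau_days > 0,
    is.logical(titration), inherits(rules, "titration_config")
  )
  structure(
    list(n_patients = as.integer(n_patients), weeks = as.integer(weeks),
         seed = as.integer(seed),
         hba1c_mean = hba1c_mean, hba1c_sd = hba1c_sd,
         tdd_per_kg_mean = tdd_per_kg_mean, tdd_per_kg_sd = tdd_per_kg_sd,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         weight_mean = weight_mean, weight_sd = weight_sd,
         morning_fraction = morning_fraction,
         sensitivity_mean = sensitivity_mean, sensitivity_sd = sensitivity_sd,
         within_day_sd = within_day_sd,
         adherence_min = adherence_min, adherence_max = adherence_max,
         slot_offset = slot_offset, tau_days = tau_days,
         lab_sd_hba1c = lab_sd_hba1c, lab_sd_fpg = lab_sd_fpg,
         setpoint_drift = setpoint_drift,
         titration = titration, rules = rules),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Virtual-cohort simulation: %d patients, %d weeks, seed %d, titration %s\n",
              x$n_patients, x$weeks, x$seed, if (x$titration) "on" else "off"))
  cat(sprintf("  HbA1c %.1f (%.1f) %% | TDD %.2f (%.2f) U/kg | BMI %.1f (%.1f) | weight %.1f (%.1f) kg\n",
              x$hba1c_mean, x$hba1c_sd, x$tdd_per_kg_mean, x$tdd_per_kg_sd,
              x$bmi_mean, x$bmi_sd, x$weight_mean, x$weight_sd))
  cat(sprintf("  sensitivity %.1f (%.1f) mmol/L per U/kg | noise SD %.1f | adherence U(%.2f, %.2f)\n",
              x$sensitivity_mean, x$sensitivity_sd, x$within_day_sd,
              x$adherence_min, x$adherence_max))
  invisible(x)
}

# eligibility bounds (enrollment criteria)
ELIG_HBA1C <- c(7.5, 9.9)
ELIG_TDD_PER_KG <- 1.0
ELIG_BMI <- 40

# deterministic per-patient seed derived from the trial seed (kept < 2^31)
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483629) + 1L
}

#' Sample an eligible virtual cohort
#'
#' Draws patients from the configured generator moments and rejection-samples
#' the enrollment criteria (HbA1c 7.5-9.9%, TDD < 1 unit/kg after rounding to
#' whole-unit doses, BMI <= 40). Errors if fewer than 1% of candidate draws
#' are eligible (infeasible moment configuration).
#'
#' @param config A [simConfig()].
#' @param seed Seed (defaults to `config$seed`).
#' @return A tibble, one row per patient: `id`, `weight_kg`, `bmi`,
#'   `baseline_hba1c_pct`, `sensitivity`, `adherence_prob`,
#'   `setpoint_prebreakfast`, `setpoint_predinner`, `morning_dose`,
#'   `evening_dose`.
#' @examples
#' sampleCohort(simConfig(n_patients = 5, seed = 7))
#' @export
sampleCohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_patients
  acc <- list()
  tried <- 0L
  accepted <- 0L
  while (accepted < n) {
    m <- max(2L * n, 50L)
    cand <- tibble::tibble(
      weight_kg = rnorm(m, config$weight_mean, config$weight_sd),
      bmi = rnorm(m, config$bmi_mean, config$bmi_sd),
      baseline_hba1c_pct = rnorm(m, config$hba1c_mean, config$hba1c_sd),
      tdd_per_kg = rnorm(m, config$tdd_per_kg_mean, config$tdd_per_kg_sd),
      sensitivity = rnorm(m, config$sensitivity_mean, config$sensitivity_sd),
      adherence_prob = runif(m, config$adherence_min, config$adherence_max)
    )
    tdd_units <- round_units(cand$tdd_per_kg * cand$weight_kg)
    cand$morning_dose <- round_units(config$morning_fraction * cand$tdd_per_kg * cand$weight_kg)
    cand$evening_dose <- pmax(0, tdd_units - cand$morning_dose)
    ok <- cand$weight_kg >= 40 & cand$weight_kg <= 150 &
      cand$bmi > 15 & cand$bmi <= ELIG_BMI &
      cand$baseline_hba1c_pct >= ELIG_HBA1C[1] & cand$baseline_hba1c_pct <= ELIG_HBA1C[2] &
      cand$tdd_per_kg > 0 &
      (cand$morning_dose + cand$evening_dose) / cand$weight_kg < ELIG_TDD_PER_KG &
      cand$morning_dose >= 1 & cand$evening_dose >= 1 &
      cand$sensitivity > 0.5
    tried <- tried + m
    accepted <- accepted + sum(ok)
    acc[[length(acc) + 1]] <- cand[ok, , drop = FALSE]
    if (tried >= 100L * n && accepted / tried < 0.01) {
      stop("infeasible generator configuration: rejection rate exceeds 99%")
    }
  }
  cohort <- utils::head(dplyr::bind_rows(acc), n)
  eag <- eagFromHba1c(cohort$baseline_hba1c_pct)
  # setpoints chosen so the baseline mean latent glucose equals the eAG of
  # the baseline HbA1c (cross-over: prebreakfast <- evening dose)
  cohort$setpoint_prebreakfast <- eag - config$slot_offset +
    cohort$sensitivity * cohort$evening_dose / cohort$weight_kg
  cohort$setpoint_predinner <- eag + config$slot_offset +
    cohort$sensitivity * cohort$morning_dose / cohort$weight_kg
  tibble::tibble(
    id = sprintf("P%02d", seq_len(n)),
    cohort[, c("weight_kg", "bmi", "baseline_hba1c_pct", "sensitivity",
               "adherence_prob", "setpoint_prebreakfast", "setpoint_predinner",
               "morning_dose", "evening_dose")]
  )
}

# latent (noise-free) slot means for a patient on a regimen, with optional
# setpoint drift offset
latent_means <- function(patient, reg, drift_offset = 0) {
  c(
    prebreakfast = patient$setpoint_prebreakfast + drift_offset -
      patient$sensitivity * reg$evening_dose / reg$weight_kg,
    predinner = patient$setpoint_predinner + drift_offset -
      patient$sensitivity * reg$morning_dose / reg$weight_kg
  )
}

#' Simulate one day of SMBG for one patient
#'
#' Each prescribed slot is measured with probability `adherence_prob`; the
#' observed value is the latent slot mean plus Gaussian within-day noise,
#' floored at 0.5 mmol/L and rounded to the glucometer's 0.1 mmol/L display.
#' Consumes the current RNG stream.
#'
#' @param patient One row of [sampleCohort()] (as list or single-row data
#'   frame).
#' @param reg The day's active [regimen()].
#' @param config A [simConfig()].
#' @param day Study day (0-based), used only for setpoint drift.
#' @return List with `readings` (tibble `slot`, `glucose`; skipped slots
#'   absent) and `latent` (named noise-free slot means, whose average drives
#'   the HbA1c state).
#' @export
stepDay <- function(patient, reg, config, day = 0) {
  lat <- latent_means(patient, reg, config$setpoint_drift * day)
  done <- runif(2) <= patient$adherence_prob
  noise <- rnorm(2, 0, config$within_day_sd)
  g <- round(pmax(0.5, lat + noise), 1)
  list(
    readings = tibble::tibble(slot = SMBG_SLOTS[done], glucose = unname(g[done])),
    latent = lat
  )
}
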