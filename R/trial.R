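#' Run a full closed-loop in-silico titration trial
#'
#' Simulates the complete intervention: a rejection-sampled eligible cohort,
#' twice-daily SMBG with imperfect adherence, urgent out-of-cycle decrements
#' on level-2 readings, weekly algorithm-guided recommendations through the
#' physician approval gate (auto-accepted with the configured probability),
#' HbA1c kinetics as an EWMA of daily mean latent glucose, laboratory draws
#' of HbA1c and fasting plasma glucose at weeks 0, 12 and 24, hypoglycemia
#' episode extraction, adherence accounting, and the trial outcome summary.
#' Fully reproducible: identical `config` (including seed) gives identical
#' output.
#'
#' @param config A [simConfig()].
#' @param study_start Date of study day 1 (default `"2020-09-07"`; prebreakfast
#'   readings are stamped 07:30, predinner 18:30 UTC).
#' @return An object of class `insilico_trial`: list with `smbg` (reading
#'   log), `episodes` ([extractEpisodes()] output), `regimen_history`
#'   (`participant_id`, `day`, `morning_dose`, `evening_dose`, `weight_kg`,
#'   `urgent`), `labs` (`participant_id`, `week`, `hba1c_pct`, `fpg_mmol_l`,
#'   `bmi`), `recommendations` (per participant-week decision rows),
#'   `summary` (a [summarizeTrial()] result), `cohort`, `config`,
#'   `study_start`.
#' @examples
#' tr <- runTrial(simConfig(n_patients = 3, weeks = 2, seed = 11))
#' tr$summary
#' @export
runTrial <- function(config, study_start = as.Date("2020-09-07")) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- sampleCohort(config)
  rules <- config$rules
  n_days <- config$weeks * 7L
  alpha <- 1 - exp(-1 / config$tau_days)
  lab_weeks <- unique(c(0L, if (config$weeks >= 12) 12L, config$weeks))
  start_ct <- as.POSIXct(paste(study_start, "00:00:00"), tz = "UTC")
  slot_sec <- c(prebreakfast = 7.5 * 3600, predinner = 18.5 * 3600)

  smbg <- list(); labs <- list(); hist <- list(); recs <- list()
  for (i in seq_len(nrow(cohort))) {
    p <- as.list(cohort[i, ])
    set.seed(patient_seed(config$seed, i))
    reg <- regimen(p$morning_dose, p$evening_dose, p$weight_kg)
    state <- eagFromHba1c(p$baseline_hba1c_pct)
    hist[[length(hist) + 1]] <- tibble::tibble(
      participant_id = p$id, day = 0L, morning_dose = reg$morning_dose,
      evening_dose = reg$evening_dose, weight_kg = reg$weight_kg, urgent = FALSE
    )
    # baseline labs before any intervention day
    labs[[length(labs) + 1]] <- tibble::tibble(
      participant_id = p$id, week = 0L,
      hba1c_pct = p$baseline_hba1c_pct + rnorm(1, 0, config$lab_sd_hba1c),
      fpg_mmol_l = latent_means(p, reg)[["prebreakfast"]] + rnorm(1, 0, config$lab_sd_fpg),
      bmi = p$bmi
    )

    day_v <- integer(0); slot_v <- character(0); gluc_v <- numeric(0)
    urgent_slots <- character(0)
    for (day in 0:(n_days - 1L)) {
      sd_out <- stepDay(p, reg, config, day)
      rd <- sd_out$readings
      if (nrow(rd) > 0) {
        day_v <- c(day_v, rep(day, nrow(rd)))
        slot_v <- c(slot_v, rd$slot)
        gluc_v <- c(gluc_v, rd$glucose)
      }
      state <- state + alpha * (mean(sd_out$latent) - state)

      if (config$titration && nrow(rd) > 0 &&
          any(rd$glucose < rules$urgent_threshold & !(rd$slot %in% urgent_slots))) {
        rec <- hypoglycemiaTrigger(rd, reg, rules, urgent_slots)
        if (!is.null(rec)) {
          urgent_slots <- union(urgent_slots, rd$slot[rd$glucose < rules$urgent_threshold])
          accept <- runif(1) <= rules$accept_probability
          rec <- applyApproval(rec, if (accept) "accept" else "decline", auto = TRUE)
          recs[[length(recs) + 1]] <- recommendation_row(p$id, day, rec)
          if (accept && any(rec$slot_changes != 0)) {
            reg <- activeRegimen(rec)
            hist[[length(hist) + 1]] <- tibble::tibble(
              participant_id = p$id, day = day + 1L, morning_dose = reg$morning_dose,
              evening_dose = reg$evening_dose, weight_kg = reg$weight_kg, urgent = TRUE
            )
          }
        }
      }

      if (config$titration && (day %% 7L) == 6L) {
        in_week <- day_v > day - 7L
        window <- data.frame(slot = slot_v[in_week], glucose = gluc_v[in_week])
        rec <- recommendDoses(window, reg, rules)
        accept <- runif(1) <= rules$accept_probability
        rec <- applyApproval(rec, if (accept) "accept" else "decline", auto = TRUE)
        recs[[length(recs) + 1]] <- recommendation_row(p$id, day, rec)
        if (accept && any(rec$slot_changes != 0)) {
          reg <- activeRegimen(rec)
          hist[[length(hist) + 1]] <- tibble::tibble(
            participant_id = p$id, day = day + 1L, morning_dose = reg$morning_dose,
            evening_dose = reg$evening_dose, weight_kg = reg$weight_kg, urgent = FALSE
          )
        }
        urgent_slots <- character(0)
      }

      wk <- (day + 1L) / 7L
      if ((day + 1L) %% 7L == 0L && wk %in% lab_weeks) {
        labs[[length(labs) + 1]] <- tibble::tibble(
          participant_id = p$id, week = as.integer(wk),
          hba1c_pct = hba1cFromEag(state) + rnorm(1, 0, config$lab_sd_hba1c),
          fpg_mmol_l = latent_means(p, reg, config$setpoint_drift * day)[["prebreakfast"]] +
            rnorm(1, 0, config$lab_sd_fpg),
          bmi = p$bmi
        )
      }
    }
    if (length(day_v)) {
      smbg[[length(smbg) + 1]] <- tibble::tibble(
        participant_id = p$id,
        time = start_ct + day_v * 86400 + unname(slot_sec[slot_v]),
        slot = slot_v, glucose = gluc_v, assisted = FALSE
      )
    }
  }

  smbg <- dplyr::bind_rows(smbg)
  smbg <- smbg[order(smbg$participant_id, smbg$time), ]
  labs <- dplyr::bind_rows(labs)
  hist <- dplyr::bind_rows(hist)
  recs <- dplyr::bind_rows(recs)
  episodes <- extractEpisodes(smbg, study_start, rules, config$weeks)
  summary <- summarizeTrial(labs, hist, smbg, episodes, study_start, config$weeks)

  structure(
    list(smbg = smbg, episodes = episodes, regimen_history = hist, labs = labs,
         recommendations = recs, summary = summary, cohort = cohort,
         config = config, study_start = study_start),
    class = "insilico_trial"
  )
}

# one audit row per decided recommendation
recommendation_row <- function(id, day, rec) {
  tibble::tibble(
    participant_id = id, day = as.integer(day), urgent = rec$urgent,
    delta_morning = rec$slot_changes[["morning"]],
    delta_evening = rec$slot_changes[["evening"]],
    rationale_morning = rec$rationale[["morning"]],
    rationale_evening = rec$rationale[["evening"]],
    step_morning = rec$step_fraction[["morning"]],
    step_evening = rec$step_fraction[["evening"]],
    approval = rec$approval
  )
}

#' @export
print.insilico_trial <- function(x, ...) {
  cat(sprintf("In-silico titration trial: %d participants, %d weeks, seed %d\n",
              x$config$n_patients, x$config$weeks, x$config$seed))
  cat(sprintf("  %d SMBG readings, %d hypoglycemia episodes, %d dose changes\n\n",
              nrow(x$smbg), nrow(x$episodes),
              sum(x$recommendations$delta_morning != 0 | x$recommendations$delta_evening != 0)))
  print(x$summary)
  invisible(x)
}
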