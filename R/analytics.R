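#' SMBG adherence percentage
#'
#' Proportion of the prescribed twice-daily SMBG measurements that the
#' participant completed, as a percentage.
#'
#' @param completed,prescribed Non-negative counts, `completed <= prescribed`,
#'   `prescribed > 0`. Vectorised.
#' @param digits Decimal places for display precision (default 1).
#' @return Percentage in \[0, 100\].
#' @examples
#' adherencePct(165, 168)
#' adherencePct(327, 336)
#' @export
adherencePct <- function(completed, prescribed, digits = 1) {
  if (any(prescribed <= 0)) stop("prescribed count must be positive")
  if (any(completed < 0 | completed > prescribed)) {
    stop("completed must lie in [0, prescribed]")
  }
  round(100 * completed / prescribed, digits)
}

#' Prescribed SMBG count over a span of days
#'
#' @param days Number of days (>= 0).
#' @param slots_per_day Prescribed readings per day (default 2: prebreakfast
#'   and predinner).
#' @return Prescribed reading count (84 days x 2 = 168 per 12-week period).
#' @examples
#' prescribedCount(84)
#' @export
prescribedCount <- function(days, slots_per_day = 2L) {
  stopifnot(all(days >= 0), all(slots_per_day >= 0))
  as.integer(days) * as.integer(slots_per_day)
}

#' Hypoglycemia incidence per participant
#'
#' @param episodes Episode count (>= 0). Vectorised.
#' @param n Number of participants (> 0).
#' @param digits Decimal places for display precision (default 2).
#' @return Episodes per participant.
#' @examples
#' incidencePerParticipant(22, 25)
#' @export
incidencePerParticipant <- function(episodes, n, digits = 2) {
  if (any(n <= 0)) stop("participant count must be positive")
  stopifnot(all(episodes >= 0))
  round(episodes / n, digits)
}

#' NGSP to IFCC HbA1c conversion (master equation)
#'
#' IFCC (mmol/mol) = (NGSP% - 2.15) x 10.929.
#'
#' @param hba1c_pct HbA1c in NGSP %, > 2.15. Vectorised.
#' @param digits Decimal places (default 1; use `NA` for unrounded).
#' @return HbA1c in IFCC mmol/mol.
#' @examples
#' ngspToIfcc(8.6)
#' ngspToIfcc(7.0)
#' @export
ngspToIfcc <- function(hba1c_pct, digits = 1) {
  if (any(hba1c_pct <= 2.15)) stop("HbA1c must exceed 2.15% (the master-equation intercept)")
  x <- (hba1c_pct - 2.15) * 10.929
  if (is.na(digits)) x else round(x, digits)
}

#' Estimated average glucose (mmol/L) from HbA1c
#'
#' ADAG linear relation: eAG (mmol/L) = 1.59 x HbA1c% - 2.59. The inverse is
#' [hba1cFromEag()]; the two compose to identity.
#'
#' @param hba1c_pct HbA1c in NGSP %, in (3, 20). Vectorised.
#' @return Estimated average glucose, mmol/L.
#' @examples
#' eagFromHba1c(7.0)
#' hba1cFromEag(eagFromHba1c(8.6))
#' @export
eagFromHba1c <- function(hba1c_pct) {
  if (any(hba1c_pct <= 3 | hba1c_pct >= 20)) stop("HbA1c out of supported range (3, 20)%")
  1.59 * hba1c_pct - 2.59
}

#' @rdname eagFromHba1c
#' @param eag_mmol_l Estimated average glucose, mmol/L.
#' @export
hba1cFromEag <- function(eag_mmol_l) {
  x <- (eag_mmol_l + 2.59) / 1.59
  if (any(x <= 3 | x >= 20)) stop("implied HbA1c out of supported range (3, 20)%")
  x
}

# active regimen rows at a given study day, one per participant
regimen_at_day <- function(regimens, day) {
  regimens <- regimens[order(regimens$participant_id, regimens$day), ]
  regimens <- regimens[regimens$day <= day, , drop = FALSE]
  regimens[!duplicated(regimens$participant_id, fromLast = TRUE), , drop = FALSE]
}

#' Trial-level outcome summary
#'
#' Aggregates labs, dose history, readings and hypoglycemia episodes into the
#' study's outcome tables: per-timepoint means and SDs of HbA1c (both units),
#' fasting plasma glucose, total daily insulin dose (units and units/kg) and
#' BMI; change scores between consecutive timepoints and overall; per-period
#' SMBG adherence; and per-period hypoglycemia incidence by level.
#'
#' Cells are complete-case: a participant missing a lab timepoint is excluded
#' from that cell (and flagged), with the cell's `n` reported. SDs are `NA`
#' (flagged) when a cell holds a single participant.
#'
#' @param labs Data frame: `participant_id`, `week` (0/12/24), `hba1c_pct`,
#'   `fpg_mmol_l`, `bmi`.
#' @param regimens Optional dose history: `participant_id`, `day` (study day
#'   the regimen became effective, 0-based), `morning_dose`, `evening_dose`,
#'   `weight_kg`.
#' @param readings Optional SMBG log (`participant_id`, `time`) for adherence.
#' @param episodes Optional output of [extractEpisodes()].
#' @param study_start Date of study day 1 (required with `readings`).
#' @param weeks Study length in weeks (default 24).
#' @return An object of class `trial_summary`: list with tibbles `timepoints`
#'   (week x variable -> mean, sd, n), `changes` (variable, from, to, delta of
#'   means), `adherence`, `incidence`, plus `n_participants` and `flagged`.
#' @export
summarizeTrial <- function(labs, regimens = NULL, readings = NULL,
                           episodes = NULL, study_start = NULL, weeks = 24) {
  labs <- as.data.frame(labs)
  stopifnot(all(c("participant_id", "week", "hba1c_pct", "fpg_mmol_l", "bmi") %in% names(labs)))
  labs$participant_id <- as.character(labs$participant_id)

  ids <- sort(unique(c(
    labs$participant_id,
    if (!is.null(regimens)) as.character(regimens$participant_id),
    if (!is.null(readings)) as.character(readings$participant_id)
  )))
  n_participants <- length(ids)
  wks <- sort(unique(labs$week))

  # long table of participant x week x variable values
  long <- list()
  for (v in c("hba1c_pct", "fpg_mmol_l", "bmi")) {
    long[[v]] <- data.frame(participant_id = labs$participant_id, week = labs$week,
                            variable = v, value = labs[[v]])
  }
  long$hba1c_mmol_mol <- data.frame(participant_id = labs$participant_id, week = labs$week,
                                    variable = "hba1c_mmol_mol",
                                    value = ngspToIfcc(labs$hba1c_pct, digits = NA))
  if (!is.null(regimens)) {
    regimens <- as.data.frame(regimens)
    regimens$participant_id <- as.character(regimens$participant_id)
    for (w in wks) {
      act <- regimen_at_day(regimens, w * 7)
      tdd_units <- act$morning_dose + act$evening_dose
      long[[paste0("tdd_", w)]] <- data.frame(
        participant_id = rep(act$participant_id, 2), week = w,
        variable = rep(c("tdd_units", "tdd_units_per_kg"), each = nrow(act)),
        value = c(tdd_units, tdd_units / act$weight_kg)
      )
    }
  }
  long <- do.call(rbind, long)
  var_order <- c("hba1c_pct", "hba1c_mmol_mol", "fpg_mmol_l", "tdd_units",
                 "tdd_units_per_kg", "bmi")
  long$variable <- factor(long$variable, levels = var_order)
  long <- long[!is.na(long$value), ]

  key <- interaction(long$variable, long$week, drop = TRUE)
  timepoints <- dplyr::bind_rows(lapply(split(long, key), function(d) tibble::tibble(
    variable = as.character(d$variable[1]), week = d$week[1],
    mean = mean(d$value),
    sd = if (nrow(d) > 1) stats::sd(d$value) else NA_real_,
    n = nrow(d)
  )))
  timepoints$variable <- factor(timepoints$variable, levels = var_order)
  timepoints <- timepoints[order(timepoints$variable, timepoints$week), ]

  # flag participants missing any lab timepoint
  lab_wks <- sort(unique(labs$week))
  have <- table(factor(labs$participant_id, levels = ids), factor(labs$week, levels = lab_wks))
  flagged <- ids[rowSums(have > 0) < length(lab_wks)]
  if (any(timepoints$n == 1)) {
    flagged <- union(flagged, "single_participant_cell:sd_undefined")
  }

  # change scores: consecutive timepoints plus overall first -> last
  pairs <- cbind(wks[-length(wks)], wks[-1])
  if (length(wks) > 2) pairs <- rbind(pairs, c(wks[1], wks[length(wks)]))
  changes <- list()
  for (v in intersect(var_order, as.character(unique(timepoints$variable)))) {
    tv <- timepoints[timepoints$variable == v, ]
    for (r in seq_len(nrow(pairs))) {
      m_from <- tv$mean[tv$week == pairs[r, 1]]
      m_to <- tv$mean[tv$week == pairs[r, 2]]
      if (length(m_from) == 1 && length(m_to) == 1) {
        changes[[length(changes) + 1]] <- tibble::tibble(
          variable = v, from_week = pairs[r, 1], to_week = pairs[r, 2],
          delta = m_to - m_from
        )
      }
    }
  }
  changes <- dplyr::bind_rows(changes)

  # adherence per 12-week period
  adherence <- NULL
  if (!is.null(readings)) {
    stopifnot(!is.null(study_start))
    readings <- as.data.frame(readings)
    start <- as.POSIXct(paste(as.Date(study_start), "00:00:00"), tz = "UTC")
    day <- floor(as.numeric(difftime(as.POSIXct(readings$time, tz = "UTC"),
                                     start, units = "days")))
    period_days <- c(min(84, weeks * 7), max(0, weeks * 7 - 84))
    rows <- list()
    for (p in 1:2) {
      if (period_days[p] == 0) next
      in_p <- if (p == 1) day >= 0 & day < 84 else day >= 84 & day < weeks * 7
      completed <- sum(in_p)
      prescribed <- prescribedCount(period_days[p]) * n_participants
      rows[[p]] <- tibble::tibble(
        period = c("weeks_1_12", "weeks_13_24")[p],
        completed = completed, prescribed = prescribed,
        completed_per_participant = completed / n_participants,
        adherence_pct = adherencePct(completed, prescribed)
      )
    }
    adherence <- dplyr::bind_rows(rows)
    adherence <- rbind(adherence, tibble::tibble(
      period = "overall", completed = sum(adherence$completed),
      prescribed = sum(adherence$prescribed),
      completed_per_participant = sum(adherence$completed) / n_participants,
      adherence_pct = adherencePct(sum(adherence$completed), sum(adherence$prescribed))
    ))
  }

  # incidence per period by level
  incidence <- NULL
  if (!is.null(episodes)) {
    episodes <- as.data.frame(episodes)
    grid <- expand.grid(period = c("weeks_1_12", "weeks_13_24"), level = 1:3,
                        stringsAsFactors = FALSE)
    cnt <- unname(mapply(function(p, l) sum(episodes$period == p & episodes$level == l),
                         grid$period, grid$level))
    incidence <- tibble::tibble(
      period = grid$period, level = grid$level, episodes = as.integer(cnt),
      incidence = incidencePerParticipant(cnt, n_participants)
    )
    incidence <- incidence[order(incidence$period, incidence$level), ]
  }

  structure(
    list(timepoints = timepoints, changes = changes, adherence = adherence,
         incidence = incidence, n_participants = n_participants,
         flagged = flagged, weeks = weeks),
    class = "trial_summary"
  )
}

#' @export
print.trial_summary <- function(x, digits = 2, ...) {
  cat(sprintf("In-silico titration trial summary (N = %d participants, %d weeks)\n\n",
              x$n_participants, x$weeks))
  cat("Glycemic outcomes, insulin doses and BMI by timepoint (mean (SD) [n]):\n")
  tp <- x$timepoints
  for (v in unique(as.character(tp$variable))) {
    tv <- tp[tp$variable == v, ]
    cells <- sprintf("wk%-2d %s (%s) [%d]", tv$week,
                     formatC(tv$mean, digits = digits, format = "f"),
                     ifelse(is.na(tv$sd), "NA", formatC(tv$sd, digits = digits, format = "f")),
                     tv$n)
    cat(sprintf("  %-17s %s\n", v, paste(cells, collapse = "  ")))
  }
  cat("\nChange scores (mean to - mean from):\n")
  ch <- x$changes
  for (r in seq_len(nrow(ch))) {
    cat(sprintf("  %-17s wk%d -> wk%d : %+.*f\n", ch$variable[r],
                ch$from_week[r], ch$to_week[r], digits, ch$delta[r]))
  }
  if (!is.null(x$adherence)) {
    cat("\nSMBG adherence:\n")
    a <- x$adherence
    for (r in seq_len(nrow(a))) {
      cat(sprintf("  %-12s %5.1f%% (%.0f/%d per participant)\n", a$period[r],
                  a$adherence_pct[r], a$completed_per_participant[r],
                  a$prescribed[r] / x$n_participants))
    }
  }
  if (!is.null(x$incidence)) {
    cat("\nHypoglycemia incidence per participant (episodes):\n")
    inc <- x$incidence
    for (p in unique(inc$period)) {
      ip <- inc[inc$period == p, ]
      cat(sprintf("  %-12s %s\n", p,
                  paste(sprintf("level %d: %.2f (%d)", ip$level, ip$incidence, ip$episodes),
                        collapse = "  ")))
    }
  }
  if (length(x$flagged)) {
    cat("\nFlagged:", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
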