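#' Summarise one review window of SMBG readings, per slot
#'
#' Deduplicates readings to at most one per (day, slot) — keeping the earliest
#' — and computes, for each prescribed slot, the count, median, fraction above
#' and below the target band, minimum, and hypoglycemia-level tallies over the
#' window.
#'
#' @param readings A data frame with columns `slot` and `glucose`
#'   (mmol/L); optional `time` (POSIXct, used for deduplication and ordering)
#'   and `assisted` (logical, external assistance required).
#' @param config A [titrationConfig()].
#' @return A data frame with one row per slot (both slots always present):
#'   `slot`, `n`, `median`, `frac_above`, `frac_below`, `min`, `n_level1`,
#'   `n_level2`, `n_level3`, `missing`. Slots with no readings are flagged
#'   `missing` with `n = 0` and `NA` statistics.
#' @examples
#' w <- data.frame(slot = rep(c("prebreakfast", "predinner"), 7), glucose = 6)
#' summarizeWindow(w)
#' @export
summarizeWindow <- function(readings, config = titrationConfig()) {
  stopifnot(inherits(config, "titration_config"))
  readings <- as.data.frame(readings)
  if (!all(c("slot", "glucose") %in% names(readings))) {
    stop("readings must have columns `slot` and `glucose`")
  }
  slot <- as.character(readings$slot)
  glucose <- as.numeric(readings$glucose)
  assisted <- if ("assisted" %in% names(readings)) as.logical(readings$assisted) else rep(FALSE, length(slot))
  assisted[is.na(assisted)] <- FALSE

  bad <- which(!(slot %in% SMBG_SLOTS) | is.na(glucose) | glucose <= 0 | glucose >= 50)
  if (length(bad)) {
    stop(sprintf("rejected %d record(s) (unknown slot or non-physiological glucose) at row(s): %s",
                 length(bad), paste(bad, collapse = ", ")))
  }

  # at most one reading per (day, slot): keep the earliest
  if ("time" %in% names(readings) && nrow(readings) > 0) {
    tm <- readings$time
    ord <- order(slot, tm)
    slot <- slot[ord]; glucose <- glucose[ord]; assisted <- assisted[ord]; tm <- tm[ord]
    keep <- !duplicated(paste(slot, as.Date(tm, tz = "UTC")))
    slot <- slot[keep]; glucose <- glucose[keep]; assisted <- assisted[keep]
  }

  out <- lapply(SMBG_SLOTS, function(s) {
    g <- glucose[slot == s]
    a <- assisted[slot == s]
    if (length(g) == 0) {
      return(data.frame(slot = s, n = 0L, median = NA_real_, frac_above = NA_real_,
                        frac_below = NA_real_, min = NA_real_,
                        n_level1 = 0L, n_level2 = 0L, n_level3 = 0L, missing = TRUE))
    }
    data.frame(
      slot = s, n = length(g),
      median = stats::median(g),
      frac_above = mean(g > config$band_high),
      frac_below = mean(g < config$band_low),
      min = min(g),
      n_level1 = sum(!a & g >= 3.0 & g <= 3.9),
      n_level2 = sum(!a & g < 3.0),
      n_level3 = sum(a),
      missing = FALSE
    )
  })
  do.call(rbind, out)
}

#' Classify the weekly consistency of a slot's readings
#'
#' A slot is `consistently_above` when at least the configured fraction
#' (default 4/7) of its readings exceed the band's upper edge *and* the slot
#' median exceeds it; symmetrically for `consistently_below`. Fewer than
#' `min_readings_per_slot` readings yield `insufficient`. Otherwise the slot
#' is `in_range` (median inside the band) or `mixed`.
#'
#' @param summary Output of [summarizeWindow()] (one or more rows).
#' @param config A [titrationConfig()].
#' @return Character vector, one classification per row of `summary`, with
#'   values in `c("consistently_above", "consistently_below", "in_range",
#'   "mixed", "insufficient")`.
#' @export
classifyConsistency <- function(summary, config = titrationConfig()) {
  stopifnot(inherits(config, "titration_config"))
  thr <- config$consistency_threshold - 1e-9
  vapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, ]
    if (s$n < config$min_readings_per_slot) return("insufficient")
    if (s$frac_above >= thr && s$median > config$band_high) return("consistently_above")
    if (s$frac_below >= thr && s$median < config$band_low) return("consistently_below")
    if (s$median >= config$band_low && s$median <= config$band_high) return("in_range")
    "mixed"
  }, character(1))
}

# decision for one reading slot given its weekly summary; returns the signed
# delta, tier fraction and rationale for the governing dose
slot_decision <- function(s, consistency, dose, config) {
  hypo_force <- s$n_level2 >= 1 || s$n_level1 >= 2
  if (hypo_force) {
    f <- if (s$n_level2 >= 1) config$step_severe else config$step_moderate
    d <- -max(1, round_units(f * dose))
    r <- "hypo_decrement"
  } else if (consistency == "consistently_above") {
    f <- if (s$median <= config$band_high + config$severity_margin) config$step_moderate else config$step_severe
    d <- max(1, round_units(f * dose))
    r <- "hyper_increment"
  } else if (consistency == "consistently_below") {
    f <- if (s$median >= config$band_low - config$severity_margin) config$step_moderate else config$step_severe
    d <- -max(1, round_units(f * dose))
    r <- "hypo_decrement"
  } else if (consistency == "insufficient") {
    f <- 0; d <- 0; r <- "insufficient_data"
  } else {
    f <- 0; d <- 0; r <- "in_range"
  }
  # a zero dose can be neither incremented (step ceiling is 20% of current
  # dose) nor decremented
  if (d != 0 && dose == 0) {
    d <- 0; f <- 0; r <- "capped"
  }
  # hard per-step ceiling
  cap <- ceiling(config$step_severe * dose)
  if (abs(d) > cap) d <- sign(d) * cap
  # doses floor at zero
  if (dose + d < 0) d <- -dose
  list(delta = d, frac = f, rationale = r)
}

# build a recommendation object from per-dose-slot decisions
make_recommendation <- function(reg, delta, frac, rationale, config, urgent = FALSE) {
  # TDD safety cap: truncate increments (largest first; morning breaks ties)
  cap_tdd <- config$tdd_cap_per_kg * reg$weight_kg
  new_tdd <- tdd(reg) + sum(delta)
  if (new_tdd > cap_tdd) {
    excess <- ceiling(new_tdd - cap_tdd)
    for (ds in DOSE_SLOTS[order(-delta[DOSE_SLOTS])]) {
      if (excess <= 0) break
      if (delta[ds] > 0) {
        cut <- min(delta[ds], excess)
        delta[ds] <- delta[ds] - cut
        excess <- excess - cut
        rationale[ds] <- "capped"
        if (delta[ds] == 0) frac[ds] <- 0
      }
    }
  }
  new_reg <- regimen(reg$morning_dose + delta[["morning"]],
                     reg$evening_dose + delta[["evening"]],
                     reg$weight_kg)
  structure(
    list(
      slot_changes = delta,
      new_regimen = new_reg,
      old_regimen = reg,
      rationale = rationale,
      step_fraction = frac,
      urgent = urgent,
      approval = "pending",
      decided_at = NULL,
      active_regimen = reg
    ),
    class = "recommendation"
  )
}

#' Weekly algorithm-guided dose recommendation
#'
#' Applies the treat-to-target rules to one review window of readings for one
#' participant. Each reading slot governs one premix dose via the cross-over
#' convention (prebreakfast -> evening dose, predinner -> morning dose). A
#' slot consistently above the band earns its governing dose an increment of
#' 15% (20% if the slot median exceeds the band edge by more than the severity
#' margin); consistently below, a symmetric decrement. Hypoglycemia takes
#' precedence: any level-2 reading, or two or more level-1 readings, in a slot
#' forbids an increment and forces a decrement of the governing dose (severe
#' tier if level 2 occurred). Deltas are rounded half-away-from-zero to whole
#' units (minimum effected change 1 unit), never exceed 20% of the current
#' dose, and the resulting total daily dose is truncated to the configured
#' units/kg safety cap.
#'
#' @param readings One review window of readings (see [summarizeWindow()]).
#' @param reg The participant's current [regimen()].
#' @param config A [titrationConfig()].
#' @return An object of class `recommendation` with elements `slot_changes`
#'   (named signed deltas, whole units, names `morning`/`evening`),
#'   `new_regimen`, `old_regimen`, `rationale` (per dose slot: `in_range`,
#'   `hyper_increment`, `hypo_decrement`, `insufficient_data`, `capped`),
#'   `step_fraction` (tier used, in \[0, 0.20\]), `urgent`, and `approval`
#'   (`"pending"` until [applyApproval()]).
#' @examples
#' w <- data.frame(
#'   slot = rep(c("prebreakfast", "predinner"), each = 7),
#'   glucose = c(10, 10, 9, 11, 10, 10, 9, 6, 6, 7, 6, 5, 6, 6)
#' )
#' recommendDoses(w, regimen(30, 20, 75))
#' @export
recommendDoses <- function(readings, reg, config = titrationConfig()) {
  stopifnot(inherits(reg, "regimen"))
  summ <- summarizeWindow(readings, config)
  cons <- classifyConsistency(summ, config)

  delta <- c(morning = 0, evening = 0)
  frac <- c(morning = 0, evening = 0)
  rationale <- c(morning = "in_range", evening = "in_range")
  for (i in seq_len(nrow(summ))) {
    ds <- unname(governingDose(summ$slot[i]))
    dec <- slot_decision(summ[i, ], cons[i], dose_of(reg, ds), config)
    delta[ds] <- dec$delta
    frac[ds] <- dec$frac
    rationale[ds] <- dec$rationale
  }
  make_recommendation(reg, delta, frac, rationale, config)
}

#' Urgent out-of-cycle hypoglycemia response
#'
#' Scans the readings uploaded since the last review; any reading below the
#' urgent threshold (default 3.0 mmol/L, level-2 hypoglycemia) triggers an
#' immediate severe-tier decrement of the governing dose of that slot, without
#' waiting for the weekly review. At most one urgent recommendation is issued
#' per slot per window: slots already handled are passed in
#' `already_triggered` and are skipped.
#'
#' @param readings Readings since the last review (see [summarizeWindow()]).
#' @param reg Current [regimen()].
#' @param config A [titrationConfig()].
#' @param already_triggered Character vector of reading slots for which an
#'   urgent recommendation was already issued this window.
#' @return A `recommendation` with `urgent = TRUE`, or `NULL` if no untreated
#'   slot has a reading below the urgent threshold.
#' @examples
#' r <- data.frame(slot = "predinner", glucose = 2.8)
#' hypoglycemiaTrigger(r, regimen(40, 20, 75))
#' @export
hypoglycemiaTrigger <- function(readings, reg, config = titrationConfig(),
                                already_triggered = character()) {
  stopifnot(inherits(reg, "regimen"))
  readings <- as.data.frame(readings)
  slot <- as.character(readings$slot)
  glucose <- as.numeric(readings$glucose)
  hypo_slots <- setdiff(unique(slot[glucose < config$urgent_threshold]), already_triggered)
  if (length(hypo_slots) == 0) return(NULL)

  delta <- c(morning = 0, evening = 0)
  frac <- c(morning = 0, evening = 0)
  rationale <- c(morning = "in_range", evening = "in_range")
  for (rs in hypo_slots) {
    ds <- unname(governingDose(rs))
    dose <- dose_of(reg, ds)
    d <- -max(1, round_units(config$step_severe * dose))
    r <- "hypo_decrement"
    if (dose == 0) { d <- 0; r <- "capped" } else frac[ds] <- config$step_severe
    if (abs(d) > ceiling(config$step_severe * dose)) d <- sign(d) * ceiling(config$step_severe * dose)
    if (dose + d < 0) d <- -dose
    delta[ds] <- d
    rationale[ds] <- r
  }
  make_recommendation(reg, delta, frac, rationale, config, urgent = TRUE)
}

#' Record the physician's decision on a recommendation
#'
#' Every recommendation must be accepted or declined exactly once. Accepting
#' activates the recommended regimen; declining leaves the previous regimen
#' active. A second decision on the same recommendation is an error.
#'
#' @param rec A `recommendation` with `approval == "pending"`.
#' @param decision `"accept"` or `"decline"`.
#' @param time Decision timestamp (recorded on the returned object).
#' @param auto Logical; `TRUE` marks an accept as `auto_accepted` (simulated
#'   physician gate).
#' @return The recommendation with `approval` set and `active_regimen` holding
#'   the now-active [regimen()] (retrieve with [activeRegimen()]).
#' @examples
#' rec <- recommendDoses(
#'   data.frame(slot = rep(c("prebreakfast", "predinner"), 7), glucose = 6),
#'   regimen(30, 20, 75)
#' )
#' rec <- applyApproval(rec, "accept")
#' activeRegimen(rec)
#' @export
applyApproval <- function(rec, decision = c("accept", "decline"),
                          time = Sys.time(), auto = FALSE) {
  stopifnot(inherits(rec, "recommendation"))
  decision <- match.arg(decision)
  if (!identical(rec$approval, "pending")) {
    stop("recommendation already decided (approval = ", rec$approval, ")")
  }
  if (decision == "accept") {
    rec$approval <- if (auto) "auto_accepted" else "accepted"
    rec$active_regimen <- rec$new_regimen
  } else {
    rec$approval <- "declined"
    rec$active_regimen <- rec$old_regimen
  }
  rec$decided_at <- time
  rec
}

#' Regimen in force after a recommendation was decided
#' @param rec A decided `recommendation`.
#' @return The active [regimen()].
#' @export
activeRegimen <- function(rec) {
  stopifnot(inherits(rec, "recommendation"))
  rec$active_regimen
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("%s dose recommendation (%s)\n",
              if (x$urgent) "Urgent" else "Weekly", x$approval))
  for (ds in DOSE_SLOTS) {
    cat(sprintf("  %-8s %+d U (%s, tier %.0f%%): %d -> %d U\n",
                ds, x$slot_changes[[ds]], x$rationale[[ds]],
                100 * x$step_fraction[[ds]],
                dose_of(x$old_regimen, ds), dose_of(x$new_regimen, ds)))
  }
  invisible(x)
}
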