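#' Titration rule configuration
#'
#' All tunable constants of the dose-adjustment rules. Defaults encode the
#' published protocol where it is explicit (glycemic band 4-8 mmol/L, weekly
#' review, step ceiling 15-20%) and conservative clinical conventions where it
#' is not (consistency threshold, severity tiers, urgent hypoglycemia
#' threshold, TDD safety cap).
#'
#' @param band_low,band_high Target capillary glucose band, mmol/L
#'   (default 4 and 8).
#' @param consistency_threshold Minimum fraction of a slot's weekly readings
#'   that must fall outside the band (on the same side) for the deviation to
#'   count as consistent (default 4/7).
#' @param min_readings_per_slot Minimum readings per slot per window for any
#'   adjustment; fewer readings yield `insufficient_data` (default 4).
#' @param step_moderate,step_severe Fractional dose-step tiers (defaults 0.15
#'   and 0.20). `step_severe` is also the hard per-step ceiling.
#' @param severity_margin Distance (mmol/L) of the slot median beyond the band
#'   edge past which the severe tier applies (default 2).
#' @param urgent_threshold Glucose (mmol/L) below which an urgent, out-of-cycle
#'   decrement is issued (default 3.0, i.e. level-2 hypoglycemia).
#' @param tdd_cap_per_kg Safety cap on total daily insulin dose, units/kg
#'   (default 1.5); recommendations are truncated to respect it.
#' @param accept_probability Probability that the simulated physician gate
#'   accepts a recommendation (default 1).
#' @param debounce_gap_min Gap (minutes) under which successive qualifying
#'   hypoglycemic readings merge into a single episode (default 60).
#' @return An object of class `titration_config`.
#' @examples
#' titrationConfig()
#' titrationConfig(band_high = 7)
#' @export
titrationConfig <- function(band_low = 4,
                            band_high = 8,
                            consistency_threshold = 4 / 7,
                            min_readings_per_slot = 4L,
                            step_moderate = 0.15,
                            step_severe = 0.20,
                            severity_margin = 2,
                            urgent_threshold = 3.0,
                            tdd_cap_per_kg = 1.5,
                            accept_probability = 1.0,
                            debounce_gap_min = 60) {
  stopifnot(
    is.numeric(band_low), is.numeric(band_high), band_low > 0,
    band_low < band_high,
    consistency_threshold > 0, consistency_threshold <= 1,
    min_readings_per_slot >= 1,
    step_moderate > 0, step_severe > 0, step_moderate <= step_severe,
    step_severe <= 0.20 + 1e-12,
    severity_margin >= 0,
    urgent_threshold > 0, urgent_threshold < band_low,
    tdd_cap_per_kg > 0,
    accept_probability >= 0, accept_probability <= 1,
    debounce_gap_min >= 0
  )
  structure(
    list(
      band_low = band_low,
      band_high = band_high,
      consistency_threshold = consistency_threshold,
      min_readings_per_slot = as.integer(min_readings_per_slot),
      step_moderate = step_moderate,
      step_severe = step_severe,
      severity_margin = severity_margin,
      urgent_threshold = urgent_threshold,
      tdd_cap_per_kg = tdd_cap_per_kg,
      accept_probability = accept_probability,
      debounce_gap_min = debounce_gap_min
    ),
    class = "titration_config"
  )
}

#' @export
print.titration_config <- function(x, ...) {
  cat("Titration rules\n")
  cat(sprintf("  target band           : %.1f - %.1f mmol/L\n", x$band_low, x$band_high))
  cat(sprintf("  consistency threshold : %.3f of slot readings (min %d readings)\n",
              x$consistency_threshold, x$min_readings_per_slot))
  cat(sprintf("  step tiers            : %.0f%% moderate / %.0f%% severe (margin %.1f mmol/L)\n",
              100 * x$step_moderate, 100 * x$step_severe, x$severity_margin))
  cat(sprintf("  urgent threshold      : < %.1f mmol/L\n", x$urgent_threshold))
  cat(sprintf("  TDD cap               : %.2f units/kg\n", x$tdd_cap_per_kg))
  invisible(x)
}
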