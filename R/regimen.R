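#' Premixed-insulin regimen
#'
#' Current twice-daily premixed insulin doses plus body weight for
#' units-per-kg accounting. Doses are whole insulin units (pens dose whole
#' units).
#'
#' @param morning_dose,evening_dose Non-negative whole insulin units.
#' @param weight_kg Body weight in kg, positive.
#' @return An object of class `regimen`.
#' @examples
#' r <- regimen(30, 20, 75)
#' tdd(r)
#' tddPerKg(r)
#' @export
regimen <- function(morning_dose, evening_dose, weight_kg) {
  stopifnot(
    length(morning_dose) == 1, length(evening_dose) == 1, length(weight_kg) == 1,
    is.numeric(morning_dose), is.numeric(evening_dose), is.numeric(weight_kg),
    morning_dose >= 0, evening_dose >= 0, weight_kg > 0,
    morning_dose == floor(morning_dose), evening_dose == floor(evening_dose)
  )
  structure(
    list(
      morning_dose = as.integer(morning_dose),
      evening_dose = as.integer(evening_dose),
      weight_kg = as.numeric(weight_kg)
    ),
    class = "regimen"
  )
}

#' Total daily dose of a regimen
#' @param x A [regimen()].
#' @return Total daily dose in insulin units.
#' @export
tdd <- function(x) {
  stopifnot(inherits(x, "regimen"))
  x$morning_dose + x$evening_dose
}

#' Total daily dose per kilogram body weight
#' @param x A [regimen()].
#' @return Total daily dose in units/kg/day.
#' @export
tddPerKg <- function(x) tdd(x) / x$weight_kg

# dose of a given dose slot ("morning"/"evening")
dose_of <- function(x, dose_slot) {
  if (dose_slot == "morning") x$morning_dose else x$evening_dose
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Premixed insulin regimen: %d U morning + %d U evening (TDD %d U, %.2f U/kg at %.1f kg)\n",
              x$morning_dose, x$evening_dose, tdd(x), tddPerKg(x), x$weight_kg))
  invisible(x)
}
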