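# Independent brute-force evaluator of the weekly dose-adjustment rule table.
# Deliberately scalar and explicit (own median, literal counting); shares no
# code path with the package implementation.

oracle_round <- function(x) {
  if (x >= 0) floor(x + 0.5) else -floor(-x + 0.5)
}

oracle_median <- function(g) {
  s <- sort(g)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# decision for one reading slot; returns the signed delta for the governing
# dose (before the TDD cap)
oracle_slot_delta <- function(g, dose, cfg) {
  n <- length(g)
  n_l2 <- 0; n_l1 <- 0
  for (x in g) {
    if (x < 3.0) n_l2 <- n_l2 + 1
    else if (x <= 3.9) n_l1 <- n_l1 + 1
  }
  delta <- 0
  if (n_l2 >= 1 || n_l1 >= 2) {
    tier <- if (n_l2 >= 1) cfg$step_severe else cfg$step_moderate
    delta <- -max(1, oracle_round(tier * dose))
  } else if (n >= cfg$min_readings_per_slot) {
    med <- oracle_median(g)
    n_above <- 0; n_below <- 0
    for (x in g) {
      if (x > cfg$band_high) n_above <- n_above + 1
      if (x < cfg$band_low) n_below <- n_below + 1
    }
    if (n_above / n >= cfg$consistency_threshold - 1e-9 && med > cfg$band_high) {
      tier <- if (med <= cfg$band_high + cfg$severity_margin) cfg$step_moderate else cfg$step_severe
      delta <- max(1, oracle_round(tier * dose))
    } else if (n_below / n >= cfg$consistency_threshold - 1e-9 && med < cfg$band_low) {
      tier <- if (med >= cfg$band_low - cfg$severity_margin) cfg$step_moderate else cfg$step_severe
      delta <- -max(1, oracle_round(tier * dose))
    }
  }
  if (dose == 0) delta <- 0
  ceil_cap <- ceiling(cfg$step_severe * dose)
  if (abs(delta) > ceil_cap) delta <- sign(delta) * ceil_cap
  if (dose + delta < 0) delta <- -dose
  delta
}

# independent scalar iteration of the noiseless titration map; returns the
# weekly dose path (week 0 .. weeks), mirroring the glucometer's 0.1 display
oracle_noiseless_path <- function(setpoint_pre, setpoint_din, morning, evening,
                                  weight, sens, weeks, cfg = titrationConfig()) {
  path <- matrix(NA_real_, nrow = weeks + 1, ncol = 2,
                 dimnames = list(NULL, c("morning", "evening")))
  path[1, ] <- c(morning, evening)
  for (w in seq_len(weeks)) {
    r_pre <- round(setpoint_pre - sens * evening / weight, 1)
    r_din <- round(setpoint_din - sens * morning / weight, 1)
    d <- oracle_recommend(rep(r_pre, 7), rep(r_din, 7), morning, evening, weight, cfg)
    morning <- morning + d[["morning"]]
    evening <- evening + d[["evening"]]
    path[w + 1, ] <- c(morning, evening)
  }
  path
}

# full window decision: cross-over mapping plus the TDD safety cap
oracle_recommend <- function(pre, din, morning, evening, weight, cfg = titrationConfig()) {
  d_evening <- oracle_slot_delta(pre, evening, cfg)   # prebreakfast -> evening dose
  d_morning <- oracle_slot_delta(din, morning, cfg)   # predinner -> morning dose
  total <- morning + evening + d_morning + d_evening
  cap <- cfg$tdd_cap_per_kg * weight
  if (total > cap) {
    excess <- ceiling(total - cap)
    # truncate increments, largest first, morning breaking ties
    order_slots <- if (d_evening > d_morning) c("evening", "morning") else c("morning", "evening")
    for (s in order_slots) {
      if (excess <= 0) break
      d <- if (s == "morning") d_morning else d_evening
      if (d > 0) {
        cut <- min(d, excess)
        if (s == "morning") d_morning <- d_morning - cut else d_evening <- d_evening - cut
        excess <- excess - cut
      }
    }
  }
  c(morning = d_morning, evening = d_evening)
}
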