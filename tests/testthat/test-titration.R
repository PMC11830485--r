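test_that("window summaries count, locate and bound readings per slot", {
  w <- data.frame(slot = rep(c("prebreakfast", "predinner"), 7), glucose = 6.0)
  s <- summarizeWindow(w)
  expect_equal(s$median, c(6, 6))
  expect_equal(s$frac_above, c(0, 0))
  expect_equal(s$frac_below, c(0, 0))

  s <- summarizeWindow(make_week(pre = c(10, 10, 9, 11, 10, 10, 9),
                                 din = c(6, 6, 7, 6, 5, 6, 6)))
  expect_equal(s$frac_above[s$slot == "prebreakfast"], 1.0)
  expect_equal(s$frac_above[s$slot == "predinner"], 0)

  s <- summarizeWindow(make_week(pre = c(6, 3.2, 7), din = 6))
  expect_equal(s$min[s$slot == "prebreakfast"], 3.2)
  expect_gt(s$frac_below[s$slot == "prebreakfast"], 0)
})

test_that("malformed records are rejected with their row numbers", {
  expect_error(summarizeWindow(data.frame(slot = "lunch", glucose = 6)), "rejected")
  expect_error(summarizeWindow(data.frame(slot = "predinner", glucose = -1)), "rejected")
  expect_error(summarizeWindow(data.frame(slot = c("prebreakfast", "predinner"),
                                          glucose = c(6, 55))), "2")
})

test_that("duplicate (day, slot) readings keep the earliest", {
  t0 <- as.POSIXct("2020-09-07 07:30", tz = "UTC")
  w <- data.frame(slot = "prebreakfast", glucose = c(9, 5),
                  time = c(t0 + 3600, t0))  # 5 measured first
  s <- summarizeWindow(w)
  expect_equal(s$n[s$slot == "prebreakfast"], 1)
  expect_equal(s$median[s$slot == "prebreakfast"], 5)
})

test_that("consistency classification follows the 4-of-7 + median rule", {
  cfg <- default_cfg
  cls <- function(g) classifyConsistency(summarizeWindow(make_week(pre = g, din = rep(6, 7)), cfg), cfg)[1]
  expect_equal(cls(rep(9, 7)), "consistently_above")
  expect_equal(cls(c(8.5, 8.6, 9, 10, 7, 6, 5)), "consistently_above")  # 4/7 above, median 8.5
  expect_equal(cls(c(9, 9, 9, 6, 6, 6, 6)), "in_range")  # 3/7 above, median in band
  # median outside the band without the count threshold only happens at even
  # n (the median then averages across the edge): mixed
  expect_equal(cls(c(2.2, 2.2, 5, 9)), "mixed")
  expect_equal(cls(c(9, 9, 9)), "insufficient")                          # below min readings
  expect_equal(cls(rep(6, 7)), "in_range")
  expect_equal(cls(rep(3.2, 7)), "consistently_below")
})

test_that("in-band week is a no-change fixed point, repeatedly", {
  w <- data.frame(slot = rep(c("prebreakfast", "predinner"), 7), glucose = 6.0)
  reg <- regimen(30, 20, 75)
  for (k in 1:3) {
    rec <- recommendDoses(w, reg, default_cfg)
    expect_equal(unname(rec$slot_changes), c(0, 0))
    expect_equal(unname(rec$rationale), c("in_range", "in_range"))
    reg <- rec$new_regimen
  }
  expect_equal(reg$morning_dose, 30)
  expect_equal(reg$evening_dose, 20)
})

test_that("consistent hyperglycemia increments the governing cross-over dose", {
  # prebreakfast high governs the evening premix; 15% of 20 U = 3 U
  w <- make_week(pre = c(10, 11, 10, 10, 11, 10, 10), din = rep(6, 7))
  rec <- recommendDoses(w, regimen(30, 20, 75), default_cfg)
  expect_equal(rec$slot_changes[["evening"]], 3)
  expect_equal(rec$new_regimen$evening_dose, 23)
  expect_equal(rec$rationale[["evening"]], "hyper_increment")
  expect_equal(rec$step_fraction[["evening"]], 0.15)
  expect_equal(rec$slot_changes[["morning"]], 0)

  # median far above the band edge escalates to the severe 20% tier
  w <- make_week(pre = rep(13, 7), din = rep(6, 7))
  rec <- recommendDoses(w, regimen(30, 20, 75), default_cfg)
  expect_equal(rec$step_fraction[["evening"]], 0.20)
  expect_equal(rec$slot_changes[["evening"]], 4)
})

test_that("hypoglycemia forces a decrement and forbids increments", {
  # two level-1 predinner readings decrement the morning premix by 15%
  w <- make_week(pre = rep(6, 7), din = c(6, 6, 3.4, 6, 3.1, 6, 6))
  rec <- recommendDoses(w, regimen(40, 20, 75), default_cfg)
  expect_equal(rec$slot_changes[["morning"]], -6)
  expect_equal(rec$new_regimen$morning_dose, 34)
  expect_equal(rec$rationale[["morning"]], "hypo_decrement")

  # a level-2 reading escalates to the severe tier
  w <- make_week(pre = rep(6, 7), din = c(6, 6, 2.8, 6, 6, 6, 6))
  rec <- recommendDoses(w, regimen(40, 20, 75), default_cfg)
  expect_equal(rec$slot_changes[["morning"]], -8)
  expect_equal(rec$step_fraction[["morning"]], 0.20)

  # even when the rest of the week is hyperglycemic, no increment is allowed
  w <- make_week(pre = rep(6, 7), din = c(12, 12, 2.8, 12, 12, 12, 12))
  rec <- recommendDoses(w, regimen(40, 20, 75), default_cfg)
  expect_lt(rec$slot_changes[["morning"]], 0)
})

test_that("zero doses and the TDD cap truncate changes with a capped rationale", {
  w <- make_week(pre = rep(6, 7), din = c(3.1, 3.2, 6, 6, 6, 6, 6))
  rec <- recommendDoses(w, regimen(0, 20, 75), default_cfg)
  expect_equal(rec$slot_changes[["morning"]], 0)
  expect_equal(rec$rationale[["morning"]], "capped")

  # 60 kg x 1.5 U/kg = 90 U cap; 50+39 = 89, severe increment requested +10
  w <- make_week(pre = rep(13, 7), din = rep(6, 7))
  rec <- recommendDoses(w, regimen(50, 39, 60), default_cfg)
  expect_equal(rec$slot_changes[["evening"]], 1)
  expect_equal(rec$rationale[["evening"]], "capped")
  expect_lte(tdd(rec$new_regimen), 1.5 * 60)
})

test_that("insufficient readings never move a dose", {
  w <- make_week(pre = c(12, 12, 12), din = c(12, 12))
  rec <- recommendDoses(w, regimen(30, 20, 75), default_cfg)
  expect_equal(unname(rec$slot_changes), c(0, 0))
  expect_equal(unname(rec$rationale), rep("insufficient_data", 2))
})

test_that("steps stay inside the 15-20% bounds over randomized windows", {
  set.seed(4711)
  for (k in 1:300) {
    w <- rand_window()
    reg <- rand_regimen()
    rec <- recommendDoses(w, reg, default_cfg)
    for (ds in c("morning", "evening")) {
      dose <- if (ds == "morning") reg$morning_dose else reg$evening_dose
      d <- rec$slot_changes[[ds]]
      expect_lte(abs(d), ceiling(0.20 * dose))
      if (d != 0 && rec$rationale[[ds]] != "capped") {
        expect_gte(abs(d), max(1, floor(0.15 * dose)))
      }
      expect_gte(if (ds == "morning") rec$new_regimen$morning_dose else rec$new_regimen$evening_dose, 0)
      expect_true(rec$step_fraction[[ds]] >= 0 && rec$step_fraction[[ds]] <= 0.20)
    }
  }
})

test_that("raising prebreakfast readings never lowers the evening recommendation", {
  set.seed(99)
  for (k in 1:100) {
    pre <- sample(c(2.8, 3.4, 5, 7, 9, 12), 7, replace = TRUE)
    reg <- regimen(sample(5:60, 1), sample(5:60, 1), 200)  # heavy: cap not binding
    d0 <- recommendDoses(make_week(pre, rep(6, 7)), reg, default_cfg)$slot_changes[["evening"]]
    shift <- runif(1, 0.5, 6)
    d1 <- recommendDoses(make_week(pre + shift, rep(6, 7)), reg, default_cfg)$slot_changes[["evening"]]
    expect_gte(d1, d0)
  }
})

test_that("urgent trigger fires below 3.0 mmol/L, once per slot per window", {
  reg <- regimen(40, 20, 75)
  rec <- hypoglycemiaTrigger(data.frame(slot = "predinner", glucose = 2.8), reg)
  expect_true(rec$urgent)
  expect_true(rec$slot_changes[["morning"]] %in% c(-6, -8))
  expect_equal(rec$slot_changes[["evening"]], 0)

  # level 1 waits for the weekly review
  expect_null(hypoglycemiaTrigger(data.frame(slot = "predinner", glucose = 3.5), reg))

  # repeated level-2 readings in the same window trigger only once
  rec1 <- hypoglycemiaTrigger(data.frame(slot = "predinner", glucose = c(2.8, 2.7)), reg)
  expect_true(!is.null(rec1))
  expect_null(hypoglycemiaTrigger(data.frame(slot = "predinner", glucose = 2.8), reg,
                                  already_triggered = "predinner"))
})

test_that("the approval gate applies or discards a recommendation exactly once", {
  w <- make_week(pre = c(10, 11, 10, 10, 11, 10, 10), din = rep(6, 7))
  reg <- regimen(30, 20, 75)
  rec <- recommendDoses(w, reg, default_cfg)
  acc <- applyApproval(rec, "accept")
  expect_equal(acc$approval, "accepted")
  expect_equal(activeRegimen(acc)$evening_dose, 23)
  expect_equal(activeRegimen(acc)$morning_dose, 30)

  dec <- applyApproval(rec, "decline")
  expect_equal(dec$approval, "declined")
  expect_equal(activeRegimen(dec)$evening_dose, 20)

  expect_error(applyApproval(acc, "decline"), "already decided")
  expect_error(applyApproval(dec, "accept"), "already decided")
})

test_that("recommendations agree with the brute-force rule-table oracle", {
  cfg <- default_cfg
  # exhaustive: all multisets of up to 5 readings from a spanning grid in one
  # slot, the other slot held in range, across dose levels
  grid <- c(2.8, 3.5, 6.0, 9.0, 10.5)
  for (dose in c(0, 3, 20, 47)) {
    for (n in 0:4) {
      combos <- if (n == 0) list(numeric(0)) else
        asplit(as.matrix(expand.grid(rep(list(grid), n))), 1)
      for (g in combos) {
        g <- as.numeric(g)
        rec <- recommendDoses(make_week(pre = g, din = rep(6, 7)), regimen(40, dose, 100), cfg)
        exp <- oracle_recommend(g, rep(6, 7), 40, dose, 100, cfg)
        expect_identical(unname(rec$slot_changes[["evening"]]), unname(exp[["evening"]]),
                         label = sprintf("evening delta for dose %d, window {%s}", dose,
                                         paste(g, collapse = ",")))
      }
    }
  }
  # randomized two-slot windows, random regimens (cap sometimes binding)
  set.seed(2024)
  for (k in 1:2000) {
    w <- rand_window()
    reg <- rand_regimen()
    rec <- recommendDoses(w, reg, cfg)
    exp <- oracle_recommend(w$glucose[w$slot == "prebreakfast"],
                            w$glucose[w$slot == "predinner"],
                            reg$morning_dose, reg$evening_dose, reg$weight_kg, cfg)
    expect_identical(unname(rec$slot_changes), unname(exp))
  }
})
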