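test_that("the 1800/100 and 500/300 rules give ISF and ICR", {
  expect_equal(compute_isf(50, "mg/dL"), 36)
  expect_equal(compute_isf(50, "mmol/L"), 2)
  expect_equal(compute_isf(1800, "mg/dL"), 1)
  expect_equal(compute_icr(50), 10)
  expect_equal(compute_icr(8), 37.5)   # small-dose 300 rule
  expect_equal(compute_icr(10), 50)    # boundary stays on the 500 rule
  expect_error(compute_isf(0), "positive")
  expect_error(compute_icr(-1), "positive")
  # exact identities over the TDD range
  set.seed(31)
  for (tdd in runif(200, 0.5, 200)) {
    expect_equal(compute_isf(tdd, "mg/dL") * tdd, 1800)
    expect_equal(compute_isf(tdd, "mmol/L") * tdd, 100)
    if (tdd >= 10) expect_equal(compute_icr(tdd) * tdd, 500)
    else expect_equal(compute_icr(tdd) * tdd, 300)
  }
})

test_that("correction bands generalize the printed table by goal anchor", {
  goal <- c(100, 150)
  expect_identical(correction_band(quantity(65, "mg/dL"), goal), -1L)
  expect_identical(correction_band(quantity(120, "mg/dL"), goal), 0L)
  expect_identical(correction_band(quantity(170, "mg/dL"), goal), 1L)
  expect_identical(correction_band(quantity(220, "mg/dL"), goal), 2L)
  expect_identical(correction_band(quantity(270, "mg/dL"), goal), 3L)
  expect_identical(correction_band(quantity(310, "mg/dL"), goal), 4L)
  expect_identical(correction_band(quantity(500, "mg/dL"), goal), 4L)
  # unspecified zone between 70 and the goal floor: planned dose (0)
  expect_identical(correction_band(quantity(85, "mg/dL"), goal), 0L)
  # re-anchored at a different goal
  expect_identical(correction_band(quantity(190, "mg/dL"), c(80, 130)), 2L)
})

test_that("mealtime bolus advice reproduces the worked example", {
  adv <- advise_bolus(quantity(210, "mg/dL"), quantity(120, "mg/dL"),
                      60, 50)
  expect_equal(adv$dbg, 90)
  expect_equal(adv$n1, 2.5)
  expect_equal(adv$n2, 6)
  expect_equal(adv$bd, 8.5)
  expect_equal(adv$bd_rounded, 8.5)
  expect_identical(adv$action, "inject")
  skip_adv <- advise_bolus(quantity(120, "mg/dL"), quantity(120, "mg/dL"),
                           0, 50)
  expect_equal(skip_adv$bd, 0)
  expect_identical(skip_adv$action, "skip")
  eat <- advise_bolus(quantity(84, "mg/dL"), quantity(120, "mg/dL"),
                      0, 50)
  expect_equal(eat$bd, -1)
  expect_identical(eat$action, "eat_carbs")
  expect_equal(eat$carbs_to_eat_g, 10)  # (-BD) * ICR
})

test_that("advice is invariant under glucose unit conversion", {
  set.seed(32)
  for (i in 1:100) {
    tdd <- runif(1, 15, 90)
    cbg <- runif(1, 50, 380)
    pbg <- runif(1, 80, 150)
    mc <- runif(1, 0, 120)
    a1 <- advise_bolus(quantity(cbg, "mg/dL"), quantity(pbg, "mg/dL"),
                       mc, tdd)
    a2 <- advise_bolus(convert_glucose(quantity(cbg, "mg/dL")),
                       convert_glucose(quantity(pbg, "mg/dL")), mc, tdd)
    expect_lt(abs(a1$bd - a2$bd), 0.05)
  }
})

test_that("burned calories and the exercise safety gate", {
  expect_equal(burned_calories(8, 70, 0.5), 280)
  expect_equal(burned_calories(6, 50, 1), 300)
  expect_equal(burned_calories(8, 70, 0), 0)
  expect_false(exercise_permitted(quantity(260, "mg/dL")))
  expect_false(exercise_permitted(quantity(79, "mg/dL")))
  expect_false(exercise_permitted(quantity(150, "mg/dL"), has_dka = TRUE))
  expect_true(exercise_permitted(quantity(150, "mg/dL")))
})

test_that("post-meal exercise reduces the bolus by (BC/4)/ICR", {
  adv <- advise_bolus_with_exercise(quantity(210, "mg/dL"),
                                    quantity(120, "mg/dL"), 60, 50,
                                    met = 4, weight = 50, duration_h = 0.5)
  # BC = 100 kcal -> offset (100/4)/10 = 2.5 U; BD = 8.5 - 2.5 = 6
  expect_equal(adv$exercise_offset, 2.5)
  expect_equal(adv$bd, 6)
  # zero burned calories reduces to the plain advice on random inputs
  set.seed(33)
  for (i in 1:30) {
    cbg <- quantity(runif(1, 60, 350), "mg/dL")
    pbg <- quantity(runif(1, 80, 150), "mg/dL")
    mc <- runif(1, 0, 100); tdd <- runif(1, 12, 80)
    plain <- advise_bolus(cbg, pbg, mc, tdd)
    withex <- advise_bolus_with_exercise(cbg, pbg, mc, tdd, 0, 70, 0.5)
    expect_equal(withex$bd, plain$bd)
    expect_identical(withex$action, plain$action)
  }
  # gate: too-high glucose blocks the offset
  blocked <- advise_bolus_with_exercise(quantity(260, "mg/dL"),
                                        quantity(120, "mg/dL"), 60, 50,
                                        8, 70, 1)
  expect_false(blocked$exercise_permitted)
  expect_equal(blocked$exercise_offset, 0)
})

test_that("exercise away from meals depends on weight status", {
  # overweight: insulin equivalent subtracted from the correction dose
  over <- advise_exercise_only(quantity(192, "mg/dL"),
                               quantity(120, "mg/dL"), 50,
                               met = 4, weight = 40, duration_h = 0.5,
                               weight_status = "overweight")
  # N1 = 72/36 = 2; BC = 80 -> (80/4)/10 = 2; dose 0 -> skip
  expect_equal(over$n1, 2)
  expect_equal(over$bd, 0)
  expect_identical(over$action, "skip")
  norm <- advise_exercise_only(quantity(120, "mg/dL"),
                               quantity(120, "mg/dL"), 50,
                               met = 4, weight = 40, duration_h = 0.5,
                               weight_status = "normal")
  expect_equal(norm$carbs_to_eat_g, 20)  # BC/4
  expect_equal(norm$n1, 2)               # 0 + (BC/4)/ICR added to N1
  zero <- advise_exercise_only(quantity(150, "mg/dL"),
                               quantity(120, "mg/dL"), 50, 4, 40, 0,
                               "normal")
  expect_equal(zero$bd, 30 / 36)
  expect_true(is.na(zero$carbs_to_eat_g) || zero$carbs_to_eat_g == 0)
})

test_that("pattern detection reproduces the printed three-day analysis", {
  log <- table_log_fixture()
  findings <- detect_patterns(log, c(70, 140))
  expect_length(findings, 1)
  f <- findings[[1]]
  expect_identical(f$slot, "before_breakfast")
  expect_identical(f$direction, "high")
  expect_identical(f$affected_dose, "bedtime_basal")
  expect_gte(f$adjustment_fraction, 0.10)
  # the single before-dinner excursion does not trigger
  expect_false("before_dinner" %in%
                 vapply(findings, `[[`, "", "slot"))
  # all-in-range log yields nothing
  quiet <- glucose_log(rep(as.Date("2024-01-01") + 0:2, each = 4),
                       rep(c("before_breakfast", "before_lunch",
                             "before_dinner", "before_bedtime"), 3),
                       rep(100, 12))
  expect_length(detect_patterns(quiet, c(70, 140)), 0)
  # fewer than three consecutive days is an error
  gappy <- glucose_log(as.Date(c("2024-01-01", "2024-01-02",
                                 "2024-01-04")),
                       rep("before_breakfast", 3), c(300, 300, 300))
  expect_error(detect_patterns(gappy, c(70, 140)), "consecutive")
})

test_that("pattern detection equals a brute-force window scan", {
  set.seed(34)
  for (i in 1:400) {
    log <- random_log()
    got <- detect_patterns(log, c(70, 140))
    want <- brute_patterns(log, c(70, 140))
    expect_setequal(vapply(got, finding_key, ""),
                    vapply(want, finding_key, ""))
  }
})

test_that("dose titration scales only the affected doses", {
  p <- make_profile(age = 30L, weight = 50 / 0.6,
                    regimen_preference = "IIT")
  regimen <- build_insulin_plan(p, kb_default)
  f <- list(slot = "before_breakfast", direction = "high",
            affected_dose = "bedtime_basal", adjustment_fraction = 0.10,
            window = as.Date("2024-01-01") + 0:2)
  adj <- adjust_doses(regimen, list(f))
  expect_equal(adj$doses[[1]]$units, 25 * 1.10)
  for (i in 2:4)
    expect_equal(adj$doses[[i]]$units, regimen$doses[[i]]$units)
  expect_equal(adj$tdd, sum(vapply(adj$doses, `[[`, 0, "units")))
  # identity with no findings; fraction range enforced
  expect_equal(adjust_doses(regimen, list())$tdd, regimen$tdd)
  bad <- f; bad$adjustment_fraction <- 0.25
  expect_error(adjust_doses(regimen, list(bad)), "0.10, 0.20")
  # low direction decreases the matching bolus dose
  g <- list(slot = "before_lunch", direction = "low",
            affected_dose = "before_breakfast_bolus",
            adjustment_fraction = 0.15, window = f$window)
  adj2 <- adjust_doses(regimen, list(g))
  expect_equal(adj2$doses[[2]]$units, regimen$doses[[2]]$units * 0.85)
  # disjoint findings commute
  ab <- adjust_doses(adjust_doses(regimen, list(f)), list(g))
  ba <- adjust_doses(adjust_doses(regimen, list(g)), list(f))
  expect_equal(vapply(ab$doses, `[[`, 0, "units"),
               vapply(ba$doses, `[[`, 0, "units"))
  # fixed regimens are not titrated this way
  fixed <- build_insulin_plan(make_profile(
    age = 30L, regimen_preference = "fixed_twice"), kb_default)
  expect_error(adjust_doses(fixed, list(f)), "IIT")
})
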