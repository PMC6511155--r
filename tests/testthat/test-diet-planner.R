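test_that("Harris-Benedict BMR matches the published coefficient sets", {
  expect_equal(compute_bmr("female", 60, 165, 30), 1393.85)
  expect_equal(compute_bmr("male", 70, 175, 40),
               13.75 * 70 + 5.003 * 175 - 6.755 * 40 + 66.5)  # 1634.325
  expect_equal(compute_bmr("male", 154, 69, 40, "imperial"),
               6.2 * 154 + 12.7 * 69 - 6.76 * 40 + 66)        # 1626.7
  expect_equal(compute_bmr("female", 132, 65, 30, "imperial"),
               4.35 * 132 + 4.7 * 65 - 4.7 * 30 + 655.1)
  expect_error(compute_bmr("male", 0, 175, 40), "positive")
})

test_that("BMR is monotone in weight and height, decreasing in age", {
  for (sex in c("male", "female")) {
    for (us in c("metric", "imperial")) {
      b0 <- compute_bmr(sex, 70, 170, 40, us)
      expect_gt(compute_bmr(sex, 75, 170, 40, us), b0)
      expect_gt(compute_bmr(sex, 70, 180, 40, us), b0)
      expect_lt(compute_bmr(sex, 70, 170, 50, us), b0)
    }
  }
})

test_that("metric and imperial BMR agree to within about 2 percent", {
  set.seed(12)
  for (i in 1:30) {
    wkg <- runif(1, 45, 120); hcm <- runif(1, 145, 195)
    age <- sample(18:70, 1); sex <- sample(c("male", "female"), 1)
    m <- compute_bmr(sex, wkg, hcm, age, "metric")
    i2 <- compute_bmr(sex, wkg * 2.20462, hcm / 2.54, age, "imperial")
    expect_lt(abs(m - i2) / m, 0.02)
  }
})

test_that("activity multipliers and maintenance calories follow the table", {
  expect_equal(activity_multiplier("sedentary"), 1.2)
  expect_equal(activity_multiplier("lightly_active"), 1.375)
  expect_equal(activity_multiplier("moderately_active"), 1.55)
  expect_equal(activity_multiplier("very_active"), 1.725)
  expect_equal(activity_multiplier("extra_active"), 1.9)
  expect_equal(maintenance_calories(1500, 1.2), 1800)
  expect_equal(maintenance_calories(1393.85, 1.55), 2160.4675)
  expect_equal(maintenance_calories(1700, 1), 1700)
})

test_that("ideal weight range comes from the healthy BMI band", {
  expect_equal(ideal_weight_range(1.70),
               c(liw = 18.5 * 1.7^2, hiw = 25 * 1.7^2))
  expect_equal(ideal_weight_range(1.00), c(liw = 18.5, hiw = 25))
  expect_equal(bmi(25 * 1.7^2, 1.70), 25)  # boundary consistency
  expect_error(ideal_weight_range(0), "positive")
})

test_that("calorie planning handles the three weight branches", {
  iw <- ideal_weight_range(1.70)
  norm <- plan_calories(65, iw[["liw"]], iw[["hiw"]], 2000, 90)
  expect_identical(norm$weight_status, "normal")
  expect_equal(norm$weight_goal, 65)
  expect_equal(norm$cpd, 2000)
  under <- plan_calories(50, 53.465, 72.25, 2000, 90)
  expect_identical(under$weight_status, "underweight")
  expect_gte(under$weight_goal, 53.465)
  expect_equal(under$cpd, 2000 + 3.465 * 7700 / 90)
  over <- plan_calories(80, 53.465, 72.25, 2200, 90)
  expect_identical(over$weight_status, "overweight")
  expect_lte(over$weight_goal, 80 - (80 - 72.25))
  expect_equal(over$cpd, 2200 - 7.75 * 7700 / 90)
  expect_error(plan_calories(120, 53.465, 72.25, 1500, 30),
               "period too short")
})

test_that("calorie planning is continuous at the range boundaries", {
  for (eps in c(1e-3, 1e-6)) {
    lo <- plan_calories(53.465 - eps, 53.465, 72.25, 2000, 90)$cpd
    hi <- plan_calories(72.25 + eps, 53.465, 72.25, 2000, 90)$cpd
    expect_equal(lo, 2000, tolerance = 1e-2)
    expect_equal(hi, 2000, tolerance = 1e-2)
  }
})

test_that("meal distribution preserves carbs and shares", {
  meals <- distribute_meals(2000)
  expect_equal(vapply(meals, `[[`, 0, "carbs_g"), c(150, 175, 175))
  meals2 <- distribute_meals(400)
  expect_equal(vapply(meals2, `[[`, 0, "carbs_g"), c(30, 35, 35))
  set.seed(13)
  for (cpd in runif(30, 200, 4000)) {
    m <- distribute_meals(cpd)
    expect_equal(sum(vapply(m, `[[`, 0, "share")), 1)
    expect_equal(sum(vapply(m, `[[`, 0, "carbs_g")), cpd / 4,
                 tolerance = 1e-9)
    expect_equal(sum(vapply(m, `[[`, 0, "calories")), cpd,
                 tolerance = 1e-9)
  }
})

test_that("forbidden foods union over medications and conditions", {
  p <- make_profile(medications = list(sct("statins")))
  expect_identical(forbidden_foods(p, kb_default), "grapefruit")
  expect_length(forbidden_foods(make_profile(), kb_default), 0)
  # shared foods listed once
  kb2 <- load_knowledge_base(list(drug_food_contra = list(
    a = list("grapefruit"), b = list("grapefruit"))))
  p2 <- make_profile(medications = list(sct("a"), sct("b")))
  expect_identical(forbidden_foods(p2, kb2), "grapefruit")
})

test_that("the assembled diet plan satisfies its invariants", {
  set.seed(14)
  for (i in 1:15) {
    p <- make_profile(age = sample(19:60, 1),
                      weight = runif(1, 45, 110),
                      height = runif(1, 150, 195),
                      lifestyle = sample(c("sedentary", "lightly_active",
                                           "moderately_active"), 1))
    dp <- build_diet_plan(p, kb_default, d = 365L)
    expect_equal(sum(vapply(dp$meals, `[[`, 0, "share")), 1)
    expect_equal(sum(vapply(dp$meals, `[[`, 0, "carbs_g")),
                 dp$calories_per_day / 4, tolerance = 1e-9)
    expect_lt(dp$ideal_weight_low, dp$ideal_weight_high)
    expect_gt(dp$calories_per_day, 0)
    if (dp$weight_status == "underweight")
      expect_gte(dp$weight_goal, dp$ideal_weight_low)
  }
  expect_error(build_diet_plan(make_profile(weight = 160), kb_default,
                               d = 2L),
               "period too short")
})
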