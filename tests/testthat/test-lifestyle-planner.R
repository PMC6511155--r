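test_that("exercise eligibility gates on conditions and pregnancy", {
  preg_thin <- make_profile(age = 28L, pregnant = TRUE, weight = 33,
                            height = 170)  # BMI ~11.4
  e <- exercise_eligibility(preg_thin, kb_default)
  expect_false(e$allowed)
  expect_match(paste(e$reasons, collapse = " "), "underweight")
  preg_pe <- make_profile(age = 28L, pregnant = TRUE,
                          conditions = list(sct("preeclampsia")))
  expect_false(exercise_eligibility(preg_pe, kb_default)$allowed)
  healthy <- make_profile(age = 25L)
  expect_true(exercise_eligibility(healthy, kb_default)$allowed)
  expect_length(exercise_eligibility(healthy, kb_default)$reasons, 0)
  # a listed condition alone is enough; age > 30 alone is not
  expect_false(exercise_eligibility(
    make_profile(age = 25L, conditions = list(sct("nephropathy"))),
    kb_default)$allowed)
  expect_true(exercise_eligibility(make_profile(age = 45L),
                                   kb_default)$allowed)
})

test_that("disease-exercise contradictions follow the knowledge base", {
  expect_identical(forbidden_exercises(
    make_profile(conditions = list(sct("foot_ulcers"))), kb_default),
    "jogging")
  expect_identical(forbidden_exercises(
    make_profile(conditions = list(sct("cataracts"))), kb_default),
    "cycling")
  expect_setequal(forbidden_exercises(
    make_profile(conditions = list(
      sct("severe_nonproliferative_retinopathy"))), kb_default),
    c("jumping", "jarring", "breath_holding"))
})

test_that("recommended exercises are preferences minus forbidden", {
  p <- make_profile(exercise_preferences = list(
    coding("COMPENDIUM", "jogging"), coding("COMPENDIUM", "swimming")))
  expect_identical(recommended_exercises(p, "jogging", kb_default),
                   "swimming")
  # no preferences: knowledge-base defaults minus forbidden
  p0 <- make_profile()
  expect_setequal(recommended_exercises(p0, character(), kb_default),
                  unlist(kb_default$exercise_defaults))
  expect_warning(
    out <- recommended_exercises(p, c("jogging", "swimming"), kb_default),
    "forbidden")
  expect_length(out, 0)
})

test_that("the exercise plan never contains a forbidden component", {
  condition_pool <- c("foot_ulcers", "cataracts",
                      "severe_nonproliferative_retinopathy")
  exercise_pool <- c("walking", "jogging", "cycling", "swimming",
                     "jumping", "yoga")
  set.seed(21)
  for (i in 1:30) {
    p <- make_profile(
      age = sample(19:55, 1),
      conditions = lapply(sample(condition_pool, sample(0:2, 1)), sct),
      exercise_preferences = lapply(
        sample(exercise_pool, sample(0:4, 1)),
        function(x) coding("COMPENDIUM", x)))
    plan <- build_exercise_plan(p, kb_default)
    codes <- vapply(plan$components, function(c) c$exercise$code, "")
    expect_length(intersect(codes, plan$forbidden_exercises), 0)
    if (!plan$allowed) expect_length(plan$components, 0)
  }
  # ineligible patients get an empty plan
  sick <- make_profile(conditions = list(sct("hypertension")))
  plan <- build_exercise_plan(sick, kb_default)
  expect_false(plan$allowed)
  expect_length(plan$components, 0)
  # components carry catalog MET values
  one <- build_exercise_plan(make_profile(exercise_preferences = list(
    coding("COMPENDIUM", "swimming"))), kb_default)
  expect_length(one$components, 1)
  expect_equal(one$components[[1]]$met,
               kb_default$exercise_catalog$swimming$met)
  # fixed regimens freeze the activity level
  expect_true(build_exercise_plan(make_profile(), kb_default,
                                  "fixed_twice")$fixed_activity_level)
  expect_false(build_exercise_plan(make_profile(), kb_default,
                                   "IIT")$fixed_activity_level)
})

test_that("learning styles follow the age/education rule table", {
  expect_setequal(select_learning_style("adult", "high", kb_default),
                  c("visual", "reading"))
  expect_setequal(select_learning_style("child", "medium", kb_default),
                  c("games", "visual"))
  expect_setequal(select_learning_style("oldAdult", "low", kb_default),
                  c("auditory", "visual"))
})

test_that("education topics track regimen, complications and history", {
  p <- make_profile()
  expect_true(all(c("monitoring", "insulin", "diet") %in%
                    select_topics(p, "IIT")))
  pc <- make_profile(conditions = list(sct("nephropathy")))
  expect_true("complications" %in% select_topics(pc, "IIT"))
  ph <- make_profile(history_of_hypoglycemia = 1L)
  expect_true("emergency" %in% select_topics(ph, "IIT"))
  expect_true("exercise" %in% select_topics(p, "IIT",
                                            exercise_active = TRUE))
  expect_false("exercise" %in% select_topics(p, "IIT"))
})

test_that("course assignment is deterministic with deduplication", {
  out <- assign_courses("insulin", "reading", kb_default)
  expect_identical(out,
                   unlist(kb_default$course_catalog$insulin$reading))
  expect_identical(assign_courses(character(), "reading", kb_default),
                   character())
  a <- assign_courses(c("insulin", "diet"), c("reading", "visual"),
                      kb_default)
  expect_identical(a, assign_courses(c("insulin", "diet"),
                                     c("reading", "visual"), kb_default))
  expect_false(anyDuplicated(a) > 0)
  expect_warning(assign_courses("exercise", "games", kb_default),
                 "no courses")
})

test_that("education coordinator falls to a relative for child/oldAdult", {
  child <- make_profile(age = 8L, has_relative = TRUE)
  expect_identical(build_education_plan(child, "IIT",
                                        kb_default)$coordinator,
                   "relative")
  adult <- make_profile(age = 30L, has_relative = TRUE)
  expect_identical(build_education_plan(adult, "IIT",
                                        kb_default)$coordinator,
                   "patient")
  lone_child <- make_profile(age = 8L, has_relative = FALSE)
  expect_identical(build_education_plan(lone_child, "IIT",
                                        kb_default)$coordinator,
                   "patient")
  # every course maps to a selected (topic, style) pair
  ep <- build_education_plan(make_profile(education_level = "high"),
                             "IIT", kb_default)
  all_pairs <- unlist(lapply(ep$topics, function(tp)
    lapply(ep$styles, function(st)
      kb_default$course_catalog[[tp]][[st]])))
  expect_true(all(ep$courses %in% all_pairs))
})
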