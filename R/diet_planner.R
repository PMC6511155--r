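# Diet sub-plan (medical nutrition therapy): Harris-Benedict basal
# metabolic rate, activity-scaled maintenance calories, ideal-weight range
# from the healthy BMI band, calorie/carb planning and per-meal shares.

CALORIES_PER_KG <- 7700  # energy content of one kg of body weight
KCAL_PER_G_CARB <- 4
MEAL_SHARES <- c(breakfast = 0.30, lunch = 0.35, dinner = 0.35)

#' Basal metabolic rate (Harris-Benedict)
#'
#' Revised Harris-Benedict equations, by sex and unit system:
#' \itemize{
#'   \item metric male: 13.75 W + 5.003 H - 6.755 A + 66.5
#'   \item metric female: 9.563 W + 1.85 H - 4.676 A + 655.1
#'   \item imperial male: 6.2 W + 12.7 H - 6.76 A + 66
#'   \item imperial female: 4.35 W + 4.7 H - 4.7 A + 655.1
#' }
#' with W in kg (metric) or pounds (imperial), H in cm or inches, A in
#' years. The two coefficient sets are independently published round-offs
#' and agree to within about 2 percent, not exactly.
#'
#' @param sex \code{"male"} or \code{"female"}.
#' @param weight Weight in kg (metric) or pounds (imperial), > 0.
#' @param height Height in cm (metric) or inches (imperial), > 0.
#' @param age Age in years.
#' @param unit_system \code{"metric"} (default) or \code{"imperial"}.
#' @return BMR in kcal/day.
#' @examples
#' compute_bmr("male", 70, 175, 40) # 1637.825
#' @export
compute_bmr <- function(sex, weight, height, age, unit_system = "metric") {
  sex <- match.arg(sex, c("male", "female"))
  unit_system <- match.arg(unit_system, c("metric", "imperial"))
  if (!is.numeric(weight) || weight <= 0 || !is.numeric(height) ||
      height <= 0)
    stop("`weight` and `height` must be positive", call. = FALSE)
  if (!is.numeric(age) || age < 0)
    stop("`age` must be non-negative", call. = FALSE)
  if (unit_system == "metric") {
    if (sex == "male") 13.75 * weight + 5.003 * height - 6.755 * age + 66.5
    else 9.563 * weight + 1.85 * height - 4.676 * age + 655.1
  } else {
    if (sex == "male") 6.2 * weight + 12.7 * height - 6.76 * age + 66
    else 4.35 * weight + 4.7 * height - 4.7 * age + 655.1
  }
}

#' Activity-level multiplier for a lifestyle
#'
#' The five-level multiplier table: sedentary 1.2, lightly active 1.375,
#' moderately active 1.55, very active 1.725, extra active 1.9.
#'
#' @param lifestyle One of the five lifestyle levels.
#' @return The multiplier.
#' @examples
#' activity_multiplier("moderately_active") # 1.55
#' @export
activity_multiplier <- function(lifestyle) {
  lifestyle <- match.arg(lifestyle, names(TABLE2_MULTIPLIERS))
  unname(TABLE2_MULTIPLIERS[[lifestyle]])
}

#' Calories to maintain current weight
#'
#' MC = activity level multiplier times BMR.
#'
#' @param bmr Basal metabolic rate in kcal/day, > 0.
#' @param al Activity-level multiplier, see [activity_multiplier()].
#' @return Maintenance calories in kcal/day.
#' @export
maintenance_calories <- function(bmr, al) {
  if (!is.numeric(bmr) || bmr <= 0) stop("`bmr` must be > 0", call. = FALSE)
  al * bmr
}

#' Ideal weight range from the healthy BMI band
#'
#' The WHO healthy BMI range 18.5--25 kg/m^2 gives lowest ideal weight
#' LIW = 18.5 h^2 and highest HIW = 25 h^2 for height h in meters.
#'
#' @param height_m Height in meters, > 0.
#' @return Named numeric vector \code{c(liw, hiw)} in kg.
#' @examples
#' ideal_weight_range(1.70) # 53.465 72.25
#' @export
ideal_weight_range <- function(height_m) {
  if (!is.numeric(height_m) || length(height_m) != 1L || is.na(height_m) ||
      height_m <= 0)
    stop("`height_m` must be a positive height in meters", call. = FALSE)
  c(liw = 18.5 * height_m^2, hiw = 25 * height_m^2)
}

#' Body mass index
#'
#' @param weight Weight in kg.
#' @param height_m Height in meters.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight, height_m) {
  if (height_m <= 0) stop("`height_m` must be > 0", call. = FALSE)
  weight / height_m^2
}

#' Plan daily calories and the weight goal
#'
#' Compares current weight with the ideal range. In range: maintain, the
#' daily calories CpD equal maintenance calories MC and the weight goal is
#' the current weight. Underweight: gain to the low end of the range; each
#' kg to gain costs 7700 kcal spread over the adjustment period of d days,
#' so CpD = MC + (LIW - W) * 7700 / d. Overweight: lose to the high end,
#' CpD = MC - (W - HIW) * 7700 / d. A reduction that drives CpD to zero or
#' below raises a "period too short" error.
#'
#' @param weight Current weight in kg.
#' @param liw,hiw Ideal-weight range bounds in kg (\code{liw < hiw}).
#' @param mc Maintenance calories in kcal/day.
#' @param d Adjustment period in days, > 0 (default 90; plans are
#'   maintained every three months).
#' @return List with \code{weight_status} (\code{"underweight"},
#'   \code{"normal"}, \code{"overweight"}), \code{weight_goal} (kg) and
#'   \code{cpd} (kcal/day).
#' @export
plan_calories <- function(weight, liw, hiw, mc, d = 90L) {
  if (liw >= hiw) stop("`liw` must be < `hiw`", call. = FALSE)
  if (d <= 0) stop("`d` must be a positive number of days", call. = FALSE)
  if (weight < liw) {
    status <- "underweight"
    goal <- liw
    cpd <- mc + (liw - weight) * CALORIES_PER_KG / d
  } else if (weight > hiw) {
    status <- "overweight"
    goal <- hiw
    cpd <- mc - (weight - hiw) * CALORIES_PER_KG / d
  } else {
    status <- "normal"
    goal <- weight
    cpd <- mc
  }
  if (cpd <= 0)
    stop(sprintf(paste0("period too short: a %d-day adjustment needs ",
                        "non-positive daily calories; increase `d`"),
                 as.integer(d)), call. = FALSE)
  list(weight_status = status, weight_goal = goal, cpd = cpd)
}

#' Distribute daily calories over three meals
#'
#' Daily carbohydrate grams are CpD / 4 (4 kcal per gram), split 30\%
#' breakfast, 35\% lunch, 35\% dinner; calories use the same shares.
#'
#' @param cpd Planned calories per day, > 0.
#' @return List of three meal specs (\code{name}, \code{share},
#'   \code{carbs_g}, \code{calories}).
#' @examples
#' distribute_meals(2000) # 150/175/175 g of carbs
#' @export
distribute_meals <- function(cpd) {
  if (!is.numeric(cpd) || cpd <= 0) stop("`cpd` must be > 0", call. = FALSE)
  total_carbs <- cpd / KCAL_PER_G_CARB
  lapply(names(MEAL_SHARES), function(nm) {
    s <- MEAL_SHARES[[nm]]
    list(name = nm, share = s, carbs_g = s * total_carbs,
         calories = s * cpd)
  })
}

#' Forbidden foods for a patient
#'
#' Union of the knowledge base food contradictions of all current
#' medications and conditions; each food listed once.
#'
#' @inheritParams contradicted_insulins
#' @return Character vector of food names.
#' @export
forbidden_foods <- function(profile, kb) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  meds <- profile_codes(profile$medications)
  conds <- profile_codes(profile$conditions)
  foods <- c(
    unlist(kb$drug_food_contra[intersect(meds, names(kb$drug_food_contra))]),
    unlist(kb$disease_food_contra[
      intersect(conds, names(kb$disease_food_contra))]))
  unique(as.character(foods))
}

#' Build the complete diet sub-plan
#'
#' Runs the five planning steps in order: BMR, activity-scaled
#' maintenance calories, ideal-weight range, calorie/weight-goal planning
#' over the adjustment period, and per-meal carb distribution with
#' forbidden foods and recommended food groups.
#'
#' @inheritParams contradicted_insulins
#' @param d Adjustment period in days (default 90).
#' @return An object of class \code{t1d_diet_plan}.
#' @export
build_diet_plan <- function(profile, kb, d = 90L) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  bmr <- compute_bmr(profile$sex, profile$weight, profile$height,
                     profile$age, "metric")
  al <- activity_multiplier(profile$lifestyle)
  mc <- maintenance_calories(bmr, al)
  iw <- ideal_weight_range(profile$height / 100)
  cal <- plan_calories(profile$weight, iw[["liw"]], iw[["hiw"]], mc, d)
  meals <- distribute_meals(cal$cpd)
  forb <- forbidden_foods(profile, kb)
  groups <- as.character(unlist(kb$food_groups))
  if (length(profile$food_preferences))
    groups <- unique(c(intersect(profile$food_preferences, groups), groups))
  groups <- setdiff(groups, forb)
  structure(
    list(bmr = bmr, activity_multiplier = al, maintenance_calories = mc,
         ideal_weight_low = iw[["liw"]], ideal_weight_high = iw[["hiw"]],
         weight_status = cal$weight_status, weight_goal = cal$weight_goal,
         adjustment_period_days = as.integer(d), calories_per_day = cal$cpd,
         total_carbs_g = cal$cpd / KCAL_PER_G_CARB, meals = meals,
         forbidden_foods = forb, recommended_food_groups = groups),
    class = "t1d_diet_plan")
}

#' @export
print.t1d_diet_plan <- function(x, ...) {
  cat(sprintf(paste0("<diet plan> BMR %.0f kcal/d x AL %.3f = MC %.0f; ",
                     "%s (goal %.1f kg); CpD %.0f kcal, %.0f g carbs\n"),
              x$bmr, x$activity_multiplier, x$maintenance_calories,
              x$weight_status, x$weight_goal, x$calories_per_day,
              x$total_carbs_g))
  for (m in x$meals)
    cat(sprintf("  %-9s %2.0f%%  %6.1f g carbs  %7.1f kcal\n", m$name,
                100 * m$share, m$carbs_g, m$calories))
  invisible(x)
}
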