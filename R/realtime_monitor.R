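# Real-time advice for basal-bolus (IIT) patients: insulin sensitivity
# factor and insulin-to-carb ratio, mealtime bolus correction with and
# without exercise, exercise safety gating, and multi-day glucose pattern
# management with dose titration.

PATTERN_SLOTS <- c("before_breakfast", "before_lunch", "before_dinner",
                   "before_bedtime")

# Which planned dose a persistent out-of-goal slot adjusts.
PATTERN_DOSE_MAP <- c(before_lunch = "before_breakfast_bolus",
                      before_dinner = "before_lunch_bolus",
                      before_bedtime = "before_dinner_bolus",
                      before_breakfast = "bedtime_basal")

#' Insulin sensitivity factor (1800/100 rule)
#'
#' ISF is the glucose drop produced by one unit of bolus insulin:
#' 1800/TDD when glucose is measured in mg/dL, 100/TDD in mmol/L.
#'
#' @param tdd Total daily dose in insulin units, > 0.
#' @param unit Glucose unit, \code{"mg/dL"} or \code{"mmol/L"}.
#' @return ISF in (unit) per insulin unit.
#' @examples
#' compute_isf(50) # 36 mg/dL/U
#' @export
compute_isf <- function(tdd, unit = "mg/dL") {
  if (!is.numeric(tdd) || length(tdd) != 1L || is.na(tdd) || tdd <= 0)
    stop("`tdd` must be a positive number of units", call. = FALSE)
  check_glucose_unit(unit)
  if (unit == "mg/dL") 1800 / tdd else 100 / tdd
}

#' Insulin-to-carb ratio (500/300 rule)
#'
#' ICR is the grams of carbohydrate covered by one unit of bolus insulin:
#' 500/TDD, or 300/TDD for small total daily doses (TDD below 10 U,
#' typically children).
#'
#' @param tdd Total daily dose in insulin units, > 0.
#' @return ICR in carb grams per insulin unit.
#' @examples
#' compute_icr(50) # 10
#' compute_icr(8)  # 37.5 (300 rule)
#' @export
compute_icr <- function(tdd) {
  if (!is.numeric(tdd) || length(tdd) != 1L || is.na(tdd) || tdd <= 0)
    stop("`tdd` must be a positive number of units", call. = FALSE)
  if (tdd < 10) 300 / tdd else 500 / tdd
}

#' Correction band for a pre-meal glucose reading
#'
#' Whole-unit dose delta relative to the planned bolus, generalized from
#' the printed band table for goal 100--150 mg/dL by anchoring the 50
#' mg/dL bands at the goal's upper bound: below 70 mg/dL is -1, inside the
#' goal is 0 (planned dose / carb counting), then +1 per 50 mg/dL band
#' above the upper bound, capped at +4. Readings between 70 mg/dL and the
#' goal's lower bound fall back to the in-goal behavior (0).
#'
#' @param cbg Current glucose [quantity()] (or mg/dL number).
#' @param goal Numeric \code{c(low, high)} in the same unit as \code{cbg}.
#' @return Integer dose delta in insulin units, -1..+4.
#' @examples
#' correction_band(quantity(220, "mg/dL"), c(100, 150)) # +2
#' @export
correction_band <- function(cbg, goal) {
  cbg <- as_quantity(cbg)
  check_glucose_unit(cbg$unit)
  if (length(goal) != 2L || goal[1] >= goal[2])
    stop("`goal` must be c(low, high) with low < high", call. = FALSE)
  v <- glucose_in(cbg, "mg/dL")
  goal_mgdl <- if (cbg$unit == "mg/dL") goal
               else goal * GLUCOSE_MGDL_PER_MMOL
  if (v < 70) return(-1L)
  if (v <= goal_mgdl[2]) return(0L)
  min(4L, as.integer(ceiling((v - goal_mgdl[2]) / 50)))
}

round_half_unit <- function(x) round(x * 2) / 2

bolus_advice <- function(dbg, n1, n2, exercise_offset, icr,
                         exercise_permitted = TRUE) {
  bd <- n1 + n2 - exercise_offset
  action <- if (bd > 0) "inject" else if (bd < 0) "eat_carbs" else "skip"
  structure(
    list(dbg = dbg, n1 = n1, n2 = n2, exercise_offset = exercise_offset,
         bd = bd, bd_rounded = round_half_unit(bd), action = action,
         carbs_to_eat_g = if (bd < 0) -bd * icr else NA_real_,
         exercise_permitted = exercise_permitted),
    class = "t1d_bolus_advice")
}

#' @export
print.t1d_bolus_advice <- function(x, ...) {
  cat(sprintf(
    "<bolus advice> DBG %.1f | N1 %.2f U | N2 %.2f U%s | BD %.2f U -> %s\n",
    x$dbg, x$n1, x$n2,
    if (x$exercise_offset != 0)
      sprintf(" | exercise -%.2f U", x$exercise_offset) else "",
    x$bd,
    switch(x$action,
           inject = sprintf("inject %.1f U", x$bd_rounded),
           skip = "skip this bolus",
           eat_carbs = sprintf("eat %.0f g of carbs", x$carbs_to_eat_g))))
  invisible(x)
}

#' Real-time mealtime bolus advice
#'
#' Computes the glucose difference DBG = CBG - PBG, the correction units
#' N1 = DBG / ISF, the carb-cover units N2 = MC / ICR, and the bolus dose
#' BD = N1 + N2. Positive BD: inject BD units (reported rounded to the
#' nearest 0.5 U, exact value retained); zero: skip the bolus; negative:
#' eat extra carbohydrate, quantified as (-BD) * ICR grams (the carb mass
#' the insulin deficit covers).
#'
#' @param cbg Current glucose [quantity()] or mg/dL number.
#' @param goal_pbg Pre-meal goal glucose, same unit as \code{cbg}.
#' @param meal_carbs_g Planned meal carbohydrate in grams (0 for no meal).
#' @param tdd Total daily insulin dose in units.
#' @return A \code{t1d_bolus_advice} with the intermediates \code{dbg},
#'   \code{n1}, \code{n2}, exact \code{bd} and \code{bd_rounded}.
#' @examples
#' advise_bolus(quantity(210, "mg/dL"), quantity(120, "mg/dL"), 60, 50)
#' @export
advise_bolus <- function(cbg, goal_pbg, meal_carbs_g, tdd) {
  cbg <- as_quantity(cbg)
  goal_pbg <- as_quantity(goal_pbg, cbg$unit)
  if (!identical(cbg$unit, goal_pbg$unit))
    stop("`cbg` and `goal_pbg` must share a unit", call. = FALSE)
  check_glucose_unit(cbg$unit)
  if (meal_carbs_g < 0) stop("`meal_carbs_g` must be >= 0", call. = FALSE)
  isf <- compute_isf(tdd, cbg$unit)
  icr <- compute_icr(tdd)
  dbg <- cbg$value - goal_pbg$value
  n1 <- dbg / isf
  n2 <- meal_carbs_g / icr
  bolus_advice(dbg, n1, n2, 0, icr)
}

#' Calories burned by an activity
#'
#' BC = MET x weight (kg) x duration (h), with MET taken from the
#' physical-activity compendium catalog.
#'
#' @param met Metabolic equivalent of task.
#' @param weight Body weight in kg.
#' @param duration_h Duration in hours.
#' @return Burned calories in kcal.
#' @examples
#' burned_calories(8, 70, 0.5) # 280
#' @export
burned_calories <- function(met, weight, duration_h) {
  if (met < 0 || weight < 0 || duration_h < 0)
    stop("`met`, `weight` and `duration_h` must be non-negative",
         call. = FALSE)
  met * weight * duration_h
}

#' Is exercising currently safe?
#'
#' Exercise is forbidden when current glucose exceeds 250 mg/dL, is below
#' 80 mg/dL (equivalents for mmol/L input), or the patient has diabetic
#' ketoacidosis.
#'
#' @param cbg Current glucose [quantity()] or mg/dL number.
#' @param has_dka Logical.
#' @return \code{TRUE} when exercise is permitted.
#' @export
exercise_permitted <- function(cbg, has_dka = FALSE) {
  v <- glucose_in(as_quantity(cbg), "mg/dL")
  !(v > 250 || v < 80 || isTRUE(has_dka))
}

#' Bolus advice when exercise follows the meal
#'
#' For exercise within three hours after the meal, the bolus is reduced by
#' the insulin equivalent of the energy burned: BD = N1 + N2 - (BC/4)/ICR,
#' where BC/4 converts burned calories into carb grams. When exercise is
#' not permitted ([exercise_permitted()] is false), no offset is applied
#' and the advice flags \code{exercise_permitted = FALSE}.
#'
#' @inheritParams advise_bolus
#' @param met,weight,duration_h Exercise MET, body weight (kg), duration
#'   (hours), see [burned_calories()].
#' @param has_dka Logical, current diabetic ketoacidosis.
#' @return A \code{t1d_bolus_advice}.
#' @export
advise_bolus_with_exercise <- function(cbg, goal_pbg, meal_carbs_g, tdd,
                                       met, weight, duration_h,
                                       has_dka = FALSE) {
  base <- advise_bolus(cbg, goal_pbg, meal_carbs_g, tdd)
  permitted <- exercise_permitted(as_quantity(cbg), has_dka)
  if (!permitted) {
    base$exercise_permitted <- FALSE
    return(base)
  }
  icr <- compute_icr(tdd)
  bc <- burned_calories(met, weight, duration_h)
  offset <- (bc / 4) / icr
  bolus_advice(base$dbg, base$n1, base$n2, offset, icr)
}

#' Advice for exercise away from meals
#'
#' When exercise is not within three hours of a meal, the advice depends
#' on weight status. Underweight or normal-weight patients are told to eat
#' the equivalent carb grams (BC/4) while the corresponding insulin units
#' (BC/4)/ICR are added to the correction dose N1, as the encoded
#' guideline prescribes. Overweight or obese patients get the insulin
#' equivalent subtracted from N1 and no extra carbs.
#'
#' @inheritParams advise_bolus_with_exercise
#' @param weight_status \code{"underweight"}, \code{"normal"} or
#'   \code{"overweight"}.
#' @return A \code{t1d_bolus_advice}; for underweight/normal patients
#'   \code{carbs_to_eat_g} carries BC/4 regardless of the dose sign.
#' @export
advise_exercise_only <- function(cbg, goal_pbg, tdd, met, weight,
                                 duration_h, weight_status,
                                 has_dka = FALSE) {
  weight_status <- match.arg(weight_status,
                             c("underweight", "normal", "overweight"))
  cbg <- as_quantity(cbg)
  goal_pbg <- as_quantity(goal_pbg, cbg$unit)
  permitted <- exercise_permitted(cbg, has_dka)
  isf <- compute_isf(tdd, cbg$unit)
  icr <- compute_icr(tdd)
  dbg <- cbg$value - goal_pbg$value
  n1 <- dbg / isf
  if (!permitted) {
    adv <- bolus_advice(dbg, n1, 0, 0, icr, exercise_permitted = FALSE)
    return(adv)
  }
  bc <- burned_calories(met, weight, duration_h)
  carb_equiv <- bc / 4
  units_equiv <- carb_equiv / icr
  if (weight_status == "overweight") {
    adv <- bolus_advice(dbg, n1, 0, units_equiv, icr)
  } else {
    adv <- bolus_advice(dbg, n1 + units_equiv, 0, 0, icr)
    adv$carbs_to_eat_g <- carb_equiv
    if (carb_equiv > 0 && adv$action == "skip") adv$action <- "eat_carbs"
  }
  adv
}

#' Multi-day glucose log
#'
#' Per-day, per-slot glucose readings for pattern management. At most one
#' value per (date, slot); all values share one unit.
#'
#' @param dates Date vector (or coercible), one entry per reading.
#' @param slots Character vector of slots (\code{"before_breakfast"},
#'   \code{"before_lunch"}, \code{"before_dinner"},
#'   \code{"before_bedtime"}).
#' @param values Numeric glucose values.
#' @param unit Shared glucose unit.
#' @return An object of class \code{t1d_glucose_log} (a data frame with
#'   columns \code{date}, \code{slot}, \code{value} and a \code{unit}
#'   attribute).
#' @export
glucose_log <- function(dates, slots, values, unit = "mg/dL") {
  check_glucose_unit(unit)
  dates <- as.Date(dates)
  slots <- as.character(slots)
  if (!all(slots %in% PATTERN_SLOTS))
    stop("`slots` must be before_breakfast/lunch/dinner/bedtime",
         call. = FALSE)
  if (length(dates) != length(slots) || length(slots) != length(values))
    stop("`dates`, `slots`, `values` must have equal length", call. = FALSE)
  if (anyDuplicated(paste(dates, slots)))
    stop("at most one value per (date, slot)", call. = FALSE)
  df <- data.frame(date = dates, slot = slots, value = as.numeric(values),
                   stringsAsFactors = FALSE)
  df <- df[order(df$date, match(df$slot, PATTERN_SLOTS)), ]
  rownames(df) <- NULL
  structure(df, unit = unit, class = c("t1d_glucose_log", "data.frame"))
}

#' Detect persistent out-of-goal glucose patterns
#'
#' Scans every window of three consecutive days; a finding is emitted for
#' a slot when all three same-slot values in a window lie outside the goal
#' range on the same side. Single excursions never trigger. Each finding
#' names the planned dose to titrate: a high/low before-lunch pattern
#' adjusts the before-breakfast bolus, before-dinner adjusts the
#' before-lunch bolus, before-bedtime adjusts the before-dinner bolus, and
#' before-breakfast adjusts the bedtime basal dose. Longer logs are
#' deduplicated per slot, keeping the most recent window.
#'
#' @param log A [glucose_log()].
#' @param goal Numeric \code{c(low, high)} goal range in the log's unit.
#' @param adjustment_fraction Fraction attached to each finding, in
#'   [0.10, 0.20]; default 0.10 (the minimum recommended change).
#' @return List of findings, each with \code{slot}, \code{direction}
#'   (\code{"high"}/\code{"low"}), \code{affected_dose},
#'   \code{adjustment_fraction} and \code{window} (the three dates).
#' @export
detect_patterns <- function(log, goal, adjustment_fraction = 0.10) {
  stopifnot(inherits(log, "t1d_glucose_log"))
  if (length(goal) != 2L || goal[1] >= goal[2])
    stop("`goal` must be c(low, high) with low < high", call. = FALSE)
  if (adjustment_fraction < 0.10 || adjustment_fraction > 0.20)
    stop("`adjustment_fraction` must be in [0.10, 0.20]", call. = FALSE)
  dates <- sort(unique(log$date))
  gaps <- as.numeric(diff(dates))
  runs <- which(gaps == 1 & c(gaps[-1], NA) == 1)
  if (!length(dates) || length(dates) < 3 || !length(runs))
    stop("pattern management needs at least 3 consecutive days of data",
         call. = FALSE)
  findings <- list()
  for (i in runs) {
    window <- dates[i + 0:2]
    for (slot in PATTERN_SLOTS) {
      vals <- log$value[log$date %in% window & log$slot == slot]
      if (length(vals) != 3L) next
      direction <- if (all(vals > goal[2])) "high"
                   else if (all(vals < goal[1])) "low"
                   else NA_character_
      if (is.na(direction)) next
      findings[[slot]] <- list(  # later windows overwrite: most recent kept
        slot = slot, direction = direction,
        affected_dose = unname(PATTERN_DOSE_MAP[[slot]]),
        adjustment_fraction = adjustment_fraction,
        window = window)
    }
  }
  unname(findings)
}

dose_matches <- function(dose, affected) {
  switch(affected,
         bedtime_basal = dose$kind == "basal",
         before_breakfast_bolus =
           dose$kind == "bolus" && dose$timing == "before_breakfast",
         before_lunch_bolus =
           dose$kind == "bolus" && dose$timing == "before_lunch",
         before_dinner_bolus =
           dose$kind == "bolus" && dose$timing == "before_dinner",
         FALSE)
}

#' Titrate planned doses from pattern findings
#'
#' Scales each affected dose by (1 + fraction) for a high pattern or
#' (1 - fraction) for a low pattern; changes must stay between 10\% and
#' 20\% of the planned dose. All other doses are untouched and the
#' regimen's TDD is updated to the new daily total.
#'
#' @param regimen An IIT \code{t1d_insulin_regimen}.
#' @param findings Findings from [detect_patterns()].
#' @return The adjusted regimen.
#' @export
adjust_doses <- function(regimen, findings) {
  stopifnot(inherits(regimen, "t1d_insulin_regimen"))
  if (regimen$kind != "IIT")
    stop("pattern-based titration applies to IIT regimens only",
         call. = FALSE)
  for (f in findings) {
    frac <- f$adjustment_fraction %||% 0.10
    if (frac < 0.10 || frac > 0.20)
      stop("adjustment fraction must be in [0.10, 0.20]", call. = FALSE)
    idx <- which(vapply(regimen$doses, dose_matches, TRUE, f$affected_dose))
    if (!length(idx))
      stop(sprintf("regimen has no dose matching '%s'", f$affected_dose),
           call. = FALSE)
    mult <- if (f$direction == "high") 1 + frac else 1 - frac
    for (i in idx) {
      regimen$doses[[i]]$units <- regimen$doses[[i]]$units * mult
      regimen$doses[[i]]$units_rounded <- round(regimen$doses[[i]]$units)
    }
  }
  regimen$tdd <- regimen_daily_units(regimen)
  regimen
}
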