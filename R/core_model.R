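# Shared domain types (codings, quantities, profiles), unit handling and
# demographic classification used by every planner.

#' @keywords internal
"_PACKAGE"

# mg/dL per mmol/L; molar mass of glucose (180.182 g/mol) divided by 10.
GLUCOSE_MGDL_PER_MMOL <- 18.0182

GLUCOSE_UNITS <- c("mg/dL", "mmol/L")

AGE_CATEGORIES <- c("child", "adolescent", "adult", "oldAdult")
SLOTS <- c("before_breakfast", "before_lunch", "before_dinner",
           "before_bedtime", "other")
LIFESTYLES <- c("sedentary", "lightly_active", "moderately_active",
                "very_active", "extra_active")

#' Terminology coding
#'
#' A minimal coded concept: a terminology system identifier (for example
#' \code{"SNOMEDCT"}, \code{"LOINC"}, \code{"UCUM"}, \code{"COMPENDIUM"}),
#' a code, and an optional human-readable display.
#'
#' @param system Terminology identifier, non-empty string.
#' @param code Code within the system, non-empty string.
#' @param display Optional display text.
#' @return An object of class \code{t1d_coding}.
#' @examples
#' coding("SNOMEDCT", "26298008", "Diabetic coma with ketoacidosis")
#' @export
coding <- function(system, code, display = "") {
  if (!is.character(system) || length(system) != 1L || !nzchar(system))
    stop("`system` must be a non-empty string", call. = FALSE)
  if (length(code) != 1L || is.na(code) || !nzchar(as.character(code)))
    stop("`code` must be a non-empty string", call. = FALSE)
  structure(
    list(system = system, code = as.character(code),
         display = as.character(display)),
    class = "t1d_coding"
  )
}

#' @export
print.t1d_coding <- function(x, ...) {
  cat(sprintf("<coding> %s|%s%s\n", x$system, x$code,
              if (nzchar(x$display)) paste0(" (", x$display, ")") else ""))
  invisible(x)
}

#' @export
format.t1d_coding <- function(x, ...) paste0(x$system, "|", x$code)

#' Measured quantity with a UCUM unit
#'
#' @param value Finite numeric value.
#' @param unit Non-empty UCUM unit code string (e.g. \code{"mg/dL"},
#'   \code{"kg"}).
#' @return An object of class \code{t1d_quantity}.
#' @examples
#' quantity(210, "mg/dL")
#' @export
quantity <- function(value, unit) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("`value` must be a single finite number", call. = FALSE)
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit))
    stop("`unit` must be a non-empty UCUM unit string", call. = FALSE)
  structure(list(value = as.numeric(value), unit = unit),
            class = "t1d_quantity")
}

#' @export
print.t1d_quantity <- function(x, ...) {
  cat(sprintf("<quantity> %g %s\n", x$value, x$unit))
  invisible(x)
}

as_quantity <- function(x, default_unit = "mg/dL") {
  if (inherits(x, "t1d_quantity")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(quantity(x, default_unit))
  stop("expected a quantity or a single number", call. = FALSE)
}

#' Single timestamped observation
#'
#' A sensor, manual, or EHR observation: a coded concept, a quantity,
#' a timestamp, and the mealtime slot it belongs to.
#'
#' @param code A [coding()] identifying the observed property.
#' @param value A [quantity()]. Glucose values must carry unit
#'   \code{"mg/dL"} or \code{"mmol/L"}.
#' @param timestamp A POSIXct/Date or ISO-8601 string.
#' @param slot Mealtime slot, one of \code{"before_breakfast"},
#'   \code{"before_lunch"}, \code{"before_dinner"}, \code{"before_bedtime"},
#'   \code{"other"}.
#' @param source One of \code{"sensor"}, \code{"manual"}, \code{"ehr"}.
#' @return An object of class \code{t1d_observation}.
#' @export
observation_record <- function(code, value, timestamp, slot = "other",
                               source = "sensor") {
  stopifnot(inherits(code, "t1d_coding"), inherits(value, "t1d_quantity"))
  slot <- match.arg(slot, SLOTS)
  source <- match.arg(source, c("sensor", "manual", "ehr"))
  if (missing(timestamp) || is.null(timestamp) ||
      (is.character(timestamp) && !nzchar(timestamp)))
    stop("`timestamp` must be present", call. = FALSE)
  ts <- as.POSIXct(timestamp, tz = "UTC")
  if (is.na(ts)) stop("`timestamp` is not a valid date-time", call. = FALSE)
  if (identical(code$code, "glucose") || grepl("glucose", tolower(code$display)))
    check_glucose_unit(value$unit)
  structure(list(code = code, value = value, timestamp = ts, slot = slot,
                 source = source),
            class = "t1d_observation")
}

check_glucose_unit <- function(unit) {
  if (!unit %in% GLUCOSE_UNITS)
    stop(sprintf("unknown glucose unit '%s' (expected 'mg/dL' or 'mmol/L')",
                 unit), call. = FALSE)
  invisible(unit)
}

#' Patient profile
#'
#' Collects the temporary patient characteristics used to build care plans:
#' demographics, anthropometrics, coded conditions/medications/allergies,
#' and preferences. This is the main input of the decision support engine.
#'
#' @param id Patient identifier string.
#' @param age Age in whole years, 0..130.
#' @param sex \code{"male"} or \code{"female"}.
#' @param weight Body weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @param pregnant Logical; \code{TRUE} requires \code{sex = "female"}.
#' @param lifestyle One of the five activity-level lifestyles
#'   (\code{"sedentary"} .. \code{"extra_active"}).
#' @param education_level \code{"low"}, \code{"medium"} or \code{"high"}.
#' @param preferred_language Language tag, default \code{"en"}.
#' @param conditions,medications,allergies Lists of [coding()] objects.
#' @param food_preferences Character vector of preferred food groups.
#' @param exercise_preferences List of [coding()] exercise codes.
#' @param regimen_preference \code{"IIT"}, \code{"fixed_once"},
#'   \code{"fixed_twice"} or \code{"none"}.
#' @param history_of_hypoglycemia,history_of_hyperglycemia Event counts.
#' @param has_dka Logical, current diabetic ketoacidosis.
#' @param has_relative Logical, a family member is available as education
#'   coordinator.
#' @return An object of class \code{t1d_patient_profile}.
#' @examples
#' patient_profile("p1", age = 30, sex = "female", weight = 65, height = 170)
#' @export
patient_profile <- function(id, age, sex, weight, height,
                            pregnant = FALSE,
                            lifestyle = "sedentary",
                            education_level = "medium",
                            preferred_language = "en",
                            conditions = list(),
                            medications = list(),
                            allergies = list(),
                            food_preferences = character(),
                            exercise_preferences = list(),
                            regimen_preference = "none",
                            history_of_hypoglycemia = 0L,
                            history_of_hyperglycemia = 0L,
                            has_dka = FALSE,
                            has_relative = FALSE) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age) ||
      age < 0 || age > 130 || age != trunc(age))
    stop("`age` must be a whole number in [0, 130]", call. = FALSE)
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(weight) || weight <= 0)
    stop("`weight` must be > 0 kg", call. = FALSE)
  if (!is.numeric(height) || height <= 0)
    stop("`height` must be > 0 cm", call. = FALSE)
  if (isTRUE(pregnant) && sex != "female")
    stop("`pregnant = TRUE` requires `sex = \"female\"`", call. = FALSE)
  lifestyle <- match.arg(lifestyle, LIFESTYLES)
  education_level <- match.arg(education_level, c("low", "medium", "high"))
  regimen_preference <- match.arg(regimen_preference,
                                  c("none", "IIT", "fixed_once", "fixed_twice"))
  for (nm in c("conditions", "medications", "allergies",
               "exercise_preferences")) {
    lst <- get(nm)
    if (!is.list(lst) || !all(vapply(lst, inherits, TRUE, "t1d_coding")))
      stop(sprintf("`%s` must be a list of coding() objects", nm),
           call. = FALSE)
  }
  structure(
    list(id = as.character(id), age = as.integer(age), sex = sex,
         pregnant = isTRUE(pregnant), weight = as.numeric(weight),
         height = as.numeric(height), lifestyle = lifestyle,
         education_level = education_level,
         preferred_language = preferred_language,
         conditions = conditions, medications = medications,
         allergies = allergies,
         food_preferences = as.character(food_preferences),
         exercise_preferences = exercise_preferences,
         regimen_preference = regimen_preference,
         history_of_hypoglycemia = as.integer(history_of_hypoglycemia),
         history_of_hyperglycemia = as.integer(history_of_hyperglycemia),
         has_dka = isTRUE(has_dka), has_relative = isTRUE(has_relative)),
    class = "t1d_patient_profile"
  )
}

#' @export
print.t1d_patient_profile <- function(x, ...) {
  cat(sprintf("<patient profile> %s: %s, %d y, %.1f kg, %.0f cm, %s\n",
              x$id, x$sex, x$age, x$weight, x$height, x$lifestyle))
  cat(sprintf("  conditions: %d | medications: %d | regimen preference: %s%s\n",
              length(x$conditions), length(x$medications),
              x$regimen_preference, if (x$pregnant) " | pregnant" else ""))
  invisible(x)
}

#' Classify age into a demographic category
#'
#' Maps age in years onto one of \code{child}, \code{adolescent},
#' \code{adult}, \code{oldAdult}. The adult band (19--55) follows the
#' adult-selection rule of the encoded guideline knowledge; the remaining
#' cut-offs (child <= 12, adolescent 13--18, oldAdult > 55) are a
#' documented package convention, overridable through the knowledge base
#' \code{age_bands} table.
#'
#' @param age Age in whole years, 0..130.
#' @param bands Optional named list with elements \code{child_max} and
#'   \code{adolescent_max} and \code{adult_max} (defaults 12, 18, 55).
#' @return One of \code{"child"}, \code{"adolescent"}, \code{"adult"},
#'   \code{"oldAdult"}.
#' @examples
#' categorize_age(30) # "adult"
#' categorize_age(8)  # "child"
#' @export
categorize_age <- function(age, bands = NULL) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age) ||
      age != trunc(age))
    stop("`age` must be a whole number", call. = FALSE)
  if (age < 0 || age > 130)
    stop("`age` must be in [0, 130]", call. = FALSE)
  b <- list(child_max = 12, adolescent_max = 18, adult_max = 55)
  if (!is.null(bands)) b[names(bands)] <- bands
  if (age <= b$child_max) "child"
  else if (age <= b$adolescent_max) "adolescent"
  else if (age <= b$adult_max) "adult"
  else "oldAdult"
}

#' Convert a glucose quantity between mg/dL and mmol/L
#'
#' Uses the fixed factor 18.0182 mg/dL per mmol/L (molar mass of glucose
#' divided by ten). The conversion is its own inverse to within 1e-9
#' relative tolerance.
#'
#' @param value A glucose [quantity()] in \code{"mg/dL"} or \code{"mmol/L"}.
#' @param to Target unit; default: the other unit.
#' @return A [quantity()] in the target unit.
#' @examples
#' convert_glucose(quantity(90, "mg/dL")) # about 5 mmol/L
#' @export
convert_glucose <- function(value, to = NULL) {
  value <- as_quantity(value)
  check_glucose_unit(value$unit)
  if (is.null(to)) to <- setdiff(GLUCOSE_UNITS, value$unit)
  check_glucose_unit(to)
  if (identical(value$unit, to)) return(value)
  v <- if (to == "mmol/L") value$value / GLUCOSE_MGDL_PER_MMOL
       else value$value * GLUCOSE_MGDL_PER_MMOL
  quantity(v, to)
}

glucose_in <- function(value, unit) convert_glucose(as_quantity(value), unit)$value

#' Flag dangerous glucose levels
#'
#' Flags hypoglycemia below 3.6 mmol/L and hyperglycemia above 9.0 mmol/L
#' (equivalently about 64.9 and 162.2 mg/dL); values between are
#' \code{"normal"}. This is flagging only -- emergency treatment is out of
#' scope.
#'
#' @param value A glucose [quantity()].
#' @return One of \code{"hypoglycemia"}, \code{"normal"},
#'   \code{"hyperglycemia"}.
#' @examples
#' classify_glucose_danger(quantity(3.5, "mmol/L")) # hypoglycemia
#' @export
classify_glucose_danger <- function(value) {
  mmol <- glucose_in(as_quantity(value), "mmol/L")
  if (mmol < 3.6) "hypoglycemia"
  else if (mmol > 9.0) "hyperglycemia"
  else "normal"
}
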