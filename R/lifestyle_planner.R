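# Lifestyle sub-plans: exercise (eligibility gate, forbidden/recommended
# exercises, component assembly from the MET catalog) and education
# (learning style, topics, course assignment).

EDUCATION_TOPICS <- c("insulin", "medications", "diet", "monitoring",
                      "emergency", "exercise", "complications")
LEARNING_STYLES <- c("reading", "visual", "auditory", "games",
                     "case_studies")

#' Is a patient eligible for an exercise plan?
#'
#' A patient is ineligible when any current condition is in the knowledge
#' base list of exercise-forbidding conditions (hypertension, dyslipidemia,
#' preproliferative retinopathy, nephropathy, cigarette smoking, ...), or
#' when pregnant and either extremely underweight (BMI below 12 kg/m^2) or
#' carrying a listed pregnancy contraindication (e.g. preeclampsia). Age
#' over 30 is recorded as an aggravating reason alongside a listed
#' condition but never bans on its own.
#'
#' @inheritParams contradicted_insulins
#' @return List with \code{allowed} (logical) and \code{reasons}
#'   (character vector, empty when allowed).
#' @export
exercise_eligibility <- function(profile, kb) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  conds <- profile_codes(profile$conditions)
  reasons <- character()
  hits <- intersect(conds, as.character(unlist(kb$exercise_forbidden_conditions)))
  if (length(hits)) {
    reasons <- c(reasons, paste0("condition: ", hits))
    if (profile$age > 30)
      reasons <- c(reasons, "age > 30 with a listed condition")
  }
  if (profile$pregnant) {
    b <- bmi(profile$weight, profile$height / 100)
    if (b < 12)
      reasons <- c(reasons, "pregnant and extremely underweight (BMI < 12)")
    preg_hits <- intersect(
      conds, as.character(unlist(kb$pregnancy_exercise_contraindications)))
    if (length(preg_hits))
      reasons <- c(reasons,
                   paste0("pregnancy contraindication: ", preg_hits))
  }
  list(allowed = !length(reasons), reasons = unique(reasons))
}

#' Exercises forbidden by current conditions
#'
#' Union of the knowledge base disease-exercise contradictions over the
#' patient's current conditions (e.g. foot ulcers forbid jogging,
#' cataracts forbid cycling, severe nonproliferative retinopathy forbids
#' jumping/jarring/breath-holding exercises).
#'
#' @inheritParams contradicted_insulins
#' @return Character vector of forbidden exercise codes.
#' @export
forbidden_exercises <- function(profile, kb) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  conds <- profile_codes(profile$conditions)
  unique(as.character(unlist(
    kb$disease_exercise_contra[
      intersect(conds, names(kb$disease_exercise_contra))])))
}

#' Recommended exercises
#'
#' The patient's preferred exercises minus the forbidden set; with no
#' stated preferences, the knowledge base default set minus the forbidden
#' set. An empty result (all preferences forbidden) comes back with a
#' warning.
#'
#' @param profile A [patient_profile()].
#' @param forbidden Character vector from [forbidden_exercises()].
#' @param kb A knowledge base (for the default set).
#' @return Character vector of exercise codes.
#' @export
recommended_exercises <- function(profile, forbidden, kb) {
  prefs <- profile_codes(profile$exercise_preferences)
  pool <- if (length(prefs)) prefs
          else as.character(unlist(kb$exercise_defaults))
  rec <- setdiff(pool, forbidden)
  if (!length(rec))
    warning("all candidate exercises are forbidden for this patient",
            call. = FALSE)
  rec
}

#' Build the exercise sub-plan
#'
#' Composes the eligibility gate, the forbidden set, and the recommended
#' set, then builds one component per recommended exercise from the MET
#' catalog with age-banded default frequency and duration. Ineligible
#' patients get an empty plan with \code{allowed = FALSE}. Plans for
#' fixed-regimen patients are marked \code{fixed_activity_level}: their
#' activity level may not be changed downstream.
#'
#' @inheritParams contradicted_insulins
#' @param regimen_kind The selected insulin regimen kind (activity level is
#'   fixed for fixed regimens); defaults to [choose_regimen()].
#' @return An object of class \code{t1d_exercise_plan}.
#' @export
build_exercise_plan <- function(profile, kb, regimen_kind = NULL) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  if (is.null(regimen_kind)) regimen_kind <- choose_regimen(profile)
  elig <- exercise_eligibility(profile, kb)
  forb <- forbidden_exercises(profile, kb)
  components <- list()
  if (elig$allowed) {
    rec <- suppressWarnings(recommended_exercises(profile, forb, kb))
    cat <- categorize_age(profile$age, kb$age_bands)
    defs <- kb$exercise_component_defaults
    for (code in rec) {
      entry <- kb$exercise_catalog[[code]]
      if (is.null(entry)) next  # unknown exercise: skip silently
      components <- c(components, list(list(
        exercise = coding("COMPENDIUM", code, entry$display %||% code),
        met = entry$met,
        frequency_per_week = defs$frequency_per_week[[cat]] %||% 3L,
        duration_min = defs$duration_min[[cat]] %||% 30L,
        intensity = entry$intensity %||% "moderate")))
    }
  }
  structure(
    list(allowed = elig$allowed, forbidden_reasons = elig$reasons,
         forbidden_exercises = forb, components = components,
         fixed_activity_level = regimen_kind %in% c("fixed_once",
                                                    "fixed_twice")),
    class = "t1d_exercise_plan")
}

#' Select learning styles for education
#'
#' Rule-table lookup by age category and education level: highly educated
#' adults get visual plus reading; children get games plus visual; older
#' adults with low education get auditory plus visual; the full table ships
#' in the knowledge base and is configurable.
#'
#' @param age_cat One of the four age categories.
#' @param education_level \code{"low"}, \code{"medium"}, \code{"high"}.
#' @param kb A knowledge base.
#' @return Character vector of learning styles.
#' @export
select_learning_style <- function(age_cat, education_level,
                                  kb = load_knowledge_base()) {
  age_cat <- match.arg(age_cat, AGE_CATEGORIES)
  education_level <- match.arg(education_level, c("low", "medium", "high"))
  styles <- kb$learning_styles[[age_cat]][[education_level]]
  if (is.null(styles)) styles <- c("visual")
  as.character(unlist(styles))
}

#' Select education topics
#'
#' Patients on intensive insulin therapy must at minimum study glucose
#' monitoring, insulin management, and diet management. Current
#' complications add the complications topic, a hypo-/hyperglycemia
#' history adds the emergency topic, and an active exercise plan adds the
#' exercise topic.
#'
#' @param profile A [patient_profile()].
#' @param regimen_kind The selected regimen kind.
#' @param exercise_active Logical: the patient has an exercise plan with
#'   components.
#' @return Character vector of topics (subset of the seven canonical
#'   topics), in canonical order.
#' @export
select_topics <- function(profile, regimen_kind, exercise_active = FALSE) {
  topics <- c("insulin", "diet", "monitoring")
  if (regimen_kind != "IIT") topics <- c("insulin", "medications", "diet")
  if (length(profile$conditions)) topics <- c(topics, "complications")
  if (profile$history_of_hypoglycemia > 0L ||
      profile$history_of_hyperglycemia > 0L)
    topics <- c(topics, "emergency")
  if (exercise_active) topics <- c(topics, "exercise")
  intersect(EDUCATION_TOPICS, topics)
}

#' Assign courses for topics and styles
#'
#' For each (topic, style) pair present, the catalog's course list is
#' appended in deterministic order: canonical topic order, then the given
#' style order, then catalog order; duplicates are removed. Missing catalog
#' entries are skipped with a warning.
#'
#' @param topics Character vector of topics.
#' @param styles Character vector of learning styles.
#' @param kb A knowledge base with a \code{course_catalog}.
#' @return Character vector of course identifiers.
#' @export
assign_courses <- function(topics, styles, kb) {
  stopifnot(inherits(kb, "t1d_kb"))
  topics <- intersect(EDUCATION_TOPICS, topics)
  courses <- character()
  missing <- character()
  for (tp in topics) {
    for (st in styles) {
      entry <- kb$course_catalog[[tp]][[st]]
      if (is.null(entry)) {
        missing <- c(missing, paste0(tp, "/", st))
        next
      }
      courses <- c(courses, as.character(unlist(entry)))
    }
  }
  if (length(missing))
    warning(sprintf("no courses in catalog for: %s",
                    paste(unique(missing), collapse = ", ")),
            call. = FALSE)
  unique(courses)
}

#' Build the education sub-plan
#'
#' Children and older adults with an available family member get the
#' relative as course coordinator; otherwise the patient coordinates.
#' Composes style selection, topic selection, and course assignment.
#'
#' @inheritParams contradicted_insulins
#' @param regimen_kind The selected regimen kind.
#' @param exercise_active Logical, see [select_topics()].
#' @return An object of class \code{t1d_education_plan} with
#'   \code{coordinator}, \code{styles}, \code{topics}, \code{courses}.
#' @export
build_education_plan <- function(profile, regimen_kind, kb,
                                 exercise_active = FALSE) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  cat <- categorize_age(profile$age, kb$age_bands)
  coordinator <- if (cat %in% c("child", "oldAdult") && profile$has_relative)
    "relative" else "patient"
  styles <- select_learning_style(cat, profile$education_level, kb)
  topics <- select_topics(profile, regimen_kind, exercise_active)
  courses <- suppressWarnings(assign_courses(topics, styles, kb))
  structure(list(coordinator = coordinator, styles = styles,
                 topics = topics, courses = courses),
            class = "t1d_education_plan")
}
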