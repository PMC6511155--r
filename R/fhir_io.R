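# FHIR-style JSON readers and writers for the exchanged documents.
# "Lite" means the profiled element subset used by this tool: documents
# carry resourceType/id and FHIR-compatible field names so real servers
# can ingest them, but no narrative or meta elements.

FHIR_SUPPORTED <- c("Patient", "Observation", "Condition",
                    "MedicationStatement", "MedicationRequest",
                    "AllergyIntolerance", "CarePlan", "Goal",
                    "NutritionOrder", "ProcedureRequest", "Device",
                    "Bundle")

LOINC_WEIGHT <- "29463-7"
LOINC_HEIGHT <- "8302-2"
LOINC_GLUCOSE <- "2339-0"

fhir_error <- function(path, msg) {
  stop(sprintf("FHIR validation error at %s: %s", path, msg), call. = FALSE)
}

validate_coding_json <- function(x, path) {
  if (is.null(x$system) || !nzchar(x$system %||% ""))
    fhir_error(paste0(path, ".system"), "missing coding system")
  if (is.null(x$code) || !nzchar(as.character(x$code %||% "")))
    fhir_error(paste0(path, ".code"), "missing code")
  invisible(x)
}

validate_quantity_json <- function(x, path) {
  if (is.null(x$value) || !is.numeric(x$value))
    fhir_error(paste0(path, ".value"), "missing numeric value")
  if (is.null(x$unit) || !nzchar(x$unit %||% ""))
    fhir_error(paste0(path, ".unit"), "missing unit")
  invisible(x)
}

#' Read a FHIR-lite JSON bundle
#'
#' Parses a Bundle document (JSON text or file path), validates each entry
#' against its resource schema (supported resource types only; every
#' Coding needs system and code, every Quantity value and unit), and
#' returns the entries as documents.
#'
#' @param json A JSON string or path to a JSON file.
#' @return List of documents of class \code{t1d_fhir_doc}, each with
#'   \code{resource_type}, \code{id}, \code{payload}.
#' @export
read_bundle <- function(json) {
  txt <- if (length(json) == 1L && file.exists(json))
    paste(readLines(json, warn = FALSE), collapse = "\n") else json
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON: ", conditionMessage(e),
                             call. = FALSE))
  if (!identical(parsed$resourceType, "Bundle"))
    fhir_error("$.resourceType", "expected a Bundle document")
  entries <- parsed$entry %||% list()
  docs <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    res <- entries[[i]]$resource %||% entries[[i]]
    path <- sprintf("$.entry[%d]", i)
    rt <- res$resourceType
    if (is.null(rt) || !rt %in% FHIR_SUPPORTED)
      fhir_error(paste0(path, ".resourceType"),
                 sprintf("unsupported resource type '%s'", rt %||% "<none>"))
    validate_resource(res, path)
    docs[[i]] <- structure(
      list(resource_type = rt, id = res$id %||% sprintf("doc-%d", i),
           payload = res),
      class = "t1d_fhir_doc")
  }
  docs
}

validate_resource <- function(res, path) {
  rt <- res$resourceType
  if (rt == "Observation") {
    if (!is.null(res$valueQuantity))
      validate_quantity_json(res$valueQuantity,
                             paste0(path, ".valueQuantity"))
    else
      fhir_error(paste0(path, ".valueQuantity"),
                 "observation lacks a value quantity")
    for (j in seq_along(res$code$coding %||% list()))
      validate_coding_json(res$code$coding[[j]],
                           sprintf("%s.code.coding[%d]", path, j))
  }
  if (rt %in% c("Condition", "MedicationStatement", "AllergyIntolerance")) {
    field <- if (rt == "MedicationStatement") "medicationCodeableConcept"
             else "code"
    codings <- res[[field]]$coding %||% list()
    if (!length(codings))
      fhir_error(sprintf("%s.%s.coding", path, field), "missing coding")
    for (j in seq_along(codings))
      validate_coding_json(codings[[j]],
                           sprintf("%s.%s.coding[%d]", path, field, j))
  }
  invisible(res)
}

coding_to_json <- function(cd) {
  list(system = cd$system, code = cd$code, display = cd$display)
}

json_to_coding <- function(x) {
  coding(x$system, x$code, x$display %||% "")
}

quantity_to_json <- function(q) list(value = q$value, unit = q$unit)

bundle_json <- function(entries, bundle_id = "bundle-1") {
  obj <- list(resourceType = "Bundle", id = bundle_id, type = "collection",
              entry = lapply(entries, function(e) list(resource = e)))
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"))
}

#' Serialize a patient profile as a FHIR-lite bundle
#'
#' Emits one Patient resource plus weight/height Observations and one
#' Condition / MedicationStatement / AllergyIntolerance per coded entry.
#' [bind_profile()] inverts this mapping.
#'
#' @param profile A [patient_profile()].
#' @param timestamp Observation timestamp (ISO string or POSIXct).
#' @return JSON text.
#' @export
write_patient_bundle <- function(profile,
                                 timestamp = "2024-01-01T08:00:00Z") {
  stopifnot(inherits(profile, "t1d_patient_profile"))
  ts <- format(as.POSIXct(timestamp, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  patient <- list(
    resourceType = "Patient", id = profile$id,
    gender = profile$sex,
    communication = list(list(language = profile$preferred_language)),
    extension = list(
      age = profile$age, pregnant = profile$pregnant,
      lifestyle = profile$lifestyle,
      education_level = profile$education_level,
      regimen_preference = profile$regimen_preference,
      food_preferences = as.list(profile$food_preferences),
      exercise_preferences = lapply(profile$exercise_preferences,
                                    coding_to_json),
      history_of_hypoglycemia = profile$history_of_hypoglycemia,
      history_of_hyperglycemia = profile$history_of_hyperglycemia,
      has_dka = profile$has_dka, has_relative = profile$has_relative))
  obs <- function(id, loinc, display, value, unit) {
    list(resourceType = "Observation", id = id, status = "final",
         code = list(coding = list(list(system = "LOINC", code = loinc,
                                        display = display))),
         subject = list(reference = paste0("Patient/", profile$id)),
         effectiveDateTime = ts,
         valueQuantity = list(value = value, unit = unit))
  }
  entries <- list(
    patient,
    obs(paste0(profile$id, "-weight"), LOINC_WEIGHT, "Body weight",
        profile$weight, "kg"),
    obs(paste0(profile$id, "-height"), LOINC_HEIGHT, "Body height",
        profile$height, "cm"))
  mk_coded <- function(rtype, field, items, prefix, extra = list()) {
    lapply(seq_along(items), function(i) {
      c(list(resourceType = rtype,
             id = sprintf("%s-%s-%d", profile$id, prefix, i)),
        stats::setNames(list(list(coding = list(coding_to_json(items[[i]])))),
                        field),
        list(subject = list(reference = paste0("Patient/", profile$id))),
        extra)
    })
  }
  entries <- c(entries,
               mk_coded("Condition", "code", profile$conditions, "cond",
                        list(verificationStatus = "confirmed")),
               mk_coded("MedicationStatement", "medicationCodeableConcept",
                        profile$medications, "med",
                        list(status = "active")),
               mk_coded("AllergyIntolerance", "code", profile$allergies,
                        "alg"))
  bundle_json(entries, paste0(profile$id, "-bundle"))
}

#' Bind FHIR-lite documents onto a patient profile
#'
#' Maps exactly one Patient document plus any Condition,
#' MedicationStatement, AllergyIntolerance and weight/height Observation
#' documents onto a [patient_profile()]. When several weight or height
#' observations are present, the latest timestamp wins.
#'
#' @param documents List of documents from [read_bundle()].
#' @return A [patient_profile()].
#' @export
bind_profile <- function(documents) {
  types <- vapply(documents, `[[`, "", "resource_type")
  pats <- documents[types == "Patient"]
  if (length(pats) != 1L)
    stop(sprintf("binding error: expected exactly 1 Patient document, got %d",
                 length(pats)), call. = FALSE)
  p <- pats[[1]]$payload
  ext <- p$extension %||% list()
  latest_obs <- function(loinc) {
    cand <- Filter(function(d) {
      d$resource_type == "Observation" &&
        any(vapply(d$payload$code$coding %||% list(),
                   function(cd) identical(cd$code, loinc), TRUE))
    }, documents)
    if (!length(cand)) return(NULL)
    ts <- vapply(cand, function(d)
      d$payload$effectiveDateTime %||% "", "")
    cand[[order(ts, decreasing = TRUE)[1]]]$payload$valueQuantity$value
  }
  coded_list <- function(rtype, field) {
    docs <- documents[types == rtype]
    unlist(lapply(docs, function(d) {
      lapply(d$payload[[field]]$coding %||% list(), json_to_coding)
    }), recursive = FALSE) %||% list()
  }
  weight <- latest_obs(LOINC_WEIGHT)
  height <- latest_obs(LOINC_HEIGHT)
  if (is.null(weight) || is.null(height))
    stop("binding error: weight and height observations are required",
         call. = FALSE)
  patient_profile(
    id = p$id %||% "patient",
    age = ext$age %||% stop("binding error: patient age missing",
                            call. = FALSE),
    sex = p$gender %||% "female",
    weight = weight, height = height,
    pregnant = isTRUE(ext$pregnant),
    lifestyle = ext$lifestyle %||% "sedentary",
    education_level = ext$education_level %||% "medium",
    preferred_language = (p$communication[[1]]$language %||% "en"),
    conditions = coded_list("Condition", "code"),
    medications = coded_list("MedicationStatement",
                             "medicationCodeableConcept"),
    allergies = coded_list("AllergyIntolerance", "code"),
    food_preferences = as.character(unlist(ext$food_preferences)),
    exercise_preferences = lapply(ext$exercise_preferences %||% list(),
                                  json_to_coding),
    regimen_preference = ext$regimen_preference %||% "none",
    history_of_hypoglycemia = ext$history_of_hypoglycemia %||% 0L,
    history_of_hyperglycemia = ext$history_of_hyperglycemia %||% 0L,
    has_dka = isTRUE(ext$has_dka),
    has_relative = isTRUE(ext$has_relative))
}

#' Serialize a glucose log as an Observation bundle
#'
#' @param log A [glucose_log()].
#' @param patient_id Patient reference.
#' @return JSON text; one final-status glucose Observation per reading,
#'   slot carried in an extension.
#' @export
write_observation_bundle <- function(log, patient_id = "patient") {
  stopifnot(inherits(log, "t1d_glucose_log"))
  unit <- attr(log, "unit")
  entries <- lapply(seq_len(nrow(log)), function(i) {
    list(resourceType = "Observation",
         id = sprintf("%s-bg-%d", patient_id, i), status = "final",
         code = list(coding = list(list(
           system = "LOINC", code = LOINC_GLUCOSE,
           display = "Glucose [Mass/volume] in Blood"))),
         subject = list(reference = paste0("Patient/", patient_id)),
         effectiveDateTime = paste0(format(log$date[i]), "T08:00:00Z"),
         valueQuantity = list(value = log$value[i], unit = unit),
         extension = list(slot = log$slot[i], date = format(log$date[i])))
  })
  bundle_json(entries, paste0(patient_id, "-bg-bundle"))
}

#' Bind glucose Observation documents onto a glucose log
#'
#' @param documents Documents from [read_bundle()].
#' @return A [glucose_log()].
#' @export
bind_glucose_log <- function(documents) {
  obs <- Filter(function(d) {
    d$resource_type == "Observation" &&
      any(vapply(d$payload$code$coding %||% list(),
                 function(cd) identical(cd$code, LOINC_GLUCOSE), TRUE))
  }, documents)
  if (!length(obs)) stop("no glucose observations in bundle", call. = FALSE)
  glucose_log(
    dates = vapply(obs, function(d)
      d$payload$extension$date %||%
        substr(d$payload$effectiveDateTime, 1, 10), ""),
    slots = vapply(obs, function(d) d$payload$extension$slot, ""),
    values = vapply(obs, function(d) d$payload$valueQuantity$value, 0),
    unit = obs[[1]]$payload$valueQuantity$unit)
}

#' Serialize a care plan as a FHIR-lite bundle
#'
#' Emits one CarePlan document plus its Goal, one MedicationRequest per
#' insulin dose, a NutritionOrder with per-meal extensions, and one
#' ProcedureRequest per exercise component and per education course.
#' Reading the bundle back and re-writing it is the identity, and
#' [bind_careplan()] recovers the plan content.
#'
#' @param plan A \code{t1d_care_plan}.
#' @return JSON text with stable key ordering.
#' @export
write_careplan_bundle <- function(plan) {
  stopifnot(inherits(plan, "t1d_care_plan"))
  pid <- plan$patient_id
  careplan <- list(
    resourceType = "CarePlan", id = paste0(pid, "-plan"),
    status = plan$status,
    category = list(coding = list(list(
      system = "SNOMEDCT", code = "698360004",
      display = "Diabetes self management plan"))),
    subject = list(reference = paste0("Patient/", pid)),
    created = format(plan$created, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    extension = list(valid_days = plan$valid_days,
                     is_current = plan$is_current,
                     regimen_kind = plan$regimen$kind,
                     tdd = plan$regimen$tdd,
                     f_factor = if (is.na(plan$regimen$f_factor)) NULL
                                else plan$regimen$f_factor))
  goal <- list(
    resourceType = "Goal", id = paste0(pid, "-goal"),
    subject = list(reference = paste0("Patient/", pid)),
    extension = list(
      hba1c_max = plan$goals$hba1c_max,
      premeal_bg_low = quantity_to_json(plan$goals$premeal_bg_low),
      premeal_bg_high = quantity_to_json(plan$goals$premeal_bg_high),
      weight_goal = plan$goals$weight_goal,
      bp_goal = plan$goals$bp_goal))
  medreqs <- lapply(seq_along(plan$regimen$doses), function(i) {
    d <- plan$regimen$doses[[i]]
    list(resourceType = "MedicationRequest",
         id = sprintf("%s-ins-%d", pid, i),
         subject = list(reference = paste0("Patient/", pid)),
         medicationCodeableConcept = list(coding = list(list(
           system = "COMPENDIUM", code = d$product$code,
           display = d$product$display %||% d$product$code))),
         dosageInstruction = list(list(
           timing = d$timing,
           doseQuantity = list(value = d$units, unit = "U"))),
         extension = list(kind = d$kind,
                          action_class = d$product$action_class,
                          units_rounded = d$units_rounded))
  })
  diet <- plan$diet
  nutrition <- list(
    resourceType = "NutritionOrder", id = paste0(pid, "-diet"),
    patient = list(reference = paste0("Patient/", pid)),
    excludeFoodModifier = as.list(diet$forbidden_foods),
    extension = list(
      dailyCalories = diet$calories_per_day,
      total_carbs_g = diet$total_carbs_g,
      bmr = diet$bmr, activity_multiplier = diet$activity_multiplier,
      maintenance_calories = diet$maintenance_calories,
      ideal_weight_low = diet$ideal_weight_low,
      ideal_weight_high = diet$ideal_weight_high,
      weight_status = diet$weight_status, weight_goal = diet$weight_goal,
      adjustment_period_days = diet$adjustment_period_days,
      recommended_food_groups = as.list(diet$recommended_food_groups),
      meal = lapply(diet$meals, function(m)
        list(name = m$name, share = m$share, carbs_g = m$carbs_g,
             calories = m$calories))))
  procs <- list()
  for (i in seq_along(plan$exercise$components)) {
    cmp <- plan$exercise$components[[i]]
    procs <- c(procs, list(list(
      resourceType = "ProcedureRequest",
      id = sprintf("%s-exr-%d", pid, i),
      subject = list(reference = paste0("Patient/", pid)),
      code = list(coding = list(coding_to_json(cmp$exercise))),
      extension = list(category = "exercise", met = cmp$met,
                       frequency_per_week = cmp$frequency_per_week,
                       duration_min = cmp$duration_min,
                       intensity = cmp$intensity))))
  }
  for (i in seq_along(plan$education$courses)) {
    procs <- c(procs, list(list(
      resourceType = "ProcedureRequest",
      id = sprintf("%s-edu-%d", pid, i),
      subject = list(reference = paste0("Patient/", pid)),
      code = list(coding = list(list(system = "COURSE",
                                     code = plan$education$courses[[i]],
                                     display = ""))),
      extension = list(category = "education",
                       coordinator = plan$education$coordinator))))
  }
  bundle_json(c(list(careplan, goal), medreqs, list(nutrition), procs),
              paste0(pid, "-careplan-bundle"))
}

#' Recover care-plan content from FHIR-lite documents
#'
#' Inverts the field mapping of [write_careplan_bundle()]: returns the
#' plan's regimen (kind, TDD, doses), goal values, diet numbers, exercise
#' components and course list as plain structures for comparison or
#' downstream use.
#'
#' @param documents Documents from [read_bundle()].
#' @return A named list mirroring the care-plan content.
#' @export
bind_careplan <- function(documents) {
  types <- vapply(documents, `[[`, "", "resource_type")
  cp <- documents[types == "CarePlan"]
  if (length(cp) != 1L)
    stop("binding error: expected exactly 1 CarePlan document",
         call. = FALSE)
  cpe <- cp[[1]]$payload$extension
  goal <- documents[types == "Goal"][[1]]$payload$extension
  doses <- lapply(documents[types == "MedicationRequest"], function(d) {
    pl <- d$payload
    list(code = pl$medicationCodeableConcept$coding[[1]]$code,
         units = pl$dosageInstruction[[1]]$doseQuantity$value,
         timing = pl$dosageInstruction[[1]]$timing,
         kind = pl$extension$kind,
         action_class = pl$extension$action_class)
  })
  nut <- documents[types == "NutritionOrder"]
  diet <- if (length(nut)) {
    e <- nut[[1]]$payload$extension
    list(calories_per_day = e$dailyCalories,
         total_carbs_g = e$total_carbs_g,
         weight_status = e$weight_status, weight_goal = e$weight_goal,
         meals = e$meal,
         forbidden_foods =
           as.character(unlist(nut[[1]]$payload$excludeFoodModifier)))
  } else NULL
  procs <- documents[types == "ProcedureRequest"]
  is_edu <- vapply(procs, function(d)
    identical(d$payload$extension$category, "education"), TRUE)
  list(status = cp[[1]]$payload$status,
       regimen_kind = cpe$regimen_kind, tdd = cpe$tdd,
       f_factor = cpe$f_factor,
       goals = list(hba1c_max = goal$hba1c_max,
                    premeal_bg_low = goal$premeal_bg_low$value,
                    premeal_bg_high = goal$premeal_bg_high$value,
                    weight_goal = goal$weight_goal),
       doses = doses, diet = diet,
       exercises = lapply(procs[!is_edu], function(d)
         d$payload$code$coding[[1]]$code),
       courses = vapply(procs[is_edu], function(d)
         d$payload$code$coding[[1]]$code, ""))
}
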