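# Assembles the four sub-plans and the goal set into one care plan with
# validity metadata, and maintains it against follow-up measurements.

#' Build a complete care plan
#'
#' Composes the insulin, diet, exercise, and education planners for one
#' patient. The result is a draft: the system proposes, a physician
#' approves (see [approve_plan()]). The plan is valid for
#' \code{valid_days} days (default 90) and is then maintained against the
#' HbA1c and weight goals.
#'
#' @inheritParams contradicted_insulins
#' @param d Diet adjustment period in days.
#' @param valid_days Plan validity in days.
#' @param f Basal fraction for IIT, see [split_iit()].
#' @param created Plan creation time (POSIXct), defaults to now.
#' @return An object of class \code{t1d_care_plan}.
#' @examples
#' kb <- load_knowledge_base()
#' p <- patient_profile("p1", 30, "female", 65, 170,
#'                      regimen_preference = "IIT")
#' plan <- build_care_plan(p, kb)
#' plan$regimen$tdd
#' @export
build_care_plan <- function(profile, kb, d = 90L, valid_days = 90L,
                            f = 0.5, created = NULL) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  regimen <- tryCatch(build_insulin_plan(profile, kb, f = f),
                      error = function(e)
                        stop("insulin_planner: ", conditionMessage(e),
                             call. = FALSE))
  diet <- tryCatch(build_diet_plan(profile, kb, d = d),
                   error = function(e)
                     stop("diet_planner: ", conditionMessage(e),
                          call. = FALSE))
  exercise <- build_exercise_plan(profile, kb, regimen$kind)
  education <- build_education_plan(profile, regimen$kind, kb,
                                    exercise_active =
                                      length(exercise$components) > 0)
  goals <- regimen$goals
  goals$weight_goal <- diet$weight_goal
  structure(
    list(patient_id = profile$id,
         created = created %||% Sys.time(),
         valid_days = as.integer(valid_days), is_current = TRUE,
         goals = goals, regimen = regimen, diet = diet,
         exercise = exercise, education = education,
         status = "draft", profile = profile),
    class = "t1d_care_plan")
}

#' Record physician approval of a plan
#'
#' @param plan A draft \code{t1d_care_plan}.
#' @return The plan with \code{status = "approved"}.
#' @export
approve_plan <- function(plan) {
  stopifnot(inherits(plan, "t1d_care_plan"))
  plan$status <- "approved"
  plan
}

#' Maintain a care plan against follow-up measurements
#'
#' Plans are reviewed every three months against the HbA1c and weight
#' goals. When either goal is unmet (measured HbA1c above the goal
#' ceiling, or weight off the weight goal by more than \code{weight_tol}
#' kg), the affected sub-plans are rebuilt from the updated profile
#' (weight feeds the TDD, so the insulin and diet plans are recomputed,
#' and the real-time ISF/ICR follow the new TDD immediately). When both
#' goals are met, the plan's validity window is simply renewed. The prior
#' plan is archived with \code{is_current = FALSE}; exactly one plan per
#' patient stays current.
#'
#' @param plan The current \code{t1d_care_plan}.
#' @param hba1c Latest HbA1c [quantity()] in percent (or a number).
#' @param weight Latest weight [quantity()] in kg (or a number).
#' @param kb A knowledge base.
#' @param weight_tol Tolerance around the weight goal in kg (default 2).
#' @return List with \code{current} (the new plan) and \code{archived}
#'   (the superseded plan, \code{is_current = FALSE}).
#' @export
maintain_plan <- function(plan, hba1c, weight, kb, weight_tol = 2) {
  stopifnot(inherits(plan, "t1d_care_plan"), inherits(kb, "t1d_kb"))
  if (!isTRUE(plan$is_current))
    stop("plan already superseded: refusing to maintain a stale plan",
         call. = FALSE)
  hba1c <- if (inherits(hba1c, "t1d_quantity")) hba1c$value else hba1c
  weight <- if (inherits(weight, "t1d_quantity")) weight$value else weight
  hba1c_met <- hba1c < plan$goals$hba1c_max
  weight_met <- is.na(plan$goals$weight_goal) ||
    abs(weight - plan$goals$weight_goal) <= weight_tol
  if (hba1c_met && weight_met) {
    new <- plan
    new$created <- Sys.time()
  } else {
    profile <- plan$profile
    profile$weight <- weight
    new <- build_care_plan(profile, kb, d = plan$diet$adjustment_period_days,
                           valid_days = plan$valid_days,
                           f = if (is.na(plan$regimen$f_factor)) 0.5
                               else plan$regimen$f_factor)
  }
  archived <- plan
  archived$is_current <- FALSE
  list(current = new, archived = archived)
}

#' @export
print.t1d_care_plan <- function(x, ...) {
  cat(sprintf("<care plan> patient %s | %s | valid %d days | %s\n",
              x$patient_id, x$status, x$valid_days,
              if (x$is_current) "current" else "archived"))
  cat(sprintf("  goals: HbA1c < %.1f%%, pre-meal %g-%g mg/dL\n",
              x$goals$hba1c_max, x$goals$premeal_bg_low$value,
              x$goals$premeal_bg_high$value))
  print(x$regimen)
  print(x$diet)
  cat(sprintf("  exercise: %s (%d components) | education: %d courses (%s)\n",
              if (x$exercise$allowed) "allowed" else "not allowed",
              length(x$exercise$components),
              length(x$education$courses), x$education$coordinator))
  invisible(x)
}
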