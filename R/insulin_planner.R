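# Long-term insulin sub-plan: glycemic goals, regimen choice, weight-based
# total daily dose (TDD), fixed and basal-bolus dose splits, and safe
# product selection.

IIT_F_VALUES <- c(0.3, 0.4, 0.5, 0.6)

#' Set glycemic and weight goals for a patient
#'
#' Pregnant adults (and adolescents) get the guideline stratum directly:
#' HbA1c below 6.5\% and a pre-meal glucose range of 90--100 mg/dL. Every
#' other (age category, pregnancy) stratum is looked up in the knowledge
#' base goal table; a history of hypoglycemia relaxes the HbA1c ceiling and
#' raises the pre-meal floor by the configured override amounts.
#'
#' @inheritParams contradicted_insulins
#' @return An object of class \code{t1d_goal_set}: \code{hba1c_max}
#'   (percent), \code{premeal_bg_low}/\code{premeal_bg_high} (mg/dL
#'   quantities), \code{bedtime_bg_range}, \code{weight_goal} (filled by the
#'   diet planner), \code{bp_goal}.
#' @export
set_goals <- function(profile, kb) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  cat <- categorize_age(profile$age, kb$age_bands)
  key <- if (profile$pregnant) paste0(cat, "_pregnant") else cat
  g <- kb$goal_defaults[[key]]
  if (is.null(g)) g <- kb$goal_defaults[[cat]]
  if (is.null(g))
    kb_error(paste0("goal_defaults.", key), "no goal template for stratum")
  hba1c <- g$hba1c_max
  low <- g$premeal_low
  high <- g$premeal_high
  if (profile$history_of_hypoglycemia > 0L && !profile$pregnant) {
    ov <- kb$goal_overrides
    hba1c <- hba1c + (ov$hypoglycemia_history_hba1c_relax %||% 0)
    low <- low + (ov$hypoglycemia_history_premeal_low_raise %||% 0)
  }
  if (low >= high) low <- high - 10
  structure(
    list(hba1c_max = hba1c,
         premeal_bg_low = quantity(low, "mg/dL"),
         premeal_bg_high = quantity(high, "mg/dL"),
         bedtime_bg_range = list(quantity(g$bedtime_low %||% low, "mg/dL"),
                                 quantity(g$bedtime_high %||% high, "mg/dL")),
         weight_goal = NA_real_,
         bp_goal = "systolic < 140 mmHg, diastolic < 90 mmHg"),
    class = "t1d_goal_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose an insulin regimen kind
#'
#' Pregnant patients and children are put on intensive insulin therapy
#' (IIT, basal-bolus) regardless of preference; other patients get their
#' stated preference, and a preference of \code{"none"} defaults to IIT.
#'
#' @param profile A [patient_profile()].
#' @return \code{"IIT"}, \code{"fixed_once"} or \code{"fixed_twice"}.
#' @export
choose_regimen <- function(profile) {
  stopifnot(inherits(profile, "t1d_patient_profile"))
  cat <- categorize_age(profile$age)
  if (profile$pregnant || cat == "child") return("IIT")
  if (profile$regimen_preference == "none") "IIT"
  else profile$regimen_preference
}

#' Total daily insulin dose from body weight
#'
#' TDD = 0.6 units per kg, unrounded; the starting dose for any regimen.
#'
#' @param weight Body weight in kg, > 0.
#' @return TDD in insulin units per day.
#' @examples
#' compute_tdd(30) # 18
#' @export
compute_tdd <- function(weight) {
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight <= 0)
    stop("`weight` must be a positive number of kg", call. = FALSE)
  0.6 * weight
}

#' Split a TDD for the twice-daily fixed regimen
#'
#' The morning dose is 2/3 of TDD and the evening dose 1/3. The morning
#' dose is split 2/3 long/intermediate-acting, 1/3 short-acting; the
#' evening dose is split in half. The four components sum exactly to TDD
#' before rounding.
#'
#' @param tdd Total daily dose in insulin units, > 0 (0 allowed as a
#'   degenerate limit).
#' @return Named numeric vector \code{c(md_l, md_s, ed_l, ed_s)}.
#' @examples
#' split_fixed_twice(compute_tdd(30)) # 8 4 3 3
#' @export
split_fixed_twice <- function(tdd) {
  if (!is.numeric(tdd) || length(tdd) != 1L || is.na(tdd) || tdd < 0)
    stop("`tdd` must be a non-negative number of units", call. = FALSE)
  md <- 2 / 3 * tdd
  ed <- 1 / 3 * tdd
  c(md_l = 2 / 3 * md, md_s = 1 / 3 * md, ed_l = ed / 2, ed_s = ed / 2)
}

#' Split a TDD for intensive insulin therapy
#'
#' Basal dose BA = f * TDD; bolus dose BO = (1 - f) * TDD, divided into
#' three equal pre-meal shots. The basal fraction f must be one of 0.3,
#' 0.4, 0.5 or 0.6; most guidelines use 0.5, the package default.
#'
#' @param tdd Total daily dose in insulin units.
#' @param f Basal fraction, one of 0.3, 0.4, 0.5, 0.6.
#' @return Named numeric vector \code{c(ba, bo, premeal)}.
#' @examples
#' split_iit(50) # ba 25, bo 25, premeal 8.33
#' @export
split_iit <- function(tdd, f = 0.5) {
  if (!is.numeric(tdd) || length(tdd) != 1L || is.na(tdd) || tdd < 0)
    stop("`tdd` must be a non-negative number of units", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L ||
      !any(abs(f - IIT_F_VALUES) < 1e-12))
    stop("`f` must be one of 0.3, 0.4, 0.5, 0.6", call. = FALSE)
  ba <- f * tdd
  bo <- (1 - f) * tdd
  c(ba = ba, bo = bo, premeal = bo / 3)
}

insulin_dose <- function(product, units, timing, kind) {
  structure(list(product = product, units = units, timing = timing,
                 kind = kind),
            class = "t1d_insulin_dose")
}

#' Build the complete insulin sub-plan
#'
#' Composes goal setting, regimen choice, weight-based TDD, the matching
#' dose split, and safe product selection per action class:
#' \itemize{
#'   \item IIT: one long-acting basal product (one bedtime shot by
#'     default, or split morning/evening when
#'     \code{basal_shots = 2}) plus one rapid-acting bolus product before
#'     each of the three meals;
#'   \item fixed twice-daily: intermediate- plus short-acting products,
#'     morning and evening, mixed in one syringe per shot;
#'   \item fixed once-daily: a single long-acting morning shot of the full
#'     TDD.
#' }
#' Dose amounts are exact internally; \code{units_rounded} carries the
#' whole-unit presentation value.
#'
#' @inheritParams contradicted_insulins
#' @param f Basal fraction for IIT, see [split_iit()].
#' @param basal_shots 1 (bedtime) or 2 (morning/evening halves) for IIT.
#' @return An object of class \code{t1d_insulin_regimen} with fields
#'   \code{kind}, \code{tdd}, \code{f_factor}, \code{doses}, \code{goals}.
#' @export
build_insulin_plan <- function(profile, kb, f = 0.5, basal_shots = 1L) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  if (!basal_shots %in% c(1L, 2L))
    stop("`basal_shots` must be 1 or 2", call. = FALSE)
  goals <- set_goals(profile, kb)
  kind <- choose_regimen(profile)
  tdd <- compute_tdd(profile$weight)
  doses <- list()
  f_factor <- NA_real_
  if (kind == "IIT") {
    f_factor <- f
    parts <- split_iit(tdd, f)
    basal <- select_insulin("long", profile, kb)
    bolus <- select_insulin("rapid", profile, kb)
    if (basal_shots == 1L) {
      doses <- list(insulin_dose(basal, parts[["ba"]], "bedtime", "basal"))
    } else {
      doses <- list(
        insulin_dose(basal, parts[["ba"]] / 2, "morning", "basal"),
        insulin_dose(basal, parts[["ba"]] / 2, "evening", "basal"))
    }
    for (tm in c("before_breakfast", "before_lunch", "before_dinner"))
      doses <- c(doses, list(insulin_dose(bolus, parts[["premeal"]], tm,
                                          "bolus")))
  } else if (kind == "fixed_twice") {
    parts <- split_fixed_twice(tdd)
    interm <- select_insulin("intermediate", profile, kb)
    short <- select_insulin("short", profile, kb)
    doses <- list(
      insulin_dose(interm, parts[["md_l"]], "morning", "mixed_long"),
      insulin_dose(short, parts[["md_s"]], "morning", "mixed_short"),
      insulin_dose(interm, parts[["ed_l"]], "evening", "mixed_long"),
      insulin_dose(short, parts[["ed_s"]], "evening", "mixed_short"))
  } else { # fixed_once
    long <- select_insulin("long", profile, kb)
    doses <- list(insulin_dose(long, tdd, "morning", "basal"))
  }
  doses <- lapply(doses, function(d) {
    d$units_rounded <- round(d$units)
    d
  })
  structure(list(kind = kind, tdd = tdd, f_factor = f_factor,
                 doses = doses, goals = goals),
            class = "t1d_insulin_regimen")
}

regimen_daily_units <- function(regimen) {
  sum(vapply(regimen$doses, function(d) d$units, 0))
}

#' @export
print.t1d_insulin_regimen <- function(x, ...) {
  cat(sprintf("<insulin regimen> %s, TDD %.1f U/day\n", x$kind, x$tdd))
  for (d in x$doses)
    cat(sprintf("  %-16s %-12s %5.1f U (%s)\n", d$timing, d$product$code,
                d$units, d$kind))
  invisible(x)
}
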