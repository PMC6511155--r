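# Deterministic generator of synthetic patients, glucose logs with
# injectable out-of-range patterns, and file fixtures. Emulates the
# sensor/EHR inputs the decision support engine consumes; it is a
# convention-driven noise model, not a physiologic glucose simulator.

# Run code under a local RNG seed without disturbing the caller's stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed below 2^31 from a base seed and salts.
derive_seed <- function(seed, ...) {
  salts <- c(...)
  s <- as.double(seed) %% 2147483629
  for (x in salts) s <- (s * 69069 + as.double(x) + 1) %% 2147483629
  as.integer(s)
}

#' Define a synthetic-data scenario
#'
#' A scenario fixes the demographic ranges, regimen mix, glucose noise
#' level, pattern injections, and master seed from which every synthetic
#' artifact is derived. All generator outputs are pure functions of
#' (scenario, index).
#'
#' @param name Scenario name.
#' @param seed Master seed (integer).
#' @param demographics List of ranges: \code{age} (c(min, max)),
#'   \code{weight} (kg), \code{height} (cm), \code{female_prob},
#'   \code{pregnant_prob} (applied to adult females only).
#' @param regimen_mix Named proportions over \code{IIT},
#'   \code{fixed_once}, \code{fixed_twice}; must sum to 1.
#' @param pattern_injections List of injections, each
#'   \code{list(slot =, direction = "high"/"low", magnitude =)} with
#'   magnitude in mg/dL.
#' @param noise_sd Gaussian glucose sensor noise (mg/dL), >= 0.
#' @return An object of class \code{t1d_scenario}.
#' @export
scenario <- function(name = "default", seed = 1L,
                     demographics = list(age = c(19, 55),
                                         weight = c(50, 100),
                                         height = c(150, 190),
                                         female_prob = 0.5,
                                         pregnant_prob = 0.1),
                     regimen_mix = c(IIT = 0.6, fixed_once = 0.1,
                                     fixed_twice = 0.3),
                     pattern_injections = list(),
                     noise_sd = 10) {
  if (abs(sum(regimen_mix) - 1) > 1e-9)
    stop("`regimen_mix` proportions must sum to 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  for (inj in pattern_injections) {
    stopifnot(inj$slot %in% PATTERN_SLOTS,
              inj$direction %in% c("high", "low"), inj$magnitude >= 0)
  }
  structure(list(name = name, seed = as.integer(seed),
                 demographics = demographics, regimen_mix = regimen_mix,
                 pattern_injections = pattern_injections,
                 noise_sd = noise_sd),
            class = "t1d_scenario")
}

#' Generate a synthetic patient profile
#'
#' Samples one profile from the scenario's demographic ranges. The same
#' (scenario seed, index) pair always yields an identical profile, and
#' every draw satisfies the profile invariants (pregnancy only for adult
#' females, positive anthropometrics).
#'
#' @param scn A [scenario()].
#' @param index Patient index within the scenario (0-based).
#' @return A [patient_profile()].
#' @export
generate_patient <- function(scn, index = 0L) {
  stopifnot(inherits(scn, "t1d_scenario"))
  dem <- scn$demographics
  local_seed(derive_seed(scn$seed, 101L, index), {
    age <- sample(seq(dem$age[1], dem$age[2]), 1L)
    sex <- if (stats::runif(1) < (dem$female_prob %||% 0.5)) "female"
           else "male"
    pregnant <- sex == "female" && age >= 19 && age <= 45 &&
      stats::runif(1) < (dem$pregnant_prob %||% 0)
    weight <- round(stats::runif(1, dem$weight[1], dem$weight[2]), 1)
    height <- round(stats::runif(1, dem$height[1], dem$height[2]), 1)
    pref <- sample(names(scn$regimen_mix), 1L, prob = scn$regimen_mix)
    lifestyle <- sample(LIFESTYLES, 1L)
    patient_profile(
      id = sprintf("%s-%04d", scn$name, index),
      age = age, sex = sex, weight = weight, height = height,
      pregnant = pregnant, lifestyle = lifestyle,
      education_level = sample(c("low", "medium", "high"), 1L),
      regimen_preference = pref,
      exercise_preferences = lapply(
        sample(c("walking", "jogging", "cycling", "swimming"),
               sample(0:2, 1L)),
        function(code) coding("COMPENDIUM", code)),
      history_of_hypoglycemia = stats::rpois(1, 0.3),
      history_of_hyperglycemia = stats::rpois(1, 0.3),
      has_relative = stats::runif(1) < 0.7)
  })
}

#' Generate a multi-day synthetic glucose log
#'
#' Each of the four daily slots gets a baseline inside the goal range
#' (drawn once per log) plus Gaussian sensor noise of \code{noise_sd}
#' mg/dL. Each pattern injection shifts its slot by its magnitude on
#' every day (up for \code{"high"}, down for \code{"low"}); injected
#' slots are anchored at the goal midpoint, so an injection of magnitude
#' above the goal half-width plus three noise standard deviations yields
#' a detectable three-day pattern with high probability, and a noise-free
#' log without injections never triggers one.
#'
#' @param profile A [patient_profile()] (identifies the log).
#' @param goal Numeric \code{c(low, high)} goal range in mg/dL.
#' @param days Number of consecutive days, >= 3.
#' @param scn A [scenario()] carrying noise and injections.
#' @param index Log index for seed derivation.
#' @param start Start date.
#' @return A [glucose_log()] in mg/dL.
#' @export
generate_glucose_log <- function(profile, goal = c(70, 140), days = 3L,
                                 scn = scenario(), index = 0L,
                                 start = as.Date("2024-03-01")) {
  stopifnot(inherits(scn, "t1d_scenario"))
  if (days < 3) stop("`days` must be >= 3", call. = FALSE)
  mid <- mean(goal)
  width <- diff(goal)
  inj_slots <- vapply(scn$pattern_injections, `[[`, "", "slot")
  local_seed(derive_seed(scn$seed, 211L, index, days), {
    baselines <- stats::setNames(
      stats::runif(4, goal[1] + 0.25 * width, goal[2] - 0.25 * width),
      PATTERN_SLOTS)
    baselines[inj_slots] <- mid
    rows <- expand.grid(date = start + seq_len(days) - 1L,
                        slot = PATTERN_SLOTS, stringsAsFactors = FALSE)
    vals <- baselines[rows$slot] +
      stats::rnorm(nrow(rows), 0, scn$noise_sd)
    for (inj in scn$pattern_injections) {
      shift <- if (inj$direction == "high") inj$magnitude
               else -inj$magnitude
      vals[rows$slot == inj$slot] <- vals[rows$slot == inj$slot] + shift
    }
    glucose_log(rows$date, rows$slot, round(pmax(vals, 20), 0), "mg/dL")
  })
}

#' The printed three-day glucose log fixture
#'
#' The three consecutive days of four-slot glucose self-monitoring used
#' to illustrate pattern management (goal 70--140 mg/dL): all
#' before-breakfast values are high, all other slots are in range except
#' a single before-dinner excursion on the second day, which must not
#' trigger a finding on its own.
#'
#' @return A [glucose_log()] with 12 mg/dL readings over May 5--7.
#' @export
table_log_fixture <- function() {
  days <- as.Date(c("2018-05-05", "2018-05-06", "2018-05-07"))
  glucose_log(
    dates = rep(days, each = 4),
    slots = rep(PATTERN_SLOTS, times = 3),
    values = c(320, 104, 96, 86,
               296, 123, 300, 136,
               341, 197, 92, 111),
    unit = "mg/dL")
}

#' The worked-example patient
#'
#' An adult on intensive insulin therapy whose weight (83.33 kg) is the
#' inverse of the weight-based dose rule at TDD = 50 U, so the real-time
#' worked example (ICR 10, ISF 36, bolus 8.5 U for a 60 g meal at glucose
#' 210 vs goal 120 mg/dL) is reproducible end to end.
#'
#' @return A [patient_profile()].
#' @export
worked_example_profile <- function() {
  patient_profile(id = "patient-x", age = 40, sex = "male",
                  weight = 50 / 0.6, height = 175,
                  lifestyle = "moderately_active",
                  education_level = "high",
                  regimen_preference = "IIT")
}

#' Write a reproducible set of fixture bundles
#'
#' Writes patient bundles for a small cohort, the worked-example patient
#' bundle, the printed three-day log as an Observation bundle, a glucose
#' log with an injected before-breakfast high pattern, and the default
#' knowledge-base config; returns a manifest of files and content hashes.
#' Same scenario and seed, same hashes.
#'
#' @param out_dir Output directory (created if missing).
#' @param scn A [scenario()].
#' @param n_patients Cohort size.
#' @return Data frame manifest with columns \code{file} and \code{md5}.
#' @export
generate_fixture_bundles <- function(out_dir, scn = scenario(),
                                     n_patients = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(name, text) {
    path <- file.path(out_dir, name)
    writeLines(text, path)
    files <<- c(files, path)
  }
  for (i in seq_len(n_patients) - 1L) {
    p <- generate_patient(scn, i)
    put(sprintf("patient_%04d.json", i), write_patient_bundle(p))
  }
  put("patient_x.json", write_patient_bundle(worked_example_profile()))
  put("three_day_log.json",
      write_observation_bundle(table_log_fixture(), "patient-x"))
  inj_scn <- scenario(name = scn$name, seed = scn$seed,
                      noise_sd = scn$noise_sd,
                      pattern_injections = list(list(
                        slot = "before_breakfast", direction = "high",
                        magnitude = 200)))
  log <- generate_glucose_log(generate_patient(scn, 0L), c(70, 140), 3L,
                              inj_scn)
  put("injected_log.json", write_observation_bundle(log, "synthetic"))
  kb_path <- file.path(out_dir, "kb.yaml")
  file.copy(default_kb_path(), kb_path, overwrite = TRUE)
  files <- c(files, kb_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
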