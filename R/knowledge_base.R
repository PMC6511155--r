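# Config-loaded catalogs and contradiction maps: insulin products, drug
# interactions, MET table, learning-style and course catalogs, goal
# templates. These stand in for the terminological knowledge a deployment
# would curate; the shipped defaults mirror the printed guideline examples.

INSULIN_CLASSES <- c("rapid", "short", "intermediate", "long")
TABLE2_MULTIPLIERS <- c(sedentary = 1.2, lightly_active = 1.375,
                        moderately_active = 1.55, very_active = 1.725,
                        extra_active = 1.9)

kb_error <- function(path, msg) {
  stop(sprintf("knowledge base config error at '%s': %s", path, msg),
       call. = FALSE)
}

default_kb_path <- function() {
  system.file("extdata", "default_kb.yaml", package = "t1dplan",
              mustWork = TRUE)
}

#' Load a knowledge base
#'
#' Reads the catalogs and contradiction maps the planners consult. Missing
#' top-level sections fall back to the shipped defaults, so an empty
#' document yields the all-defaults knowledge base. Drug-drug
#' contradictions may be stored once per unordered pair; symmetry is
#' enforced on load. All type invariants (five activity-level multipliers,
#' unique preference ranks within an insulin action class) are validated
#' and violations raise a config error naming the failing path.
#'
#' @param config_source \code{NULL} for the shipped defaults, a path to a
#'   YAML or JSON document, or an already-parsed named list.
#' @return An object of class \code{t1d_kb}.
#' @examples
#' kb <- load_knowledge_base()
#' names(kb$activity_levels)
#' @export
load_knowledge_base <- function(config_source = NULL) {
  defaults <- yaml::read_yaml(default_kb_path())
  user <- NULL
  if (is.null(config_source)) {
    user <- list()
  } else if (is.character(config_source) && length(config_source) == 1L) {
    if (!file.exists(config_source))
      kb_error(config_source, "file not found")
    user <- if (grepl("\\.json$", config_source, ignore.case = TRUE))
      jsonlite::read_json(config_source, simplifyVector = TRUE)
    else yaml::read_yaml(config_source)
    if (is.null(user)) user <- list()
  } else if (is.list(config_source)) {
    user <- config_source
  } else {
    kb_error("<config_source>", "must be NULL, a file path, or a list")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    kb_error(unknown[1L], "unknown section")
  kb <- defaults
  kb[names(user)] <- user
  kb <- validate_kb(kb)
  structure(kb, class = "t1d_kb")
}

validate_kb <- function(kb) {
  al <- unlist(kb$activity_levels)
  if (!setequal(names(al), names(TABLE2_MULTIPLIERS)))
    kb_error("activity_levels", "must contain exactly the five lifestyles")
  if (!isTRUE(all.equal(al[names(TABLE2_MULTIPLIERS)], TABLE2_MULTIPLIERS,
                        tolerance = 1e-12)))
    kb_error("activity_levels",
             "multipliers must be 1.2, 1.375, 1.55, 1.725, 1.9")

  cat <- kb$insulin_catalog
  if (!length(cat)) kb_error("insulin_catalog", "must not be empty")
  for (i in seq_along(cat)) {
    p <- cat[[i]]
    path <- sprintf("insulin_catalog[%d]", i)
    if (is.null(p$code) || !nzchar(p$code)) kb_error(path, "missing code")
    if (is.null(p$action_class) || !p$action_class %in% INSULIN_CLASSES)
      kb_error(paste0(path, ".action_class"),
               "must be rapid, short, intermediate, or long")
    if (is.null(p$preference_rank) || !is.numeric(p$preference_rank))
      kb_error(paste0(path, ".preference_rank"), "missing rank")
  }
  classes <- vapply(cat, `[[`, "", "action_class")
  ranks <- vapply(cat, function(p) as.numeric(p$preference_rank), 0)
  for (cl in unique(classes)) {
    r <- ranks[classes == cl]
    if (anyDuplicated(r))
      kb_error("insulin_catalog",
               sprintf("duplicate preference_rank within class '%s'", cl))
  }

  kb$drug_drug_contra <- symmetrize_pairs(kb$drug_drug_contra)

  if (!is.null(kb$goal_defaults)) {
    for (nm in names(kb$goal_defaults)) {
      g <- kb$goal_defaults[[nm]]
      if (g$premeal_low >= g$premeal_high)
        kb_error(sprintf("goal_defaults.%s", nm),
                 "premeal_low must be < premeal_high")
      if (g$hba1c_max <= 0)
        kb_error(sprintf("goal_defaults.%s", nm), "hba1c_max must be > 0")
    }
  }
  kb
}

# Expand a pair map so a ~ b implies b ~ a; idempotent.
symmetrize_pairs <- function(m) {
  if (is.null(m) || !length(m)) return(m)
  out <- lapply(m, function(x) as.character(unlist(x)))
  for (a in names(m)) {
    for (b in out[[a]]) {
      out[[b]] <- unique(c(out[[b]], a))
    }
  }
  out <- lapply(out, sort)
  out[order(names(out))]
}

#' Serialize a knowledge base to YAML
#'
#' Writing then re-loading the shipped defaults is the identity.
#'
#' @param kb A \code{t1d_kb} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "t1d_kb"))
  yaml::write_yaml(unclass(kb), path)
  invisible(path)
}

#' @export
print.t1d_kb <- function(x, ...) {
  cat(sprintf(paste0("<knowledge base> %d insulin products, %d exercises, ",
                     "%d drug-drug pairs, %d goal strata\n"),
              length(x$insulin_catalog), length(x$exercise_catalog),
              length(x$drug_drug_contra), length(x$goal_defaults)))
  invisible(x)
}

profile_codes <- function(codings) {
  vapply(codings, function(cd) cd$code, "")
}

#' Insulins contradicted for a patient
#'
#' An insulin product is contradicted when it is drug-drug contradicted
#' with any currently taken medication, or drug-disease contradicted with
#' any current condition. Codes absent from the knowledge base contribute
#' nothing.
#'
#' @param profile A [patient_profile()].
#' @param kb A [load_knowledge_base()] result.
#' @return Character vector of contradicted insulin codes (possibly empty),
#'   with a \code{"reasons"} attribute mapping each code to the triggering
#'   medication/condition.
#' @examples
#' kb <- load_knowledge_base()
#' p <- patient_profile("p", 40, "male", 80, 180,
#'   medications = list(coding("SNOMEDCT", "beta-blockers")))
#' contradicted_insulins(p, kb) # "detemir"
#' @export
contradicted_insulins <- function(profile, kb) {
  stopifnot(inherits(profile, "t1d_patient_profile"), inherits(kb, "t1d_kb"))
  meds <- profile_codes(profile$medications)
  conds <- profile_codes(profile$conditions)
  out <- character()
  reasons <- list()
  for (p in kb$insulin_catalog) {
    hits <- character()
    dd <- as.character(unlist(kb$drug_drug_contra[[p$code]]))
    hit_meds <- intersect(meds, dd)
    if (length(hit_meds))
      hits <- c(hits, paste0("drug-drug: ", hit_meds))
    ddis <- as.character(unlist(kb$drug_disease_contra[[p$code]]))
    hit_conds <- intersect(conds, ddis)
    if (length(hit_conds))
      hits <- c(hits, paste0("drug-disease: ", hit_conds))
    if (length(hits)) {
      out <- c(out, p$code)
      reasons[[p$code]] <- hits
    }
  }
  structure(unique(out), reasons = reasons)
}

#' Select the preferred safe insulin of an action class
#'
#' Returns the lowest preference-rank product of the class that is not in
#' [contradicted_insulins()]; e.g. if the first-choice long-acting product
#' is contradicted by a current medication, the next-ranked product is
#' selected instead.
#'
#' @param action_class One of \code{"rapid"}, \code{"short"},
#'   \code{"intermediate"}, \code{"long"}.
#' @inheritParams contradicted_insulins
#' @return The selected product (list with \code{code}, \code{display},
#'   \code{action_class}, \code{preference_rank}).
#' @export
select_insulin <- function(action_class, profile, kb) {
  action_class <- match.arg(action_class, INSULIN_CLASSES)
  contra <- contradicted_insulins(profile, kb)
  cand <- Filter(function(p) p$action_class == action_class,
                 kb$insulin_catalog)
  if (!length(cand))
    kb_error("insulin_catalog",
             sprintf("no product of class '%s'", action_class))
  cand <- cand[order(vapply(cand, function(p) as.numeric(p$preference_rank),
                            0))]
  for (p in cand) {
    if (!p$code %in% contra) return(p)
  }
  why <- attr(contra, "reasons")[vapply(cand, `[[`, "", "code")]
  stop(sprintf(
    "no safe insulin of class '%s': all products contradicted (%s)",
    action_class,
    paste(vapply(seq_along(cand), function(i)
      paste0(cand[[i]]$code, " [", paste(why[[i]], collapse = "; "), "]"),
      ""), collapse = ", ")), call. = FALSE)
}
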