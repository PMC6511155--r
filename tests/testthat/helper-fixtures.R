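# Shared fixtures and independent oracles used across the suite.

kb_default <- load_knowledge_base()

make_profile <- function(...) {
  args <- list(id = "t", age = 30L, sex = "female", weight = 65,
               height = 170)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(patient_profile, args)
}

sct <- function(code) coding("SNOMEDCT", code)

# Independent brute-force oracle for contradicted insulins: scan every
# (medication, insulin) and (condition, insulin) pair of the KB.
brute_contradicted <- function(profile, kb) {
  meds <- vapply(profile$medications, function(cd) cd$code, "")
  conds <- vapply(profile$conditions, function(cd) cd$code, "")
  out <- character()
  for (p in kb$insulin_catalog) {
    for (m in meds)
      if (m %in% unlist(kb$drug_drug_contra[[p$code]]))
        out <- c(out, p$code)
    for (cn in conds)
      if (cn %in% unlist(kb$drug_disease_contra[[p$code]]))
        out <- c(out, p$code)
  }
  sort(unique(out))
}

# Independent brute-force pattern scan: every consecutive-3-day window,
# all three same-slot values outside goal on the same side; per slot the
# most recent qualifying window wins (matching the dedup contract).
brute_patterns <- function(log, goal) {
  slots <- c("before_breakfast", "before_lunch", "before_dinner",
             "before_bedtime")
  dates <- sort(unique(log$date))
  found <- list()
  for (start in seq_along(dates)) {
    window <- dates[start] + 0:2
    if (!all(window %in% dates)) next
    for (slot in slots) {
      vals <- log$value[log$date %in% window & log$slot == slot]
      if (length(vals) != 3) next
      if (all(vals > goal[2]))
        found[[slot]] <- list(slot = slot, direction = "high",
                              window = window)
      else if (all(vals < goal[1]))
        found[[slot]] <- list(slot = slot, direction = "low",
                              window = window)
    }
  }
  unname(found)
}

finding_key <- function(f) paste(f$slot, f$direction, max(f$window))

random_log <- function(goal = c(70, 140)) {
  days <- sample(3:6, 1)
  start <- as.Date("2024-01-01") + sample(0:60, 1)
  slots <- c("before_breakfast", "before_lunch", "before_dinner",
             "before_bedtime")
  rows <- expand.grid(date = start + seq_len(days) - 1L, slot = slots,
                      stringsAsFactors = FALSE)
  glucose_log(rows$date, rows$slot,
              round(runif(nrow(rows), 40, 260)), "mg/dL")
}
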