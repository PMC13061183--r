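library(data.table)

# Small hand-curated concept table used across tests.
tiny_concepts <- function() {
  data.table(
    canonical_name = c("Naproxen", "Ketorolac", "Acetaminophen",
                       "Ferrous Sulfate", "Hydrocortisone", "Diclofenac"),
    aliases = c("", "", "TYLENOL|PARAMOL",
                "FERFOLIC|IRONFORTE|FOLIRON", "", ""),
    is_top_list = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
}

tiny_kb_rows <- function() {
  data.table(
    drug_a = c("Naproxen", "Ketorolac", "Acetaminophen", "Diclofenac"),
    drug_b = c("Ketorolac", "Diclofenac", "Naproxen", "Naproxen"),
    severity = c("contraindicated", "contraindicated", "minor", "major"))
}

# Build a line-item table in the prescription CSV dialect from a list of
# prescriptions: list(list(id, pid, age, sex, spec, drugs = c(...)), ...)
make_items <- function(spec_list) {
  rbindlist(lapply(spec_list, function(p) {
    data.table(prescription_id = p$id,
               patient_id = p$pid,
               age = as.character(p$age),
               sex = p$sex,
               specialty = if (is.null(p$spec)) "general practice" else p$spec,
               drug_name = p$drugs)
  }))
}

# Independent brute-force oracle: resolves raw KB rows to a max-severity map
# itself (no package loader) and checks all pairs with a double loop.
oracle_build <- function(kb_rows) {
  rank <- c(moderate = 1L, major = 2L, contraindicated = 3L)
  e <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(kb_rows))) {
    s <- tolower(trimws(kb_rows$severity[i]))
    if (!s %in% names(rank)) next
    a <- tolower(gsub("\\s+", " ", trimws(kb_rows$drug_a[i])))
    b <- tolower(gsub("\\s+", " ", trimws(kb_rows$drug_b[i])))
    key <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    old <- if (exists(key, envir = e, inherits = FALSE)) get(key, envir = e) else NULL
    if (is.null(old) || rank[[s]] > rank[[old]]) assign(key, s, envir = e)
  }
  e
}

oracle_pairs <- function(concepts, env) {
  cs <- sort(unique(tolower(concepts)))
  out <- list()
  if (length(cs) >= 2L) {
    for (i in seq_len(length(cs) - 1L)) {
      for (j in (i + 1L):length(cs)) {
        key <- paste(cs[i], cs[j], sep = "\r")
        if (exists(key, envir = env, inherits = FALSE)) {
          out[[length(out) + 1L]] <- data.table(
            first = cs[i], second = cs[j], severity = get(key, envir = env))
        }
      }
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(first = character(0), second = character(0),
               severity = character(0))
}

# Fabricate a minimal cohort + screen_result pair for summary-level tests:
# `df` has one row per prescription with columns prescription_id, patient_id,
# sex, age, specialty, drug_count, n_interactions, and optional severity
# flags has_contra / has_major / has_moderate.
fake_screened <- function(df) {
  df <- as.data.table(df)
  if (is.null(df$patient_id)) df[, patient_id := paste0("P", .I)]
  if (is.null(df$sex)) df[, sex := "female"]
  if (is.null(df$age)) df[, age := 50L]
  if (is.null(df$specialty)) df[, specialty := "general practice"]
  if (is.null(df$drug_count)) df[, drug_count := 3L]
  for (f in c("has_contra", "has_major", "has_moderate")) {
    if (is.null(df[[f]])) df[, (f) := FALSE]
  }
  df[n_interactions > 0 & !(has_contra | has_major | has_moderate),
     has_major := TRUE]
  pres <- df[, .(prescription_id, patient_id, age, sex, specialty,
                 drug_count,
                 age_group = assign_age_group(age),
                 polypharmacy = flag_polypharmacy(drug_count))]
  cohort <- structure(list(
    prescriptions = pres,
    items = data.table(),
    flow = list(n_input = nrow(pres), n_missing_demo = 0L, n_single_drug = 0L,
                n_no_top_drug = 0L, n_retained = nrow(pres)),
    match_report = NULL), class = "ddi_cohort")

  act <- df[n_interactions > 0L]
  if (nrow(act)) {
    sev_sets <- mapply(function(mo, ma, co) {
      c(if (mo) "moderate", if (ma) "major", if (co) "contraindicated")
    }, act$has_moderate, act$has_major, act$has_contra, SIMPLIFY = FALSE)
    ni <- act$n_interactions
    row_id <- rep(seq_len(nrow(act)), ni)
    pos <- sequence(ni)
    klen <- lengths(sev_sets)[row_id]
    sevs <- unlist(sev_sets)[cumsum(lengths(sev_sets))[row_id] -
                               lengths(sev_sets)[row_id] +
                               ((pos - 1L) %% klen) + 1L]
    ints <- data.table(prescription_id = act$prescription_id[row_id],
                       first = paste0("a", pos),
                       second = paste0("b", pos),
                       severity = sevs)
  } else {
    ints <- data.table(prescription_id = character(0), first = character(0),
                       second = character(0), severity = character(0))
  }
  prof_key <- fifelse(df$n_interactions == 0L, "none",
    paste0(fifelse(df$has_moderate, "m", ""),
           fifelse(df$has_major, "M", ""),
           fifelse(df$has_contra, "C", "")))
  prof_map <- c(none = "none", m = "moderate_only", M = "major_only",
                C = "contra_only", mM = "moderate+major", MC = "major+contra",
                mC = "moderate+contra", mMC = "all_three")
  per_pres <- df[, .(prescription_id, n_interactions,
                     profile = factor(prof_map[prof_key],
                                      levels = ddiscreen:::PROFILE_LEVELS))]
  per_pair <- ints[, .(severity = severity[1L], frequency = .N),
                   by = .(first, second)]
  totals <- vapply(SEVERITY_LEVELS, function(s) sum(ints$severity == s),
                   integer(1))
  sr <- structure(list(interactions = ints, per_prescription = per_pres,
                       per_pair = per_pair, totals = totals,
                       n_prescriptions = nrow(pres)),
                  class = "screen_result")
  list(cohort = cohort, sr = sr)
}
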