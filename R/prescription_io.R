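# Prescription ingestion, exclusion cascade with disjoint flow accounting,
# and demographic strata.

AGE_GROUP_LEVELS <- c("0-18", "19-39", "40-64", "65-100")

#' Read raw prescription line items
#'
#' One CSV row per dispensed line item. Line items are grouped by
#' `prescription_id`; stable input order is preserved.
#'
#' @param path CSV with header
#'   `prescription_id,patient_id,age,sex,specialty,drug_name`
#'   (sex coded M/F, empty = missing; empty age = missing).
#' @return data.table of line items (one row per item) with `age` integer
#'   (NA when missing) and `sex` in {male, female, NA}.
#' @export
read_prescriptions <- function(path) {
  raw <- data.table::fread(path, colClasses = "character", encoding = "UTF-8",
                           keepLeadingZeros = TRUE)
  req <- c("prescription_id", "patient_id", "age", "sex", "specialty", "drug_name")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop(sprintf("prescription CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  raw[, age := suppressWarnings(as.integer(age))]
  raw[, sex := data.table::fcase(toupper(trimws(sex)) == "M", "male",
                                 toupper(trimws(sex)) == "F", "female",
                                 default = NA_character_)]
  raw[]
}

#' Assign an age group
#'
#' Closed integer intervals 0-18 / 19-39 / 40-64 / 65-100. Ages above 100 are
#' mapped into 65-100 with a warning; negative ages are an error.
#'
#' @param age integer vector of ages in years.
#' @return factor with the four age-group levels.
#' @export
assign_age_group <- function(age) {
  if (any(age < 0, na.rm = TRUE)) stop("negative age", call. = FALSE)
  over <- sum(age > 100, na.rm = TRUE)
  if (over > 0) {
    warning(sprintf("%d age(s) above 100 mapped to 65-100", over), call. = FALSE)
  }
  cut(pmin(age, 100L), breaks = c(-1, 18, 39, 64, 100),
      labels = AGE_GROUP_LEVELS)
}

#' Flag polypharmacy
#'
#' @param drug_count integer vector of retained medications per prescription.
#' @param threshold polypharmacy cut (default 5 medications).
#' @return logical: `drug_count >= threshold`.
#' @export
flag_polypharmacy <- function(drug_count, threshold = 5L) {
  drug_count >= threshold
}

#' Apply the exclusion cascade and assemble the analysis cohort
#'
#' Prescriptions are excluded, in this order, if they (1) miss patient sex or
#' age, (2) contain fewer than two drugs, or (3) contain no drug from the
#' reference top list. Each prescription lands in exactly one flow bucket
#' (first matching reason), so the buckets are disjoint and sum to the input
#' count. Non-systemic line items are removed before the single-drug test by
#' default (`topical_removal = "line"`); `topical_removal = "prescription"`
#' instead drops any prescription containing a non-systemic item, and
#' `topical_removal = "after"` applies the single-drug test before removing
#' topicals.
#'
#' Unmatched drug names are retained as inert items: they count toward
#' `drug_count` but cannot interact. A matched but non-systemic item does
#' not satisfy the top-list rule.
#'
#' @param items line-item data.table from [read_prescriptions()].
#' @param index an `alias_index`.
#' @param top_list canonical names that define the inclusion rule; default:
#'   concepts flagged `is_top_list` in the index.
#' @param topical_removal "line" (default), "prescription", or "after".
#' @return object of class `ddi_cohort`: list with `prescriptions`
#'   (data.table: prescription_id, patient_id, age, sex, specialty,
#'   drug_count, age_group, polypharmacy), `items` (retained systemic items
#'   with concept), `flow` (cohort-flow counts), `match_report`.
#' @export
apply_exclusion_cascade <- function(items, index,
                                    top_list = NULL,
                                    topical_removal = c("line", "prescription", "after")) {
  topical_removal <- match.arg(topical_removal)
  stopifnot(inherits(index, "alias_index"))
  if (is.null(top_list)) {
    top_list <- index$concepts$canonical_name[index$concepts$is_top_list]
  }
  top_list <- normalize_drug_name(top_list)
  items <- data.table::as.data.table(items)
  # accept both the raw CSV dialect (character age, M/F sex) and the
  # normalized form produced by read_prescriptions()
  if (is.character(items$age)) {
    items <- data.table::copy(items)
    items[, age := suppressWarnings(as.integer(age))]
  }
  if (any(items$sex %in% c("M", "F", ""), na.rm = TRUE)) {
    items <- data.table::copy(items)
    items[, sex := data.table::fcase(toupper(trimws(sex)) == "M", "male",
                                     toupper(trimws(sex)) == "F", "female",
                                     sex %in% c("male", "female"), sex,
                                     default = NA_character_)]
  }

  mm <- match_drug_names(index, items$drug_name)
  items <- cbind(items, mm[, list(concept, matched, systemic)])

  # per-prescription header facts
  hdr <- items[, list(patient_id = patient_id[1L],
                      age = age[1L],
                      sex = sex[1L],
                      specialty = specialty[1L],
                      n_items = .N,
                      n_systemic = sum(systemic),
                      has_topical = any(!systemic),
                      has_top_sys = any(systemic & matched &
                                          concept %in% top_list)),
               by = "prescription_id"]

  n_input <- nrow(hdr)
  miss_demo <- is.na(hdr$age) | is.na(hdr$sex)
  eff_count <- switch(topical_removal,
                      line = hdr$n_systemic,
                      prescription = ifelse(hdr$has_topical, 0L, hdr$n_items),
                      after = hdr$n_items)
  single <- !miss_demo & eff_count < 2L
  # after-mode: prescriptions passing the single-drug test on raw counts still
  # screen only systemic items, and drug_count reflects systemic items
  no_top <- !miss_demo & !single & !hdr$has_top_sys
  keep <- !miss_demo & !single & !no_top

  flow <- list(n_input = n_input,
               n_missing_demo = sum(miss_demo),
               n_single_drug = sum(single),
               n_no_top_drug = sum(no_top),
               n_retained = sum(keep))

  kept <- hdr[keep]
  pres <- data.table::data.table(
    prescription_id = kept$prescription_id,
    patient_id = kept$patient_id,
    age = kept$age,
    sex = kept$sex,
    specialty = kept$specialty,
    drug_count = kept$n_systemic)
  if (nrow(pres)) {
    pres[, age_group := assign_age_group(age)]
    pres[, polypharmacy := flag_polypharmacy(drug_count)]
  } else {
    pres[, age_group := factor(character(0), levels = AGE_GROUP_LEVELS)]
    pres[, polypharmacy := logical(0)]
  }
  kept_items <- items[prescription_id %in% pres$prescription_id & systemic == TRUE]
  structure(list(prescriptions = pres,
                 items = kept_items,
                 flow = flow,
                 match_report = match_report(mm)),
            class = "ddi_cohort")
}

#' @export
print.ddi_cohort <- function(x, ...) {
  f <- x$flow
  cat("Cohort:", f$n_retained, "prescriptions retained of", f$n_input, "\n")
  cat(sprintf("  excluded: %d missing demographics, %d single-drug, %d no top-list drug\n",
              f$n_missing_demo, f$n_single_drug, f$n_no_top_drug))
  cat("  patients:", length(unique(x$prescriptions$patient_id)), "\n")
  invisible(x)
}

#' Cohort-flow report
#'
#' @param cohort a `ddi_cohort`.
#' @param path optional JSON output path.
#' @return the flow list (conserves: input = sum of buckets + retained).
#' @export
flow_report <- function(cohort, path = NULL) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  if (!is.null(path)) {
    jsonlite::write_json(cohort$flow, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(cohort$flow))
  }
  cohort$flow
}
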