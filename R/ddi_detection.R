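# Within-prescription interaction detection, severity-profile classification
# and cohort-level screening aggregates.

PROFILE_LEVELS <- c("none", "moderate_only", "major_only", "contra_only",
                    "moderate+major", "major+contra", "moderate+contra",
                    "all_three")

#' Detect interactions within one prescription
#'
#' Enumerates the distinct unordered pairs of matched systemic drug concepts
#' in the prescription and keeps those present in the knowledge base. A pair
#' is counted once per prescription regardless of duplicated line items;
#' unmatched or non-systemic items contribute nothing.
#'
#' @param concepts character vector of matched systemic canonical names for
#'   one prescription (duplicates allowed, collapsed internally).
#' @param kb an `interaction_kb`.
#' @return data.table with columns `first`, `second`, `severity` (zero rows
#'   when nothing interacts).
#' @export
detect_interactions <- function(concepts, kb) {
  stopifnot(inherits(kb, "interaction_kb"))
  cs <- sort(unique(normalize_drug_name(concepts[!is.na(concepts)])))
  cs <- cs[nzchar(cs)]
  if (length(cs) < 2L || kb$n_pairs == 0L) {
    return(kb$pairs[0L, list(first, second, severity)])
  }
  idx <- utils::combn(length(cs), 2L)
  cand <- data.table::data.table(first = cs[idx[1L, ]], second = cs[idx[2L, ]])
  out <- kb$pairs[cand, on = c("first", "second"), nomatch = NULL]
  out[order(first, second), list(first, second, severity)]
}

#' Classify the severity profile of one prescription
#'
#' The category is determined solely by the SET of severities present, giving
#' eight mutually exclusive categories over the powerset of
#' {moderate, major, contraindicated}.
#'
#' @param severities character vector of severities detected in one
#'   prescription (may be empty).
#' @return one of the eight profile labels.
#' @export
classify_profile <- function(severities) {
  s <- unique(severities)
  stopifnot(all(s %in% SEVERITY_LEVELS))
  has_mod <- "moderate" %in% s
  has_maj <- "major" %in% s
  has_con <- "contraindicated" %in% s
  if (!has_mod && !has_maj && !has_con) return("none")
  if (has_mod && has_maj && has_con)    return("all_three")
  if (has_mod && has_maj)               return("moderate+major")
  if (has_maj && has_con)               return("major+contra")
  if (has_mod && has_con)               return("moderate+contra")
  if (has_mod) "moderate_only" else if (has_maj) "major_only" else "contra_only"
}

#' Screen a cohort against the knowledge base
#'
#' Runs pair detection over every retained prescription and aggregates:
#' per-prescription interaction counts and severity profiles, per-pair
#' frequencies with severity, and instance totals by severity. Iteration
#' order is canonical (sorted keys) so outputs are byte-stable.
#'
#' @param cohort a `ddi_cohort`.
#' @param kb an `interaction_kb`.
#' @return object of class `screen_result`: list with `interactions`
#'   (prescription_id, first, second, severity), `per_prescription`
#'   (prescription_id, n_interactions, profile), `per_pair` (first, second,
#'   severity, frequency), `totals` (named instance counts by severity),
#'   `n_prescriptions`.
#' @export
screen_cohort <- function(cohort, kb) {
  stopifnot(inherits(cohort, "ddi_cohort"), inherits(kb, "interaction_kb"))
  pres <- cohort$prescriptions
  items <- cohort$items

  inter <- empty_interactions()
  if (nrow(pres) && nrow(items) && kb$n_pairs > 0L) {
    di <- unique(items[matched == TRUE & systemic == TRUE,
                       list(prescription_id, concept)])
    # all within-prescription concept pairs via self-join, then KB filter
    a <- di[di, on = "prescription_id", allow.cartesian = TRUE]
    a <- a[concept < i.concept,
           list(prescription_id, first = concept, second = i.concept)]
    inter <- kb$pairs[a, on = c("first", "second"), nomatch = NULL,
                      list(prescription_id, first, second, severity)]
    data.table::setorderv(inter, c("prescription_id", "first", "second"))
  }

  per_pres <- inter[, list(n_interactions = .N,
                           profile = classify_profile(severity)),
                    by = "prescription_id"]
  all_pres <- data.table::data.table(prescription_id = pres$prescription_id)
  per_pres <- per_pres[all_pres, on = "prescription_id"]
  per_pres[is.na(n_interactions), `:=`(n_interactions = 0L, profile = "none")]
  per_pres[, profile := factor(profile, levels = PROFILE_LEVELS)]
  data.table::setorderv(per_pres, "prescription_id")

  per_pair <- inter[, list(severity = severity[1L], frequency = .N),
                    by = c("first", "second")]
  data.table::setorderv(per_pair, c("first", "second"))

  totals <- vapply(SEVERITY_LEVELS, function(s) sum(inter$severity == s),
                   integer(1))
  structure(list(interactions = inter,
                 per_prescription = per_pres,
                 per_pair = per_pair,
                 totals = totals,
                 n_prescriptions = nrow(pres)),
            class = "screen_result")
}

empty_interactions <- function() {
  data.table::data.table(prescription_id = character(0), first = character(0),
                         second = character(0), severity = character(0))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screen result:", nrow(x$interactions), "interaction instances in",
      x$n_prescriptions, "prescriptions\n")
  cat(sprintf("  contraindicated %d | major %d | moderate %d | unique pairs %d\n",
              x$totals[["contraindicated"]], x$totals[["major"]],
              x$totals[["moderate"]], nrow(x$per_pair)))
  invisible(x)
}

#' Write detected interactions and per-pair aggregates as CSV
#'
#' @param sr a `screen_result`.
#' @param interactions_path,per_pair_path output CSV paths (either may be
#'   NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_screen_csv <- function(sr, interactions_path = NULL, per_pair_path = NULL) {
  stopifnot(inherits(sr, "screen_result"))
  if (!is.null(interactions_path)) {
    out <- sr$interactions[, list(prescription_id, drug_a = first,
                                  drug_b = second, severity)]
    data.table::fwrite(out, interactions_path)
  }
  if (!is.null(per_pair_path)) {
    out <- sr$per_pair[, list(drug_a = first, drug_b = second, severity,
                              frequency)]
    data.table::fwrite(out, per_pair_path)
  }
  invisible(c(interactions_path, per_pair_path))
}
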