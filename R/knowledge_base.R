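# Severity-graded pairwise interaction knowledge base with canonical
# unordered-pair keys and highest-severity resolution.

#' Severity levels recognised by the screen
#'
#' Interaction severities form a total order: contraindicated > major >
#' moderate. "minor" is a legal label in source compendia but is dropped at
#' ingestion and never stored (minor interactions are clinically negligible
#' and would otherwise contaminate prevalence denominators).
#'
#' @format Named integer vector mapping label to rank.
#' @export
SEVERITY_RANKS <- c(moderate = 1L, major = 2L, contraindicated = 3L)

#' Ordered severity labels, lowest first
#' @export
SEVERITY_LEVELS <- names(SEVERITY_RANKS)

#' Normalize a drug name for keying
#'
#' Trims, collapses internal whitespace, and case-folds to lower case.
#' Alphabetical pair order is defined on this normalized form.
#'
#' @param x character vector of raw drug names.
#' @return character vector of normalized names.
#' @export
normalize_drug_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Canonical unordered drug-pair key
#'
#' Standardizes a pair by sorting the normalized names alphabetically so that
#' (A, B) and (B, A) yield the same key and pairs are never double counted.
#'
#' @param name_a,name_b drug names (free text; normalized internally).
#' @return length-2 character vector `c(first, second)` with `first < second`.
#' @seealso [canonical_pair_vec()] for the vectorized form.
#' @export
canonical_pair <- function(name_a, name_b) {
  a <- normalize_drug_name(name_a)
  b <- normalize_drug_name(name_b)
  if (!nzchar(a) || !nzchar(b)) {
    stop("canonical_pair: drug names must be non-empty after normalization",
         call. = FALSE)
  }
  if (a == b) {
    stop(ddi_error("duplicate_drug",
                   sprintf("self-pair: '%s' and '%s' normalize to the same drug",
                           name_a, name_b)))
  }
  if (a < b) c(a, b) else c(b, a)
}

#' Vectorized canonical pair keys
#'
#' @param a,b character vectors of equal length.
#' @return data.table with columns `first`, `second`.
#' @export
canonical_pair_vec <- function(a, b) {
  a <- normalize_drug_name(a)
  b <- normalize_drug_name(b)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("canonical_pair_vec: empty drug name after normalization", call. = FALSE)
  }
  if (any(a == b)) {
    stop(ddi_error("duplicate_drug", "self-pair in vectorized canonical keying"))
  }
  swap <- a > b
  data.table::data.table(first  = ifelse(swap, b, a),
                         second = ifelse(swap, a, b))
}

# Classed condition so callers can distinguish self-pair rejection from
# ordinary validation failures.
ddi_error <- function(class, message) {
  structure(class = c(class, "ddi_error", "error", "condition"),
            list(message = message, call = NULL))
}

#' Load an interaction knowledge base from tabular records
#'
#' Each input row names two interacting drugs and a severity label. Rows
#' labelled "minor" are dropped (and counted); rows with an unknown severity
#' label are rejected (and reported with their row indices); surviving rows
#' are keyed canonically and duplicate keys are collapsed to the highest
#' severity seen, so the loaded KB carries exactly one severity per pair.
#'
#' @param x a data.frame with columns `drug_a`, `drug_b`, `severity`, or the
#'   path of a CSV file with that header.
#' @return an object of class `interaction_kb`: list with `pairs`
#'   (data.table `first`, `second`, `severity`, `rank`, keyed by pair),
#'   `n_pairs`, `n_dropped_minor`, `rejected_rows` (integer row indices),
#'   `n_input_rows`.
#' @export
load_interaction_kb <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- data.table::fread(x, colClasses = "character", encoding = "UTF-8")
  }
  x <- data.table::as.data.table(x)
  req <- c("drug_a", "drug_b", "severity")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop(sprintf("interaction KB is missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  n_input <- nrow(x)
  if (n_input == 0L) {
    return(new_interaction_kb(empty_pairs(), 0L, integer(0), 0L))
  }
  sev <- tolower(trimws(x$severity))
  minor <- sev == "minor"
  known <- sev %in% SEVERITY_LEVELS
  rejected <- which(!known & !minor)
  keep <- known & !minor
  n_minor <- sum(minor)
  if (!any(keep)) {
    return(new_interaction_kb(empty_pairs(), n_minor, rejected, n_input))
  }
  pairs <- canonical_pair_vec(x$drug_a[keep], x$drug_b[keep])
  pairs[, rank := SEVERITY_RANKS[sev[keep]]]
  pairs <- pairs[, list(rank = max(rank)), by = c("first", "second")]
  pairs[, severity := SEVERITY_LEVELS[rank]]
  data.table::setcolorder(pairs, c("first", "second", "severity", "rank"))
  data.table::setkeyv(pairs, c("first", "second"))
  new_interaction_kb(pairs, n_minor, rejected, n_input)
}

empty_pairs <- function() {
  p <- data.table::data.table(first = character(0), second = character(0),
                              severity = character(0), rank = integer(0))
  data.table::setkeyv(p, c("first", "second"))
  p
}

new_interaction_kb <- function(pairs, n_dropped_minor, rejected_rows, n_input_rows) {
  structure(list(pairs = pairs,
                 n_pairs = nrow(pairs),
                 n_dropped_minor = as.integer(n_dropped_minor),
                 rejected_rows = as.integer(rejected_rows),
                 n_input_rows = as.integer(n_input_rows)),
            class = "interaction_kb")
}

#' @export
print.interaction_kb <- function(x, ...) {
  cat("Interaction knowledge base:", x$n_pairs, "unique drug pairs\n")
  if (x$n_pairs > 0) {
    tab <- table(factor(x$pairs$severity, levels = rev(SEVERITY_LEVELS)))
    for (s in names(tab)) cat(sprintf("  %-16s %d\n", s, tab[[s]]))
  }
  cat("  dropped minor rows:", x$n_dropped_minor,
      "| rejected rows:", length(x$rejected_rows), "\n")
  invisible(x)
}

#' Look up the severity of a drug pair
#'
#' Symmetric in its arguments; a self-pair is an error (not "absent").
#'
#' @param kb an `interaction_kb`.
#' @param name_a,name_b drug names.
#' @return severity label, or `NA_character_` when the pair is absent.
#' @export
kb_lookup <- function(kb, name_a, name_b) {
  stopifnot(inherits(kb, "interaction_kb"))
  key <- canonical_pair(name_a, name_b)
  i <- kb$pairs[list(key[1], key[2]), on = c("first", "second"), which = TRUE]
  if (is.na(i)) NA_character_ else kb$pairs$severity[i]
}

#' Loader report for a knowledge base
#'
#' @param kb an `interaction_kb`.
#' @param path optional path; when given, the report is written there as JSON.
#' @return list with input/kept/dropped counts (invisibly when written).
#' @export
kb_report <- function(kb, path = NULL) {
  stopifnot(inherits(kb, "interaction_kb"))
  rep <- list(n_input_rows = kb$n_input_rows,
              n_pairs = kb$n_pairs,
              n_dropped_minor = kb$n_dropped_minor,
              n_rejected_rows = length(kb$rejected_rows),
              rejected_rows = kb$rejected_rows)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
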