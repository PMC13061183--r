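# Free-text drug-name matching: brands and formulations are mapped to
# canonical generic concepts through a curated alias-pattern index, and
# non-systemic (topical/ophthalmic) formulations are flagged by keyword.

#' Default non-systemic formulation keywords
#'
#' Tokens that mark a line item as a non-systemic formulation. The screen
#' targets systemic exposure, so items whose name contains one of these as a
#' whole token are flagged `systemic = FALSE` and excluded from interaction
#' detection.
#'
#' @export
NONSYSTEMIC_KEYWORDS <- c("cream", "lotion", "drops", "ointment", "gel",
                          "topical", "shampoo")

#' Build an alias-pattern index over a drug-concept table
#'
#' Each concept contributes its canonical name plus any curated alias
#' patterns (brand names, formulation spellings). Matching is
#' case-insensitive substring containment on normalized text, with
#' longest-pattern-first precedence so that e.g. "losartan
#' potassium/hydrochlorothiazide" beats "losartan". A pattern claimed by two
#' concepts is a build error.
#'
#' @param concepts data.frame (or CSV path) with columns `canonical_name`,
#'   `aliases` (`|`-separated, may be empty), `is_top_list` (logical or 0/1).
#' @param nonsystemic_keywords character vector of formulation keywords.
#' @return object of class `alias_index`.
#' @export
build_alias_index <- function(concepts, nonsystemic_keywords = NONSYSTEMIC_KEYWORDS) {
  if (is.character(concepts) && length(concepts) == 1L) {
    concepts <- data.table::fread(concepts, colClasses = list(character = c(
      "canonical_name", "aliases")), encoding = "UTF-8")
  }
  concepts <- data.table::as.data.table(concepts)
  req <- c("canonical_name", "aliases", "is_top_list")
  miss <- setdiff(req, names(concepts))
  if (length(miss)) {
    stop(sprintf("concept table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(concepts) == 0L) stop("concept table is empty", call. = FALSE)
  if (length(nonsystemic_keywords) == 0L) {
    stop("nonsystemic_keywords must be non-empty", call. = FALSE)
  }
  kw <- normalize_drug_name(nonsystemic_keywords)
  if (any(!nzchar(kw))) stop("empty non-systemic keyword", call. = FALSE)

  canon <- normalize_drug_name(concepts$canonical_name)
  dup <- canon[duplicated(canon)]
  if (length(dup)) {
    stop(sprintf("duplicate canonical name(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  alias_lists <- strsplit(ifelse(is.na(concepts$aliases), "", concepts$aliases),
                          "|", fixed = TRUE)
  pat <- data.table::rbindlist(lapply(seq_along(canon), function(i) {
    p <- unique(c(canon[i], normalize_drug_name(alias_lists[[i]])))
    p <- p[nzchar(p)]
    data.table::data.table(pattern = p, concept = canon[i])
  }))
  coll <- pat[, list(n = length(unique(concept)),
                     who = paste(unique(concept), collapse = " / ")),
              by = "pattern"][n > 1L]
  if (nrow(coll)) {
    stop(sprintf("alias pattern(s) claimed by multiple concepts: %s",
                 paste(sprintf("'%s' (%s)", coll$pattern, coll$who),
                       collapse = "; ")), call. = FALSE)
  }
  # precedence: longest pattern first, ties by canonical-name order
  data.table::setorderv(pat, c("concept"))
  pat <- pat[order(-nchar(pattern), concept)]
  structure(list(patterns = pat,
                 concepts = data.table::data.table(
                   canonical_name = canon,
                   is_top_list = as.logical(concepts$is_top_list)),
                 nonsystemic_keywords = kw),
            class = "alias_index")
}

#' @export
print.alias_index <- function(x, ...) {
  cat("Alias index:", nrow(x$concepts), "concepts,",
      nrow(x$patterns), "patterns,",
      sum(x$concepts$is_top_list), "on the top list\n")
  invisible(x)
}

#' Match free-text drug names against an alias index
#'
#' Vectorized. A name matches the concept of the longest pattern occurring in
#' its normalized text (ties broken by canonical-name order); names with no
#' hit are retained as unmatched (they still count toward drug counts but can
#' never interact). Independently of matching, the name is flagged
#' non-systemic when any formulation keyword occurs as a whole token.
#'
#' @param index an `alias_index`.
#' @param raw_names character vector of free-text drug names.
#' @return data.table with columns `raw_name`, `concept` (NA when
#'   unmatched), `matched`, `systemic`.
#' @export
match_drug_names <- function(index, raw_names) {
  stopifnot(inherits(index, "alias_index"))
  if (any(!nzchar(trimws(raw_names)))) {
    stop("match_drug_names: empty raw drug name", call. = FALSE)
  }
  norm <- normalize_drug_name(raw_names)
  uq <- unique(norm)
  assigned <- rep(NA_character_, length(uq))
  open <- rep(TRUE, length(uq))
  pats <- index$patterns
  for (i in seq_len(nrow(pats))) {
    if (!any(open)) break
    hit <- open & grepl(pats$pattern[i], uq, fixed = TRUE)
    if (any(hit)) {
      assigned[hit] <- pats$concept[i]
      open[hit] <- FALSE
    }
  }
  # token-level non-systemic flag, independent of concept matching
  toks <- strsplit(uq, "[^a-z0-9]+")
  nonsys <- vapply(toks, function(t) any(t %in% index$nonsystemic_keywords),
                   logical(1))
  m <- match(norm, uq)
  data.table::data.table(raw_name = raw_names,
                         concept = assigned[m],
                         matched = !is.na(assigned[m]),
                         systemic = !nonsys[m])
}

#' Match a single drug name
#'
#' @param index an `alias_index`.
#' @param raw_name one free-text drug name.
#' @return one-row data.table as in [match_drug_names()].
#' @export
match_drug_name <- function(index, raw_name) {
  stopifnot(length(raw_name) == 1L)
  match_drug_names(index, raw_name)
}

#' Match report
#'
#' Totals plus the most frequent unmatched names (top 20 by frequency), for
#' auditing alias-table coverage.
#'
#' @param matches data.table from [match_drug_names()].
#' @param path optional JSON output path.
#' @return list report.
#' @export
match_report <- function(matches, path = NULL) {
  un <- matches[matched == FALSE,
                list(n = .N), by = "raw_name"][order(-n, raw_name)]
  rep <- list(n_inputs = nrow(matches),
              n_matched = sum(matches$matched),
              n_unmatched = sum(!matches$matched),
              n_nonsystemic = sum(!matches$systemic),
              top_unmatched = utils::head(un, 20L))
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows")
    return(invisible(rep))
  }
  rep
}
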