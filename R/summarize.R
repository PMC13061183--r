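# Descriptive statistics: prevalence at prescription and patient level,
# severity shares, the eight-category profile distribution, pair coverage,
# top-k interaction tables, and stratified summaries with group tests.

#' Round half away from zero
#'
#' Display rounding used for every reported percentage: 12.345 -> 12.35,
#' -12.345 -> -12.35 (base `round` rounds half to even). Display-only; all
#' internal arithmetic keeps full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(num, den) 100 * num / den

summary_stat <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE))
  list(mean = mean(x), sd = sd(x), median = q[2],
       iqr_low = q[1], iqr_high = q[3], n = length(x))
}

#' Prevalence summary at prescription and patient level
#'
#' Prescription-level prevalence is the share of prescriptions with at least
#' one detected interaction; patient-level prevalence is the share of
#' patients with at least one interacting prescription. Two mean-interaction
#' variants are reported because both denominators occur in practice: over
#' all prescriptions and over interacting prescriptions only.
#'
#' @param sr a `screen_result` derived from `cohort`.
#' @param cohort the screened `ddi_cohort`.
#' @return list with counts, percentages (full precision and display-rounded
#'   `*_pct`), and the two `mean_interactions_*` summary stats.
#' @export
prevalence_summary <- function(sr, cohort) {
  stopifnot(inherits(sr, "screen_result"), inherits(cohort, "ddi_cohort"))
  pres <- cohort$prescriptions
  if (nrow(pres) == 0L) stop("empty cohort", call. = FALSE)
  pp <- sr$per_prescription
  n_pres <- nrow(pres)
  with_ddi <- pp[n_interactions > 0L, prescription_id]
  n_with <- length(with_ddi)

  pat <- pres[, list(prescription_id, patient_id)]
  n_patients <- length(unique(pat$patient_id))
  pat_with <- unique(pat[prescription_id %in% with_ddi, patient_id])

  list(n_prescriptions = n_pres,
       n_with_ddi = n_with,
       prescription_prevalence_pct = round_half_up(pct(n_with, n_pres)),
       prescription_prevalence_raw = pct(n_with, n_pres),
       n_patients = n_patients,
       n_patients_with_ddi = length(pat_with),
       patient_prevalence_pct = round_half_up(pct(length(pat_with), n_patients)),
       patient_prevalence_raw = pct(length(pat_with), n_patients),
       interactions_total = nrow(sr$interactions),
       mean_interactions_all = summary_stat(pp$n_interactions),
       mean_interactions_interacting =
         if (n_with > 0) summary_stat(pp[n_interactions > 0L, n_interactions])
         else NULL)
}

#' Severity distribution
#'
#' Instance-level shares (each detected interaction counted once) and
#' per-prescription any-severity rates (share of prescriptions containing at
#' least one interaction of that severity).
#'
#' @param sr a `screen_result`.
#' @return list with `instance_counts`, `instance_shares_pct` (NULL when no
#'   interactions: shares are undefined, not zero), and
#'   `prescription_rates_pct`.
#' @export
severity_distribution <- function(sr) {
  stopifnot(inherits(sr, "screen_result"))
  total <- sum(sr$totals)
  shares <- if (total > 0) round_half_up(pct(sr$totals, total)) else NULL
  rates <- vapply(SEVERITY_LEVELS, function(s) {
    n <- length(unique(sr$interactions[severity == s, prescription_id]))
    round_half_up(pct(n, sr$n_prescriptions))
  }, numeric(1))
  list(instance_counts = sr$totals,
       instance_shares_pct = shares,
       prescription_rates_pct = rates)
}

#' Eight-category severity-profile distribution
#'
#' Percentages over ALL prescriptions; the "none" category is the complement
#' of prescription-level prevalence.
#'
#' @param sr a `screen_result`.
#' @return data.table with `profile`, `n`, `pct` (display-rounded) and
#'   `pct_raw`.
#' @export
profile_distribution <- function(sr) {
  stopifnot(inherits(sr, "screen_result"))
  if (sr$n_prescriptions == 0L) stop("empty cohort", call. = FALSE)
  tab <- sr$per_prescription[, list(n = .N), by = "profile"]
  full <- data.table::data.table(profile = factor(PROFILE_LEVELS,
                                                  levels = PROFILE_LEVELS))
  tab <- tab[full, on = "profile"]
  tab[is.na(n), n := 0L]
  tab[, pct_raw := pct(n, sr$n_prescriptions)]
  tab[, pct := round_half_up(pct_raw)]
  tab[, list(profile, n, pct, pct_raw)]
}

#' Pair coverage
#'
#' How many distinct interacting pairs were observed, against the number of
#' pairs in the knowledge base. The denominator is taken from the loaded KB
#' (`kb$n_pairs`) rather than a combinatorial formula: with combination
#' products as first-class concepts the KB pair universe is not C(n, 2).
#'
#' @param sr a `screen_result`.
#' @param kb an `interaction_kb`.
#' @return list(observed_unique_pairs, denominator, pct, pct_raw).
#' @export
pair_coverage <- function(sr, kb) {
  stopifnot(inherits(sr, "screen_result"), inherits(kb, "interaction_kb"))
  if (kb$n_pairs == 0L) stop("empty knowledge base", call. = FALSE)
  obs <- nrow(sr$per_pair)
  list(observed_unique_pairs = obs,
       denominator = kb$n_pairs,
       pct = round_half_up(pct(obs, kb$n_pairs)),
       pct_raw = pct(obs, kb$n_pairs))
}

#' Top interacting pairs
#'
#' Ranked by descending frequency (ties broken by canonical pair name),
#' optionally within each severity stratum. The percentage column is the
#' pair's share of all interaction instances.
#'
#' @param sr a `screen_result`.
#' @param k rows to keep (per severity stratum when stratified).
#' @param stratify_by_severity rank within severity strata (default TRUE;
#'   strata print moderate, major, contraindicated in that order).
#' @return data.table `severity, first, second, frequency, pct, pct_raw`.
#' @export
top_interactions <- function(sr, k = 10L, stratify_by_severity = TRUE) {
  stopifnot(inherits(sr, "screen_result"), k >= 1L)
  total <- sum(sr$totals)
  tab <- data.table::copy(sr$per_pair)
  tab[, pct_raw := pct(frequency, total)]
  tab[, pct := round_half_up(pct_raw)]
  if (stratify_by_severity) {
    tab[, rank := SEVERITY_RANKS[severity]]
    tab <- tab[order(rank, -frequency, first, second)]
    tab <- tab[, utils::head(.SD, k), by = "severity"]
  } else {
    tab <- tab[order(-frequency, first, second)]
    tab <- utils::head(tab, k)
  }
  tab[, list(severity, first, second, frequency, pct, pct_raw)]
}

#' Stratified summary table with group tests
#'
#' Per stratum (sex, age group, or specialty): prescription count and share,
#' count/% with any interaction, interactions per prescription (mean +/- SD,
#' over all prescriptions in the stratum), counts/% with contraindicated /
#' major / moderate interactions, polypharmacy %, and medications per
#' prescription (mean +/- SD). Group tests: chi-squared on the
#' any-interaction proportion; for the interaction-count mean, Student's t
#' (2 strata) or one-way ANOVA (>2) when a Shapiro-Wilk pre-check (on a
#' subsample capped at 5,000) does not reject normality, otherwise the
#' rank-based fallback (Wilcoxon / Kruskal-Wallis).
#'
#' @param sr a `screen_result`.
#' @param cohort the screened `ddi_cohort`.
#' @param stratifier one of "sex", "age_group", "specialty".
#' @param top_n for specialty: keep the highest-volume `top_n` strata
#'   (default 10); ignored otherwise.
#' @return list with `table` (data.table, one row per stratum) and `tests`
#'   (list of test results; NULL with an explanation when <2 usable strata).
#' @export
stratified_summary <- function(sr, cohort,
                               stratifier = c("sex", "age_group", "specialty"),
                               top_n = 10L) {
  stratifier <- match.arg(stratifier)
  stopifnot(inherits(sr, "screen_result"), inherits(cohort, "ddi_cohort"))
  pres <- data.table::copy(cohort$prescriptions)
  pp <- sr$per_prescription
  pres <- pp[pres, on = "prescription_id"]

  sev_by_pres <- lapply(SEVERITY_LEVELS, function(s)
    unique(sr$interactions[severity == s, prescription_id]))
  names(sev_by_pres) <- SEVERITY_LEVELS
  for (s in SEVERITY_LEVELS) {
    pres[, (paste0("has_", s)) := prescription_id %in% sev_by_pres[[s]]]
  }
  pres[, stratum := as.character(pres[[stratifier]])]

  n_total <- nrow(pres)
  tab <- pres[, list(
    n_prescriptions = .N,
    pct_of_total = round_half_up(pct(.N, n_total)),
    n_with_ddi = sum(n_interactions > 0L),
    pct_with_ddi = round_half_up(pct(sum(n_interactions > 0L), .N)),
    interactions_mean = mean(n_interactions),
    interactions_sd = sd(n_interactions),
    n_contra = sum(has_contraindicated),
    pct_contra = round_half_up(pct(sum(has_contraindicated), .N)),
    n_major = sum(has_major),
    pct_major = round_half_up(pct(sum(has_major), .N)),
    n_moderate = sum(has_moderate),
    pct_moderate = round_half_up(pct(sum(has_moderate), .N)),
    n_polypharmacy = sum(polypharmacy),
    pct_polypharmacy = round_half_up(pct(sum(polypharmacy), .N)),
    drugs_mean = mean(drug_count),
    drugs_sd = sd(drug_count)
  ), by = "stratum"]
  data.table::setorderv(tab, "n_prescriptions", -1L)
  if (stratifier == "specialty" && nrow(tab) > top_n) {
    tab <- utils::head(tab, top_n)
    pres <- pres[stratum %in% tab$stratum]
  }
  if (stratifier == "age_group") {
    tab <- tab[order(match(stratum, AGE_GROUP_LEVELS))]
  }

  usable <- tab[n_prescriptions > 0L, stratum]
  tests <- if (length(usable) < 2L) {
    list(skipped = TRUE, reason = "fewer than two non-empty strata")
  } else {
    g <- pres[stratum %in% usable]
    list(skipped = FALSE,
         any_ddi_chisq = run_chisq(g$stratum, g$n_interactions > 0L),
         count_location = run_location_test(g$n_interactions, g$stratum),
         polypharmacy_chisq = run_chisq(g$stratum, g$polypharmacy))
  }
  list(stratifier = stratifier, table = tab[], tests = tests)
}

run_chisq <- function(group, flag) {
  ct <- table(group, flag)
  res <- suppressWarnings(chisq.test(ct, correct = FALSE))
  list(test_name = "chi_squared", statistic = unname(res$statistic),
       df = unname(res$parameter), p_value = unname(res$p.value),
       p_display = format_p(res$p.value))
}

run_location_test <- function(y, group) {
  group <- factor(group)
  # normality gate: Shapiro-Wilk on a subsample capped at 5,000
  ys <- if (length(y) > 5000L) y[seq(1L, length(y), length.out = 5000L)] else y
  sw <- if (length(unique(ys)) > 1L && length(ys) >= 3L) {
    suppressWarnings(shapiro.test(ys))
  } else NULL
  normal <- !is.null(sw) && sw$p.value > 0.05
  two <- nlevels(group) == 2L
  res <- if (normal && two) {
    r <- t.test(y ~ group)
    list(test_name = "t", statistic = unname(r$statistic),
         df = unname(r$parameter), p_value = r$p.value)
  } else if (normal) {
    r <- summary(aov(y ~ group))[[1]]
    list(test_name = "anova", statistic = r[["F value"]][1],
         df = r[["Df"]][1], p_value = r[["Pr(>F)"]][1])
  } else if (two) {
    r <- suppressWarnings(wilcox.test(y ~ group))
    list(test_name = "wilcoxon", statistic = unname(r$statistic),
         df = NA_real_, p_value = r$p.value)
  } else {
    r <- kruskal.test(y ~ group)
    list(test_name = "kruskal_wallis", statistic = unname(r$statistic),
         df = unname(r$parameter), p_value = r$p.value)
  }
  res$normality_p <- if (is.null(sw)) NA_real_ else sw$p.value
  res$p_display <- format_p(res$p_value)
  res
}

#' Display formatting for p-values
#'
#' Exact below 0.001 is reported as "<0.001", the usual table convention.
#'
#' @param p numeric p-values.
#' @return character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", formatC(p, digits = 3, format = "f"))
}
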