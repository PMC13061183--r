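# Seeded synthetic-data generator: prescription cohorts and interaction
# knowledge bases with a recorded ground truth, emulating the structure of
# national outpatient claims (multi-drug prescriptions, brand aliasing,
# topical formulations, a polypharmacy-heavy drug-count distribution) so the
# whole pipeline is testable without proprietary data.

#' Simulation configuration
#'
#' Defaults encode the cohort structure reported for a national outpatient
#' claims year: ~2.4 prescriptions per patient, ~4.9 drugs per prescription
#' with ~47.5% polypharmacy (an overdispersed, shifted negative-binomial
#' count), the four-age-group mixture, a 58% female share, specialty volumes
#' dominated by general practice, and a ~1.2% missing-demographics rate.
#' Sizes (`n_patients`) are set per use; rates and moments are the stated
#' world and should not be tuned per test.
#'
#' @param seed integer seed (mandatory; all generation is deterministic).
#' @param n_patients number of patients.
#' @param rx_per_patient list(mean, size): shifted negative binomial,
#'   truncated at >= 1 prescription.
#' @param drug_count list(size, polypharmacy_target): shifted negative
#'   binomial truncated at >= 1 drug; the NB mean is calibrated by bisection
#'   so that P(count >= 5) hits the polypharmacy target.
#' @param age_mix patient-level probabilities over the four age groups.
#' @param female_share probability a patient is female.
#' @param specialties named numeric vector of specialty volume shares
#'   (normalised internally).
#' @param n_drugs number of simple drug concepts.
#' @param n_combos number of combination-product concepts (their names join
#'   two component names with "/"; they are concepts in their own right).
#' @param top_fraction fraction of concepts flagged on the reference top
#'   list (the most-prescribed ones by sampling weight).
#' @param kb_density named fractions of all concept pairs assigned each
#'   severity (contraindicated, major, moderate); must sum to <= 1.
#' @param minor_density fraction of pairs emitted as "minor" KB rows (these
#'   must be dropped at ingestion).
#' @param duplicate_row_rate fraction of KB pairs re-emitted as a swapped,
#'   lower-or-equal-severity duplicate row (exercises max-severity
#'   resolution).
#' @param n_aliases_per_drug brand aliases fabricated per concept.
#' @param brand_rate probability a line item is written under a brand alias.
#' @param decorate_rate probability a line item carries dose/form text.
#' @param topical_rate probability a prescription gains one extra
#'   non-systemic (topical) line item.
#' @param unknown_rate probability a line item is an unknown (unmatched)
#'   drug name.
#' @param missing_demo_rate probability a prescription has sex or age
#'   blanked.
#' @param specialty_pref_conc Dirichlet concentration for specialty-level
#'   drug preference vectors (smaller = more specialty-specific prescribing).
#' @param model_truth list of generating parameters for
#'   [generate_model_truth_data()]: `beta` (named: intercept, drug_count,
#'   age_19_39, age_40_64, age_65_100, sex_female), `sigma` (noise SD),
#'   `beta_interaction` (named drug-count slope increments per age group),
#'   `logit` (named log-odds scale: intercept, drug_count, age_19_39,
#'   age_40_64, age_65_100, sex_female).
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(seed,
                       n_patients = 2000L,
                       rx_per_patient = list(mean = 2.41, size = 1.87),
                       drug_count = list(size = 7.3, polypharmacy_target = 0.475),
                       age_mix = c(`0-18` = 0.1384, `19-39` = 0.1978,
                                   `40-64` = 0.4297, `65-100` = 0.2341),
                       female_share = 0.5796,
                       specialties = c("general practice" = 0.4207,
                                       "internal medicine" = 0.1732,
                                       "cardiology" = 0.0779,
                                       "emergency medicine" = 0.0645,
                                       "psychiatry" = 0.0427,
                                       "orthopedics" = 0.0364,
                                       "neurology" = 0.0354,
                                       "obstetrics and gynecology" = 0.0214,
                                       "pediatrics" = 0.0207,
                                       "urology" = 0.0162,
                                       "dermatology" = 0.0309,
                                       "ophthalmology" = 0.0300,
                                       "radiation oncology" = 0.0300),
                       n_drugs = 60L,
                       n_combos = 3L,
                       top_fraction = 0.8,
                       kb_density = c(contraindicated = 0.004, major = 0.047,
                                      moderate = 0.025),
                       minor_density = 0.05,
                       duplicate_row_rate = 0.10,
                       n_aliases_per_drug = 2L,
                       brand_rate = 0.30,
                       decorate_rate = 0.40,
                       topical_rate = 0.05,
                       unknown_rate = 0.02,
                       missing_demo_rate = 0.0116,
                       specialty_pref_conc = 0.5,
                       model_truth = default_model_truth()) {
  if (missing(seed)) stop("sim_config requires a seed", call. = FALSE)
  probs <- c(female_share, kb_density, minor_density, duplicate_row_rate,
             brand_rate, decorate_rate, topical_rate, unknown_rate,
             missing_demo_rate, top_fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(age_mix) - 1) < 1e-8,
            all(specialties > 0),
            n_drugs >= 3L,
            drug_count$polypharmacy_target > 0,
            drug_count$polypharmacy_target < 1)
  if (sum(kb_density) > 1) stop("kb_density fractions sum above 1", call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              rx_per_patient = rx_per_patient, drug_count = drug_count,
              age_mix = age_mix, female_share = female_share,
              specialties = specialties / sum(specialties),
              n_drugs = as.integer(n_drugs), n_combos = as.integer(n_combos),
              top_fraction = top_fraction, kb_density = kb_density,
              minor_density = minor_density,
              duplicate_row_rate = duplicate_row_rate,
              n_aliases_per_drug = as.integer(n_aliases_per_drug),
              brand_rate = brand_rate, decorate_rate = decorate_rate,
              topical_rate = topical_rate, unknown_rate = unknown_rate,
              missing_demo_rate = missing_demo_rate,
              specialty_pref_conc = specialty_pref_conc,
              model_truth = model_truth)
  class(cfg) <- "sim_config"
  cfg
}

#' Default model-generating truth
#'
#' Effect sizes for outcome-generating simulations: the drug-count slope,
#' graded age effects, and a small negative female effect for the count
#' model; slope increments by age for the interaction model; and odds ratios
#' (log scale) for the contraindication model.
#'
#' @return list(beta, sigma, beta_interaction, logit).
#' @export
default_model_truth <- function() {
  list(beta = c(intercept = -1.5, drug_count = 0.460,
                age_19_39 = 0.105, age_40_64 = 0.373, age_65_100 = 0.520,
                sex_female = -0.042),
       sigma = 1.8,
       beta_interaction = c(age_19_39 = 0.057, age_40_64 = 0.180,
                            age_65_100 = 0.279),
       logit = c(intercept = -4.0, drug_count = log(1.275),
                 age_19_39 = log(2.796), age_40_64 = log(2.245),
                 age_65_100 = log(1.345), sex_female = log(1.032)))
}

# NB-mean calibration: find mu of the (non-shifted) NB part so that the
# shifted count 1 + NB(size, mu) hits the polypharmacy target P(X >= 5).
calibrate_nb_mu <- function(size, target, threshold = 5L) {
  f <- function(mu) (1 - pnbinom(threshold - 2L, size = size, mu = mu)) - target
  lo <- 1e-6; hi <- 1e4
  if (f(hi) < 0) stop("infeasible polypharmacy target for this dispersion",
                      call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

r_shifted_nb <- function(n, size, mu) {
  1L + rnbinom(n, size = size, mu = mu)
}

#' @importFrom stats pnbinom rgamma
NULL

rdirichlet1 <- function(k, conc) {
  g <- rgamma(k, shape = conc, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

concept_name <- function(i) sprintf("drug%03d", i)
alias_name <- function(i, j) sprintf("BX%03d%s", i, LETTERS[j])

#' Generate a synthetic knowledge base and concept/alias table
#'
#' Fabricates `n_drugs` generic concepts (plus `n_combos` combination
#' products), deterministic brand aliases, and a pairwise severity-graded KB
#' drawn at the configured densities. The emitted KB rows include "minor"
#' rows and swapped lower-severity duplicates on purpose, so the loader's
#' drop/resolve behaviour is exercised; the `truth` record stores the
#' resolved pair map that loading must reproduce.
#'
#' @param cfg a `sim_config`.
#' @return list with `kb_rows` (data.table `drug_a,drug_b,severity` as a KB
#'   CSV would contain), `concepts` (data.table
#'   `canonical_name,aliases,is_top_list`), `truth` (list: `pairs` resolved
#'   data.table, `n_minor_rows`, `weights` global sampling weights).
#' @export
generate_kb <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  names <- concept_name(seq_len(cfg$n_drugs))
  if (cfg$n_combos > 0L) {
    comp <- matrix(sample(names, 2L * cfg$n_combos), ncol = 2L)
    combos <- apply(comp, 1L, function(r) paste(sort(r), collapse = "/"))
    names <- c(names, unique(combos))
  }
  n <- length(names)
  aliases <- vapply(seq_len(n), function(i) {
    if (cfg$n_aliases_per_drug == 0L) return("")
    paste(alias_name(i, seq_len(cfg$n_aliases_per_drug)), collapse = "|")
  }, character(1))
  # popularity: Zipf-ish global weights; the top list = heaviest concepts
  w <- 1 / seq_len(n)^0.8
  w <- sample(w)  # decouple weight from id order
  n_top <- max(1L, round(cfg$top_fraction * n))
  is_top <- rank(-w, ties.method = "first") <= n_top
  concepts <- data.table::data.table(canonical_name = names,
                                     aliases = aliases,
                                     is_top_list = is_top)

  idx <- utils::combn(n, 2L)
  pairs <- canonical_pair_vec(names[idx[1L, ]], names[idx[2L, ]])
  dens <- cfg$kb_density
  u <- runif(nrow(pairs))
  cut1 <- dens[["contraindicated"]]
  cut2 <- cut1 + dens[["major"]]
  cut3 <- cut2 + dens[["moderate"]]
  sev <- rep(NA_character_, nrow(pairs))
  sev[u < cut1] <- "contraindicated"
  sev[u >= cut1 & u < cut2] <- "major"
  sev[u >= cut2 & u < cut3] <- "moderate"
  keep <- !is.na(sev)
  truth_pairs <- pairs[keep]
  truth_pairs[, severity := sev[keep]]
  data.table::setkeyv(truth_pairs, c("first", "second"))

  rows <- truth_pairs[, list(drug_a = first, drug_b = second, severity)]
  # swapped duplicates at equal-or-lower severity (max-severity must win)
  ndup <- round(cfg$duplicate_row_rate * nrow(rows))
  if (ndup > 0L && nrow(rows) > 0L) {
    di <- sample.int(nrow(rows), min(ndup, nrow(rows)))
    lower <- vapply(rows$severity[di], function(s) {
      r <- SEVERITY_RANKS[[s]]
      SEVERITY_LEVELS[sample.int(r, 1L)]
    }, character(1))
    dup <- data.table::data.table(drug_a = rows$drug_b[di],
                                  drug_b = rows$drug_a[di],
                                  severity = lower)
    rows <- rbind(rows, dup)
  }
  n_minor <- 0L
  if (cfg$minor_density > 0 && any(!keep)) {
    free <- which(!keep)
    n_minor <- min(length(free), round(cfg$minor_density * nrow(pairs)))
    if (n_minor > 0L) {
      mi <- sample(free, n_minor)
      rows <- rbind(rows, data.table::data.table(drug_a = pairs$first[mi],
                                                 drug_b = pairs$second[mi],
                                                 severity = "minor"))
    }
  }
  rows <- rows[sample.int(nrow(rows))]
  list(kb_rows = rows[],
       concepts = concepts,
       truth = list(pairs = truth_pairs[], n_minor_rows = n_minor,
                    weights = setNames(w, names)))
}

# Brute-force interaction oracle: plain double loop over a concept set
# against a hashed pair map. Used only to record ground truth.
oracle_env <- function(truth_pairs) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(truth_pairs)) {
    k <- paste(truth_pairs$first, truth_pairs$second, sep = "\r")
    for (i in seq_along(k)) assign(k[i], truth_pairs$severity[i], envir = e)
  }
  e
}

oracle_detect <- function(concepts, env) {
  cs <- sort(unique(concepts))
  out <- list()
  if (length(cs) >= 2L) {
    for (i in seq_len(length(cs) - 1L)) {
      for (j in seq((i + 1L), length(cs))) {
        key <- paste(cs[i], cs[j], sep = "\r")
        s <- if (exists(key, envir = env, inherits = FALSE))
          get(key, envir = env) else NULL
        if (!is.null(s)) {
          out[[length(out) + 1L]] <- list(first = cs[i], second = cs[j],
                                          severity = s)
        }
      }
    }
  }
  data.table::rbindlist(out)
}

#' Generate a synthetic prescription cohort
#'
#' Draws patients (age, sex), their prescriptions (specialty, drug count),
#' and line items (specialty-preferential drug sampling without replacement
#' within a prescription), then roughens the records the way claims data
#' are rough: brand-alias substitution, dose/form decoration, injected
#' topical items, unknown drug names, and missing demographics. The truth
#' record carries, per prescription, the planted systemic concepts, the
#' expected exclusion bucket, and the expected interactions computed with a
#' brute-force pair oracle over the KB truth.
#'
#' @param cfg a `sim_config`.
#' @param kb result of [generate_kb()] (regenerated from `cfg` when NULL).
#' @param csv_path optional path; when given, line items are written as a
#'   prescription CSV (`prescription_id,patient_id,age,sex,specialty,
#'   drug_name`).
#' @param truth_path optional path for the truth record as JSON.
#' @return list with `items` (line-item data.table in CSV dialect),
#'   `truth` (list: `prescriptions` data.table with expected bucket and
#'   interaction count, `interactions` data.table, `flow` expected bucket
#'   totals), and `kb`.
#' @export
generate_cohort <- function(cfg, kb = NULL, csv_path = NULL, truth_path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(kb)) kb <- generate_kb(cfg)
  set.seed(cfg$seed + 1L)

  concepts <- kb$concepts
  n_concepts <- nrow(concepts)
  weights <- kb$truth$weights

  # specialty formularies: Dirichlet-perturbed preference over concepts
  spn <- names(cfg$specialties)
  pref <- lapply(spn, function(s) {
    p <- weights * rdirichlet1(n_concepts, cfg$specialty_pref_conc)
    p / sum(p)
  })
  names(pref) <- spn

  n_pat <- cfg$n_patients
  pat_age_group <- sample(names(cfg$age_mix), n_pat, TRUE, prob = cfg$age_mix)
  age_lo <- c(`0-18` = 0L, `19-39` = 19L, `40-64` = 40L, `65-100` = 65L)
  age_hi <- c(`0-18` = 18L, `19-39` = 39L, `40-64` = 64L, `65-100` = 100L)
  pat_age <- age_lo[pat_age_group] +
    floor(runif(n_pat) * (age_hi[pat_age_group] - age_lo[pat_age_group] + 1L))
  pat_sex <- ifelse(runif(n_pat) < cfg$female_share, "F", "M")
  pat_id <- sprintf("P%06d", seq_len(n_pat))

  mu_rx <- cfg$rx_per_patient$mean - 1
  n_rx <- r_shifted_nb(n_pat, cfg$rx_per_patient$size, mu_rx)
  pres_pat <- rep(seq_len(n_pat), n_rx)
  n_pres <- length(pres_pat)
  pres_id <- sprintf("RX%07d", seq_len(n_pres))
  pres_spec <- sample(spn, n_pres, TRUE, prob = cfg$specialties)

  mu_dc <- calibrate_nb_mu(cfg$drug_count$size,
                           cfg$drug_count$polypharmacy_target)
  dcount <- r_shifted_nb(n_pres, cfg$drug_count$size, mu_dc)
  dcount <- pmin(dcount, n_concepts)

  # draw planted systemic concepts per prescription
  spec_idx <- match(pres_spec, spn)
  planted <- vector("list", n_pres)
  for (i in seq_len(n_pres)) {
    planted[[i]] <- concepts$canonical_name[
      sample.int(n_concepts, dcount[i], prob = pref[[spec_idx[i]]])]
  }

  miss <- runif(n_pres) < cfg$missing_demo_rate
  miss_field <- ifelse(runif(n_pres) < 0.5, "age", "sex")
  topical <- runif(n_pres) < cfg$topical_rate

  items <- data.table::data.table(
    prescription_id = rep(pres_id, dcount),
    patient_id = rep(pat_id[pres_pat], dcount),
    age = rep(pat_age[pres_pat], dcount),
    sex = rep(pat_sex[pres_pat], dcount),
    specialty = rep(pres_spec, dcount),
    drug_name = unlist(planted),
    concept_truth = unlist(planted),
    systemic_truth = TRUE)

  # unknown (unmatched) items replace planted ones at the configured rate;
  # they are inert: counted in drug totals but never interacting
  unk <- runif(nrow(items)) < cfg$unknown_rate
  if (any(unk)) {
    items$drug_name[unk] <- sprintf("ZZUNK%05d", sample.int(99999L, sum(unk),
                                                            replace = TRUE))
    items$concept_truth[unk] <- NA_character_
  }

  # brand substitution + decoration on known items
  alias_tab <- strsplit(concepts$aliases, "|", fixed = TRUE)
  names(alias_tab) <- concepts$canonical_name
  known <- which(!is.na(items$concept_truth))
  sub <- known[runif(length(known)) < cfg$brand_rate]
  if (length(sub)) {
    items$drug_name[sub] <- vapply(items$concept_truth[sub], function(cn) {
      al <- alias_tab[[cn]]
      if (length(al) && nzchar(al[1L])) sample(al, 1L) else cn
    }, character(1))
  }
  dec <- runif(nrow(items)) < cfg$decorate_rate
  forms <- c("TAB", "CAP", "AMP", "SYRUP")
  doses <- c("5MG", "10MG", "50MG", "100MG", "500MG")
  items$drug_name[dec] <- paste(toupper(items$drug_name[dec]),
                                sample(doses, sum(dec), TRUE),
                                sample(forms, sum(dec), TRUE))

  # inject one topical line item into flagged prescriptions
  if (any(topical)) {
    ti <- which(topical)
    tdrug <- concepts$canonical_name[sample.int(n_concepts, length(ti),
                                                replace = TRUE)]
    tkw <- sample(c("cream", "lotion", "drops", "ointment"), length(ti), TRUE)
    titems <- data.table::data.table(
      prescription_id = pres_id[ti],
      patient_id = pat_id[pres_pat[ti]],
      age = pat_age[pres_pat[ti]],
      sex = pat_sex[pres_pat[ti]],
      specialty = pres_spec[ti],
      drug_name = paste(toupper(tdrug), toupper(tkw), "1%"),
      concept_truth = tdrug,
      systemic_truth = FALSE)
    items <- rbind(items, titems)
  }
  data.table::setorderv(items, "prescription_id")

  # blank demographics at the prescription level
  if (any(miss)) {
    mp <- pres_id[miss]
    blank_age <- mp[miss_field[miss] == "age"]
    blank_sex <- mp[miss_field[miss] == "sex"]
    items[prescription_id %in% blank_age, age := NA_integer_]
    items[prescription_id %in% blank_sex, sex := ""]
  }

  # ground truth: bucket per prescription (first-match order), interactions
  top_set <- concepts$canonical_name[concepts$is_top_list]
  env <- oracle_env(kb$truth$pairs)
  # concepts per prescription from the item table (after unknown substitution)
  known_items <- items[systemic_truth == TRUE & !is.na(concept_truth),
                       list(prescription_id, concept_truth)]
  sys_by_pres <- split(known_items$concept_truth, known_items$prescription_id)
  # systemic item count includes unknowns (inert but counted)
  syscount <- items[systemic_truth == TRUE, .N, by = "prescription_id"]
  sysc <- setNames(syscount$N, syscount$prescription_id)

  bucket <- character(n_pres)
  ints <- vector("list", n_pres)
  for (i in seq_len(n_pres)) {
    pid <- pres_id[i]
    cs <- sys_by_pres[[pid]]
    if (miss[i]) {
      bucket[i] <- "missing_demo"
    } else if (sysc[[pid]] < 2L) {
      bucket[i] <- "single_drug"
    } else if (!any(cs %in% top_set)) {
      bucket[i] <- "no_top_drug"
    } else {
      bucket[i] <- "retained"
      det <- oracle_detect(cs, env)
      if (nrow(det)) {
        det[, prescription_id := pid]
        ints[[i]] <- det
      }
    }
  }
  truth_int <- data.table::rbindlist(ints)
  if (nrow(truth_int)) {
    data.table::setcolorder(truth_int, c("prescription_id", "first", "second",
                                         "severity"))
    data.table::setorderv(truth_int, c("prescription_id", "first", "second"))
  } else {
    truth_int <- empty_interactions()
  }
  n_int <- if (nrow(truth_int))
    truth_int[, .N, by = "prescription_id"] else NULL
  truth_pres <- data.table::data.table(
    prescription_id = pres_id, patient_id = pat_id[pres_pat],
    specialty = pres_spec, bucket = bucket,
    drug_count = unname(sysc[pres_id]))
  truth_pres[, n_interactions := 0L]
  if (!is.null(n_int)) {
    truth_pres[n_int, n_interactions := i.N, on = "prescription_id"]
  }
  truth_pres[bucket != "retained", n_interactions := NA_integer_]
  flow <- as.list(table(factor(bucket, levels = c("missing_demo", "single_drug",
                                                  "no_top_drug", "retained"))))
  names(flow) <- paste0("n_", names(flow))
  flow$n_input <- n_pres

  out_items <- items[, list(prescription_id, patient_id,
                            age = as.character(age),
                            sex, specialty, drug_name)]
  out_items[is.na(age) | age == "NA", age := ""]
  if (!is.null(csv_path)) data.table::fwrite(out_items, csv_path)
  truth <- list(prescriptions = truth_pres[], interactions = truth_int[],
                flow = flow)
  if (!is.null(truth_path)) {
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE,
                         dataframe = "rows", na = "null")
  }
  list(items = out_items[], truth = truth, kb = kb)
}

#' Generate a design table with outcomes drawn from stated model truth
#'
#' Covariates (drug count, age group, sex, specialty) are drawn as in
#' [generate_cohort()]; the outcome is then generated directly from the
#' configured truth: linear predictor + Gaussian noise for the count model
#' (with optional drug-count-by-age slope increments), Bernoulli(logistic)
#' for the contraindication model.
#'
#' @param cfg a `sim_config` (uses its `model_truth` block).
#' @param n number of prescriptions (rows).
#' @param kind "linear", "interaction", or "logistic".
#' @return a `ddi_design` whose `data` carries `ddi_count` / `any_contra`
#'   outcomes, plus attribute `truth` (the generating parameters).
#' @export
generate_model_truth_data <- function(cfg, n = 20000L,
                                      kind = c("linear", "interaction",
                                               "logistic")) {
  stopifnot(inherits(cfg, "sim_config"))
  kind <- match.arg(kind)
  mt <- cfg$model_truth
  set.seed(cfg$seed + 2L)
  n <- as.integer(n)

  age_group <- factor(sample(names(cfg$age_mix), n, TRUE, prob = cfg$age_mix),
                      levels = AGE_GROUP_LEVELS)
  sex <- factor(ifelse(runif(n) < cfg$female_share, "female", "male"),
                levels = c("male", "female"))
  specialty <- stats::relevel(
    factor(sample(names(cfg$specialties), n, TRUE, prob = cfg$specialties)),
    "general practice")
  mu_dc <- calibrate_nb_mu(cfg$drug_count$size,
                           cfg$drug_count$polypharmacy_target)
  drug_count <- as.numeric(r_shifted_nb(n, cfg$drug_count$size, mu_dc))

  b <- mt$beta
  age_eff <- c(`0-18` = 0, `19-39` = b[["age_19_39"]],
               `40-64` = b[["age_40_64"]], `65-100` = b[["age_65_100"]])
  lp <- b[["intercept"]] + b[["drug_count"]] * drug_count +
    age_eff[as.character(age_group)] +
    ifelse(sex == "female", b[["sex_female"]], 0)

  d <- data.table::data.table(
    prescription_id = sprintf("RX%07d", seq_len(n)),
    patient_id = sprintf("P%06d", seq_len(n)),
    drug_count = drug_count, age_group = age_group, sex = sex,
    specialty = specialty)
  if (kind == "linear") {
    d[, ddi_count := lp + rnorm(n, 0, mt$sigma)]
    d[, any_contra := FALSE]
  } else if (kind == "interaction") {
    inc <- c(`0-18` = 0, `19-39` = mt$beta_interaction[["age_19_39"]],
             `40-64` = mt$beta_interaction[["age_40_64"]],
             `65-100` = mt$beta_interaction[["age_65_100"]])
    lpi <- lp + inc[as.character(age_group)] * drug_count
    d[, ddi_count := lpi + rnorm(n, 0, mt$sigma)]
    d[, any_contra := FALSE]
  } else {
    g <- mt$logit
    age_g <- c(`0-18` = 0, `19-39` = g[["age_19_39"]],
               `40-64` = g[["age_40_64"]], `65-100` = g[["age_65_100"]])
    eta <- g[["intercept"]] + g[["drug_count"]] * drug_count +
      age_g[as.character(age_group)] +
      ifelse(sex == "female", g[["sex_female"]], 0)
    d[, any_contra := rbinom(n, 1L, plogis(eta)) == 1L]
    d[, ddi_count := 0]
  }
  dsgn <- structure(list(data = d[],
                         dropped_specialties = integer(0),
                         n_dropped_rows = 0L,
                         references = c(sex = "male", age_group = "0-18",
                                        specialty = "general practice")),
                    class = "ddi_design")
  attr(dsgn, "truth") <- mt
  dsgn
}
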