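# Regression models of interaction burden: OLS for the per-prescription
# interaction count (with and without drug-count interaction terms), logistic
# regression for the presence of a contraindicated pair, VIF diagnostics and
# case-resampling bootstrap CIs.

#' Build a model-ready design table from a screened cohort
#'
#' One row per prescription. Outcomes: `ddi_count` (detected interactions)
#' and `any_contra` (contains a contraindicated pair). Predictors:
#' `drug_count` (numeric), `age_group` (reference "0-18"), `sex` (reference
#' "male"), `specialty` (reference "general practice"). Specialties below
#' `min_specialty_volume` prescriptions are dropped with accounting, to keep
#' sparse specialty levels from destabilising estimates.
#'
#' @param cohort a `ddi_cohort`.
#' @param sr the matching `screen_result`.
#' @param min_specialty_volume minimum prescriptions per specialty
#'   (default 5000; set 0 to keep all).
#' @param specialty_ref reference specialty level (default "general
#'   practice").
#' @return object of class `ddi_design`: list with `data` (data.table),
#'   `dropped_specialties` (named volume vector), `n_dropped_rows`,
#'   `references`.
#' @export
build_design <- function(cohort, sr, min_specialty_volume = 5000L,
                         specialty_ref = "general practice") {
  stopifnot(inherits(cohort, "ddi_cohort"), inherits(sr, "screen_result"))
  d <- data.table::copy(cohort$prescriptions)
  d <- sr$per_prescription[d, on = "prescription_id"]
  contra_ids <- unique(sr$interactions[severity == "contraindicated",
                                       prescription_id])
  d[, ddi_count := n_interactions]
  d[, any_contra := prescription_id %in% contra_ids]

  vol <- d[, .N, by = "specialty"]
  dropped <- vol[N < min_specialty_volume]
  d2 <- d[!specialty %in% dropped$specialty]
  if (nrow(d2) == 0L) stop("no prescriptions left after specialty filtering",
                           call. = FALSE)

  for (v in c("sex", "specialty")) {
    if (length(unique(d2[[v]])) < 2L) {
      stop(sprintf("degenerate design: predictor '%s' has a single level", v),
           call. = FALSE)
    }
  }
  if (!specialty_ref %in% d2$specialty) {
    stop(sprintf("reference specialty '%s' absent after filtering",
                 specialty_ref), call. = FALSE)
  }
  d2[, sex := stats::relevel(factor(sex, levels = c("male", "female")), "male")]
  d2[, age_group := factor(as.character(age_group), levels = AGE_GROUP_LEVELS)]
  d2[, specialty := stats::relevel(factor(specialty), specialty_ref)]
  d2[, drug_count := as.numeric(drug_count)]
  structure(list(data = d2[],
                 dropped_specialties = setNames(dropped$N, dropped$specialty),
                 n_dropped_rows = nrow(d) - nrow(d2),
                 references = c(sex = "male", age_group = "0-18",
                                specialty = specialty_ref)),
            class = "ddi_design")
}

design_formula <- function(outcome, interactions = FALSE, data = NULL) {
  terms <- c("drug_count", "age_group", "sex", "specialty")
  if (!is.null(data)) {
    # a single-level factor (e.g. one age group present) is silently dropped
    keep <- vapply(terms, function(v)
      !is.factor(data[[v]]) || length(unique(as.character(data[[v]]))) > 1L,
      logical(1))
    terms <- terms[keep]
  }
  rhs <- paste(terms, collapse = " + ")
  if (interactions) {
    cat_terms <- setdiff(terms, "drug_count")
    rhs <- paste(c(rhs, paste0("drug_count:", cat_terms)), collapse = " + ")
  }
  as.formula(paste(outcome, "~", rhs))
}

coef_table <- function(fit, exponentiate = FALSE) {
  sm <- summary(fit)$coefficients
  est <- sm[, 1]
  se <- sm[, 2]
  z <- qnorm(0.975)
  # OLS uses t quantiles; Wald normal for glm
  crit <- if (inherits(fit, "glm")) z else qt(0.975, df = fit$df.residual)
  lo <- est - crit * se
  hi <- est + crit * se
  p <- sm[, 4]
  if (exponentiate) {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  data.table::data.table(term = rownames(sm), estimate = unname(est),
                         ci_low = unname(lo), ci_high = unname(hi),
                         p_value = unname(p), p_display = format_p(unname(p)))
}

#' Fit the interaction-count linear model
#'
#' Ordinary least squares for the per-prescription DDI count on drug count,
#' age group, sex and specialty, with analytic 95% CIs and adjusted R^2. The
#' count outcome is modelled linearly (not Poisson); the case-resampling
#' bootstrap is the robustness mechanism when residual assumptions fail.
#'
#' @param design a `ddi_design`.
#' @return object of class `linear_fit`: list with `coefficients`
#'   (data.table), `adjusted_r2`, `n_obs`, `model` (the lm object),
#'   `formula`.
#' @export
fit_count_model <- function(design) {
  fit_linear(design, interactions = FALSE)
}

#' Fit the interaction-adjusted linear model
#'
#' Adds product terms between drug count and each categorical predictor, so
#' the drug-count slope is the slope at the reference levels and product
#' terms measure how each added medication's marginal interaction burden
#' differs by age group, sex and specialty.
#'
#' @param design a `ddi_design`.
#' @return a `linear_fit` (see [fit_count_model()]).
#' @export
fit_interaction_model <- function(design) {
  fit_linear(design, interactions = TRUE)
}

fit_linear <- function(design, interactions) {
  stopifnot(inherits(design, "ddi_design"))
  d <- design$data
  f <- design_formula("ddi_count", interactions, d)
  fit <- lm(f, data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  adj_r2 <- summary(fit)$adj.r.squared
  # a variance-free outcome explains nothing; avoid 0/0 artifacts
  if (var(d$ddi_count) == 0 || !is.finite(adj_r2)) adj_r2 <- 0
  structure(list(coefficients = coef_table(fit),
                 adjusted_r2 = adj_r2,
                 n_obs = nrow(d),
                 formula = f,
                 model = fit),
            class = "linear_fit")
}

#' Fit the contraindication logistic model
#'
#' Maximum-likelihood logistic regression for the presence of at least one
#' contraindicated pair; estimates are reported as odds ratios with Wald 95%
#' CIs, plus the model AIC.
#'
#' @param design a `ddi_design`.
#' @return object of class `logistic_fit`: list with `odds_ratios`
#'   (data.table), `aic`, `n_obs`, `model`, `formula`.
#' @export
fit_contra_model <- function(design) {
  stopifnot(inherits(design, "ddi_design"))
  d <- design$data
  y <- d$any_contra
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; logistic model is undefined", call. = FALSE)
  }
  f <- design_formula("any_contra", FALSE, d)
  fit <- suppressWarnings(glm(f, data = d, family = binomial()))
  sm <- summary(fit)$coefficients
  big <- abs(sm[, 1]) > 15 | sm[, 2] > 100
  if (!fit$converged || any(big)) {
    stop(sprintf("possible complete/quasi-separation (term(s): %s)",
                 paste(rownames(sm)[big | !fit$converged], collapse = ", ")),
         call. = FALSE)
  }
  structure(list(odds_ratios = coef_table(fit, exponentiate = TRUE),
                 aic = AIC(fit),
                 n_obs = nrow(d),
                 formula = f,
                 model = fit),
            class = "logistic_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear fit: n =", x$n_obs,
      "| adjusted R^2 =", formatC(x$adjusted_r2, digits = 3, format = "f"), "\n")
  print(x$coefficients[, list(term, estimate = round(estimate, 4),
                              ci_low = round(ci_low, 4),
                              ci_high = round(ci_high, 4), p = p_display)])
  invisible(x)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit: n =", x$n_obs,
      "| AIC =", formatC(x$aic, digits = 1, format = "f"), "\n")
  print(x$odds_ratios[, list(term, OR = round(estimate, 3),
                             ci_low = round(ci_low, 3),
                             ci_high = round(ci_high, 3), p = p_display)])
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from regressing model-matrix
#' column j on all other columns (intercept excluded from the j set). Values
#' at or above `flag_threshold` (default 3, the criterion used for these
#' models) are flagged.
#'
#' @param design a `ddi_design`, or a data.frame of numeric predictors.
#' @param flag_threshold flag VIFs at or above this value.
#' @return object of class `vif_set`: data.table `term, vif, flagged`;
#'   an effectively infinite VIF (aliased column) is reported as `Inf`.
#' @export
compute_vif <- function(design, flag_threshold = 3) {
  X <- if (inherits(design, "ddi_design")) {
    model.matrix(design_formula("ddi_count", FALSE, design$data),
                 data = design$data)[, -1, drop = FALSE]
  } else {
    as.matrix(as.data.frame(design))
  }
  if (ncol(X) < 2L) stop("VIF needs at least two predictors", call. = FALSE)
  if (any(apply(X, 2, var) == 0)) {
    stop("constant predictor column in VIF computation", call. = FALSE)
  }
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(data.table::data.table(term = colnames(X), vif = vifs,
                                   flagged = vifs >= flag_threshold),
            class = c("vif_set", "data.table", "data.frame"))
}

#' Case-resampling bootstrap confidence intervals
#'
#' Nonparametric bootstrap (default B = 1000 resamples): prescriptions are
#' resampled with replacement, the model is refit, and percentile 2.5/97.5
#' CIs are taken per term. A resample that loses a factor level (so the fit
#' would change meaning) is redrawn, counted, and capped at 10 * B redraws.
#' Fully reproducible under `seed`.
#'
#' @param fit_fun fitting function taking a `ddi_design` and returning a fit
#'   whose `coefficients`/`odds_ratios` table has `term` and `estimate`
#'   (e.g. [fit_count_model()], [fit_contra_model()]).
#' @param design a `ddi_design`.
#' @param B number of resamples (>= 100).
#' @param seed integer seed (required).
#' @return list with `cis` (data.table `term, ci_low, ci_high`), `B`,
#'   `n_redraws`, `seed`, `method = "percentile"`.
#' @export
bootstrap_ci <- function(fit_fun, design, B = 1000L, seed) {
  stopifnot(inherits(design, "ddi_design"), B >= 100L)
  if (missing(seed)) stop("bootstrap_ci requires a seed", call. = FALSE)
  d <- design$data
  n <- nrow(d)
  factor_cols <- c("age_group", "sex", "specialty")
  levels_needed <- lapply(factor_cols, function(v)
    unique(as.character(d[[v]])))
  names(levels_needed) <- factor_cols

  base_fit <- fit_fun(design)
  tab <- if (inherits(base_fit, "logistic_fit")) base_fit$odds_ratios else
    base_fit$coefficients
  terms <- tab$term

  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = B, ncol = length(terms),
                  dimnames = list(NULL, terms))
  redraws <- 0L
  cap <- 10L * B
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    db <- d[idx]
    ok <- all(vapply(factor_cols, function(v)
      all(levels_needed[[v]] %in% as.character(db[[v]])), logical(1)))
    if (!ok) {
      redraws <- redraws + 1L
      if (redraws > cap) stop("bootstrap redraw cap exceeded", call. = FALSE)
      next
    }
    dsgn_b <- design
    dsgn_b$data <- db
    fb <- tryCatch(fit_fun(dsgn_b), error = function(e) NULL)
    if (is.null(fb)) {
      redraws <- redraws + 1L
      if (redraws > cap) stop("bootstrap redraw cap exceeded", call. = FALSE)
      next
    }
    tb <- if (inherits(fb, "logistic_fit")) fb$odds_ratios else fb$coefficients
    draws[b, tb$term] <- tb$estimate
    b <- b + 1L
  }
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              type = 7)
  list(cis = data.table::data.table(term = terms,
                                    ci_low = qs[1, terms],
                                    ci_high = qs[2, terms]),
       B = B, n_redraws = redraws, seed = as.integer(seed),
       method = "percentile")
}

#' Export a model fit as CSV / JSON
#'
#' CSV columns `term, estimate, ci_low, ci_high, p`; JSON carries fit
#' metadata (n, adjusted R^2 or AIC, bootstrap settings when supplied).
#'
#' @param fit a `linear_fit` or `logistic_fit`.
#' @param csv_path,json_path output paths (either may be NULL).
#' @param bootstrap optional result of [bootstrap_ci()] to embed.
#' @return invisibly, the coefficient table written.
#' @export
write_fit <- function(fit, csv_path = NULL, json_path = NULL, bootstrap = NULL) {
  tab <- if (inherits(fit, "logistic_fit")) fit$odds_ratios else fit$coefficients
  out <- tab[, list(term, estimate, ci_low, ci_high, p = p_display)]
  if (!is.null(bootstrap)) {
    out <- bootstrap$cis[out, on = "term"]
    data.table::setnames(out, c("ci_low", "ci_high", "i.ci_low", "i.ci_high"),
                         c("boot_ci_low", "boot_ci_high", "ci_low", "ci_high"))
    data.table::setcolorder(out, c("term", "estimate", "ci_low", "ci_high",
                                   "boot_ci_low", "boot_ci_high", "p"))
  }
  if (!is.null(csv_path)) data.table::fwrite(out, csv_path)
  if (!is.null(json_path)) {
    meta <- list(n_obs = fit$n_obs,
                 adjusted_r2 = fit$adjusted_r2,
                 aic = fit$aic,
                 formula = deparse(fit$formula),
                 bootstrap = if (!is.null(bootstrap))
                   bootstrap[c("B", "seed", "method", "n_redraws")])
    jsonlite::write_json(Filter(Negate(is.null), meta), json_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
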