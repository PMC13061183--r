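make_design <- function(d) {
  structure(list(data = as.data.table(d), dropped_specialties = integer(0),
                 n_dropped_rows = 0L,
                 references = c(sex = "male", age_group = "0-18",
                                specialty = "general practice")),
            class = "ddi_design")
}

test_that("build_design filters low-volume specialties and validates coding", {
  set.seed(3)
  n <- 6000 + 5500 + 400
  fx <- fake_screened(data.table(
    prescription_id = paste0("R", 1:n),
    sex = sample(c("male", "female"), n, TRUE),
    age = sample(0:100, n, TRUE),
    specialty = rep(c("general practice", "cardiology", "rare"),
                    c(6000, 5500, 400)),
    n_interactions = rpois(n, 1)))
  des <- build_design(fx$cohort, fx$sr, min_specialty_volume = 5000)
  expect_named(des$dropped_specialties, "rare")
  expect_equal(nrow(des$data), 11500)
  expect_equal(des$n_dropped_rows, 400L)
  expect_identical(levels(des$data$specialty)[1], "general practice")
  expect_identical(levels(des$data$sex)[1], "male")

  males <- fake_screened(data.table(prescription_id = paste0("R", 1:20),
                                    sex = "male", n_interactions = 0L))
  expect_error(build_design(males$cohort, males$sr,
                            min_specialty_volume = 0), "sex")
  expect_error(build_design(fx$cohort, fx$sr, min_specialty_volume = 0,
                            specialty_ref = "dermatology"), "reference")
})

test_that("count model recovers a planted drug-count slope", {
  cfg <- sim_config(seed = 1701)
  cfg$model_truth$beta[["drug_count"]] <- 0.50
  des <- generate_model_truth_data(cfg, n = 20000, kind = "linear")
  fit <- fit_count_model(des)
  b <- fit$coefficients[term == "drug_count"]
  expect_gt(0.50, b$ci_low)
  expect_lt(0.50, b$ci_high)
  expect_lt(abs(b$estimate - 0.50), 0.02)
  expect_gt(fit$adjusted_r2, 0)
})

test_that("degenerate outcomes behave: constant and exactly linear", {
  set.seed(9)
  d <- data.table(prescription_id = paste0("R", 1:500),
                  drug_count = as.numeric(sample(2:9, 500, TRUE)),
                  age_group = factor(sample(c("0-18", "40-64"), 500, TRUE),
                                     levels = ddiscreen:::AGE_GROUP_LEVELS),
                  sex = factor(sample(c("male", "female"), 500, TRUE),
                               levels = c("male", "female")),
                  specialty = factor(rep("general practice", 500)),
                  ddi_count = 3, any_contra = FALSE)
  fit <- suppressWarnings(fit_count_model(make_design(d)))  # perfect fit
  slopes <- fit$coefficients[term != "(Intercept)", estimate]
  expect_true(all(abs(slopes) < 1e-12))
  expect_lte(fit$adjusted_r2, 0)

  d2 <- copy(d)[, ddi_count := 2 + 0.5 * drug_count +
                  (sex == "female") * 0.25]
  fit2 <- suppressWarnings(fit_count_model(make_design(d2)))
  expect_equal(fit2$adjusted_r2, 1, tolerance = 1e-10)
})

test_that("interaction model recovers reference and age-specific slopes", {
  cfg <- sim_config(seed = 1702)
  cfg$model_truth$beta[["drug_count"]] <- 0.15
  cfg$model_truth$beta_interaction[["age_65_100"]] <- 0.28
  des <- generate_model_truth_data(cfg, n = 20000, kind = "interaction")
  fit <- fit_interaction_model(des)
  # single-seed check: estimate within 4 analytic SEs of truth (the proper
  # 95%-CI coverage rate over many seeds is asserted in test-acceptance.R)
  se_of <- function(row) (row$ci_high - row$ci_low) / (2 * qnorm(0.975))
  base <- fit$coefficients[term == "drug_count"]
  expect_lt(abs(base$estimate - 0.15), 4 * se_of(base))
  old <- fit$coefficients[term == "drug_count:age_group65-100"]
  expect_lt(abs(old$estimate - 0.28), 4 * se_of(old))
})

test_that("zeroed product columns reproduce the main-effects fit", {
  cfg <- sim_config(seed = 1703)
  des <- generate_model_truth_data(cfg, n = 3000, kind = "linear")
  main <- fit_count_model(des)
  X <- model.matrix(main$formula, des$data)
  Xi <- model.matrix(ddiscreen:::design_formula("ddi_count", TRUE, des$data),
                     des$data)
  prod_cols <- grep(":", colnames(Xi))
  Xi[, prod_cols] <- 0
  ols <- lm.fit(Xi, des$data$ddi_count)
  shared <- colnames(X)
  expect_equal(ols$coefficients[shared],
               setNames(main$coefficients$estimate, main$coefficients$term)[shared],
               tolerance = 1e-10)
})

test_that("logistic model recovers a planted odds ratio and reports AIC", {
  cfg <- sim_config(seed = 1704)
  cfg$model_truth$logit[["drug_count"]] <- log(1.3)
  des <- generate_model_truth_data(cfg, n = 50000, kind = "logistic")
  fit <- fit_contra_model(des)
  or <- fit$odds_ratios[term == "drug_count"]
  expect_gt(1.3, or$ci_low); expect_lt(1.3, or$ci_high)
  expect_true(is.finite(fit$aic))
  expect_true(all(fit$odds_ratios$estimate > 0))
  expect_true(all(fit$odds_ratios$ci_low <= fit$odds_ratios$estimate &
                    fit$odds_ratios$estimate <= fit$odds_ratios$ci_high))
})

test_that("logistic fit matches the closed-form 2x2 odds ratio", {
  # collapsed design: binary exposure only
  set.seed(41)
  n <- 4000
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1); dd <- sum(x == 0 & y == 0)
  or_closed <- (a * dd) / (b * cc)
  fit <- glm(y ~ x, family = binomial())
  expect_equal(unname(exp(coef(fit)["x"])), or_closed, tolerance = 1e-6)
})

test_that("logistic error paths: single class and separation", {
  d <- data.table(prescription_id = paste0("R", 1:200),
                  drug_count = as.numeric(sample(2:9, 200, TRUE)),
                  age_group = factor("40-64", levels = ddiscreen:::AGE_GROUP_LEVELS),
                  sex = factor(rep(c("male", "female"), 100),
                               levels = c("male", "female")),
                  specialty = factor(rep(c("general practice", "cardiology"), 100)),
                  ddi_count = 0, any_contra = FALSE)
  expect_error(fit_contra_model(make_design(d)), "single class")
  d2 <- copy(d)[, any_contra := drug_count >= 6]  # perfectly separated
  expect_error(fit_contra_model(make_design(d2)), "separation")
})

test_that("VIF equals the auxiliary-regression definition", {
  # orthogonal predictors
  X <- data.frame(a = rep(c(-1, 1), 50), b = rep(c(-1, -1, 1, 1), 25),
                  c = rnorm(100))
  X$c <- resid(lm(c ~ a + b, X))  # force orthogonality
  v <- compute_vif(X)
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-10)

  # duplicated predictor is reported as unbounded
  X2 <- data.frame(a = rnorm(50))
  X2$b <- X2$a
  X2$c <- rnorm(50)
  v2 <- compute_vif(X2)
  expect_true(is.infinite(v2[v2$term == "a", vif]))

  # random 5-predictor design vs independent correlation-matrix oracle
  set.seed(88)
  Z <- matrix(rnorm(200 * 5), 200, 5) %*% chol(0.4 + 0.6 * diag(5))
  colnames(Z) <- paste0("x", 1:5)
  v3 <- compute_vif(as.data.frame(Z))
  oracle <- diag(solve(stats::cor(Z)))
  expect_equal(v3$vif, unname(oracle), tolerance = 1e-8)

  expect_error(compute_vif(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant")
  expect_error(compute_vif(data.frame(a = rnorm(10))), "two predictors")
})

test_that("bootstrap is seed-deterministic with B defaulting to 1000", {
  expect_equal(eval(formals(bootstrap_ci)$B), 1000L)
  cfg <- sim_config(seed = 1705)
  des <- generate_model_truth_data(cfg, n = 800, kind = "linear")
  b1 <- bootstrap_ci(fit_count_model, des, B = 120, seed = 7)
  b2 <- bootstrap_ci(fit_count_model, des, B = 120, seed = 7)
  expect_identical(b1$cis, b2$cis)
  b3 <- bootstrap_ci(fit_count_model, des, B = 120, seed = 8)
  expect_false(identical(b1$cis, b3$cis))
  expect_error(bootstrap_ci(fit_count_model, des, B = 50, seed = 1))
  expect_error(bootstrap_ci(fit_count_model, des, B = 120), "seed")
})

test_that("fit export writes CSV and JSON metadata", {
  cfg <- sim_config(seed = 1706)
  des <- generate_model_truth_data(cfg, n = 1000, kind = "linear")
  fit <- fit_count_model(des)
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, fc, fj)
  tab <- fread(fc)
  expect_identical(names(tab), c("term", "estimate", "ci_low", "ci_high", "p"))
  meta <- jsonlite::read_json(fj)
  expect_equal(meta$n_obs, 1000)
  expect_true(!is.null(meta$adjusted_r2))
})
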