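test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(0.125), 0.13)
  expect_equal(round_half_up(-0.125), -0.13)
  expect_equal(round_half_up(46.055), 46.06)
  expect_equal(round_half_up(2.345, 1), 2.3)  # 2.345 not exactly .5 in binary
  expect_equal(round_half_up(2.675), 2.68)
})

test_that("prevalence percentages recompute exactly from their counts", {
  fx <- fake_screened(data.table(
    prescription_id = paste0("R", 1:200),
    patient_id = paste0("P", rep(1:80, length.out = 200)),
    n_interactions = rep(c(0L, 2L), c(120, 80))))
  ps <- prevalence_summary(fx$sr, fx$cohort)
  expect_equal(ps$n_with_ddi, 80L)
  expect_equal(ps$prescription_prevalence_pct,
               round_half_up(100 * 80 / 200))
  expect_equal(ps$patient_prevalence_pct,
               round_half_up(100 * ps$n_patients_with_ddi / ps$n_patients))
  expect_equal(ps$mean_interactions_interacting$mean, 2)
  expect_equal(ps$mean_interactions_all$mean, 160 / 200)

  none <- fake_screened(data.table(prescription_id = paste0("R", 1:10),
                                   n_interactions = 0L))
  p0 <- prevalence_summary(none$sr, none$cohort)
  expect_equal(p0$prescription_prevalence_pct, 0)
  expect_equal(p0$patient_prevalence_pct, 0)
  expect_null(p0$mean_interactions_interacting)
})

test_that("severity shares normalise to 100 and vanish when undefined", {
  fx <- fake_screened(data.table(
    prescription_id = paste0("R", 1:60),
    n_interactions = rep(c(1L, 0L), c(30, 30)),
    has_major = rep(c(TRUE, FALSE), c(20, 40)),
    has_moderate = rep(c(FALSE, TRUE, FALSE), c(20, 10, 30))))
  sv <- severity_distribution(fx$sr)
  expect_equal(sum(sv$instance_counts), 30)
  expect_equal(sum(sv$instance_shares_pct), 100, tolerance = 0.02)
  raw <- 100 * sv$instance_counts / sum(sv$instance_counts)
  expect_equal(sum(raw), 100)

  single <- fake_screened(data.table(prescription_id = "R1",
                                     n_interactions = 1L,
                                     has_moderate = TRUE))
  expect_equal(severity_distribution(single$sr)$instance_shares_pct[["moderate"]],
               100)

  empty <- fake_screened(data.table(prescription_id = "R1",
                                    n_interactions = 0L))
  expect_null(severity_distribution(empty$sr)$instance_shares_pct)
})

test_that("profile distribution partitions and complements prevalence", {
  fx <- fake_screened(data.table(
    prescription_id = paste0("R", 1:100),
    n_interactions = rep(c(0L, 1L, 2L), c(54, 26, 20)),
    has_major = rep(c(FALSE, TRUE, TRUE), c(54, 26, 20)),
    has_moderate = rep(c(FALSE, FALSE, TRUE), c(54, 26, 20))))
  pd <- profile_distribution(fx$sr)
  expect_equal(sum(pd$n), 100L)
  expect_equal(pd[profile == "none", pct], 54)
  expect_equal(pd[profile == "major_only", n], 26L)
  expect_equal(pd[profile == "moderate+major", n], 20L)
  ps <- prevalence_summary(fx$sr, fx$cohort)
  expect_equal(pd[profile == "none", pct_raw],
               100 - ps$prescription_prevalence_raw)

  all_none <- fake_screened(data.table(prescription_id = paste0("R", 1:5),
                                       n_interactions = 0L))
  pd0 <- profile_distribution(all_none$sr)
  expect_equal(pd0[profile == "none", pct], 100)
  expect_equal(sum(pd0[profile != "none", n]), 0L)
})

test_that("pair coverage uses the KB denominator", {
  kb <- load_interaction_kb(data.table(
    drug_a = c("a", "b", "c", "d"), drug_b = c("b", "c", "d", "e"),
    severity = "moderate"))
  fx <- fake_screened(data.table(prescription_id = "R1", n_interactions = 2L,
                                 has_moderate = TRUE))
  pc <- pair_coverage(fx$sr, kb)
  expect_equal(pc$denominator, 4L)
  expect_equal(pc$observed_unique_pairs, 2L)
  expect_equal(pc$pct, 50)

  empty <- fake_screened(data.table(prescription_id = "R1",
                                    n_interactions = 0L))
  expect_equal(pair_coverage(empty$sr, kb)$pct, 0)
  kb0 <- load_interaction_kb(data.table(drug_a = character(0),
                                        drug_b = character(0),
                                        severity = character(0)))
  expect_error(pair_coverage(fx$sr, kb0), "empty")
})

test_that("top interactions rank by frequency with stable ties", {
  sr <- structure(list(
    interactions = data.table(),
    per_pair = data.table(
      first = c("a", "a", "b", "c"), second = c("x", "y", "z", "z"),
      severity = c("major", "major", "moderate", "moderate"),
      frequency = c(10L, 30L, 5L, 5L)),
    totals = c(moderate = 10L, major = 40L, contraindicated = 0L),
    per_prescription = data.table(), n_prescriptions = 10L),
    class = "screen_result")
  top <- top_interactions(sr, k = 10)
  expect_identical(top[severity == "major", first], c("a", "a"))
  expect_identical(top[severity == "major", second], c("y", "x"))
  # tie at 5 broken by pair name
  expect_identical(top[severity == "moderate", first], c("b", "c"))
  expect_equal(top[severity == "major"][1, pct], round_half_up(100 * 30 / 50))
  expect_equal(nrow(top_interactions(sr, k = 1)), 2L)  # one per stratum
  flat <- top_interactions(sr, k = 2, stratify_by_severity = FALSE)
  expect_equal(flat$frequency, c(30L, 10L))
})

test_that("stratified tables conserve marginals and attach tests", {
  set.seed(8)
  n <- 600
  fx <- fake_screened(data.table(
    prescription_id = paste0("R", 1:n),
    sex = sample(c("male", "female"), n, TRUE),
    age = sample(0:100, n, TRUE),
    drug_count = sample(2:9, n, TRUE),
    n_interactions = rpois(n, 1),
    has_major = runif(n) < 0.3))
  for (strat in c("sex", "age_group")) {
    st <- stratified_summary(fx$sr, fx$cohort, strat)
    expect_equal(sum(st$table$n_prescriptions), n)
    expect_equal(sum(st$table$n_with_ddi),
                 sum(fx$sr$per_prescription$n_interactions > 0))
    expect_false(st$tests$skipped)
    expect_true(st$tests$any_ddi_chisq$p_value >= 0 &&
                  st$tests$any_ddi_chisq$p_value <= 1)
  }
  one <- fake_screened(data.table(prescription_id = paste0("R", 1:10),
                                  sex = "female", n_interactions = 0L))
  st1 <- stratified_summary(one$sr, one$cohort, "sex")
  expect_true(st1$tests$skipped)
})

test_that("null strata give uniform-ish chi-squared p; planted effects are caught", {
  # identical distributions: rejection rate at alpha=0.05 stays near 0.05
  rej <- vapply(1:120, function(s) {
    set.seed(1000 + s)
    flag <- runif(1200) < 0.3
    grp <- rep(c("a", "b"), 600)
    ct <- table(grp, flag)
    suppressWarnings(chisq.test(ct, correct = FALSE)$p.value) < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12)

  # planted doubled interaction rate, n = 2000 per stratum
  hit <- vapply(1:200, function(s) {
    set.seed(2000 + s)
    fx <- fake_screened(data.table(
      prescription_id = paste0("R", 1:4000),
      sex = rep(c("male", "female"), each = 2000),
      n_interactions = c(rbinom(2000, 1, 0.15), rbinom(2000, 1, 0.30))))
    st <- stratified_summary(fx$sr, fx$cohort, "sex")
    st$tests$any_ddi_chisq$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("p-value display floors at <0.001", {
  expect_identical(format_p(c(0.5, 0.0009)), c("0.500", "<0.001"))
})
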