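test_that("read_prescriptions groups line items and validates columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("prescription_id,patient_id,age,sex,specialty,drug_name",
               "R1,P1,40,F,general practice,naproxen",
               "R1,P1,40,F,general practice,ketorolac",
               "R1,P1,40,F,general practice,acetaminophen"), f)
  items <- read_prescriptions(f)
  expect_equal(nrow(items), 3L)
  expect_equal(length(unique(items$prescription_id)), 1L)
  expect_identical(items$sex[1], "female")
  expect_identical(items$age[1], 40L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("prescription_id,patient_id,age,sex,specialty,drug_name", f2)
  expect_equal(nrow(read_prescriptions(f2)), 0L)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("prescription_id,patient_id,age,sex,drug_name",
               "R1,P1,40,F,naproxen"), f3)
  expect_error(read_prescriptions(f3), "specialty")
})

test_that("age groups use closed integer intervals with the 18/19 cut", {
  expect_identical(as.character(assign_age_group(c(0L, 18L, 19L, 39L, 40L,
                                                   64L, 65L, 100L))),
                   c("0-18", "0-18", "19-39", "19-39", "40-64",
                     "40-64", "65-100", "65-100"))
  expect_warning(g <- assign_age_group(101L), "above 100")
  expect_identical(as.character(g), "65-100")
  expect_error(assign_age_group(-1L), "negative")
})

test_that("polypharmacy threshold is >= 5 medications, configurable", {
  expect_identical(flag_polypharmacy(c(5L, 4L, 2L)), c(TRUE, FALSE, FALSE))
  expect_true(flag_polypharmacy(4L, threshold = 4L))
})

test_that("exclusion cascade buckets a hand-built toy exactly", {
  toy <- make_items(list(
    list(id = "R1", pid = "P1", age = 40, sex = "",  drugs = c("naproxen", "ketorolac")),
    list(id = "R2", pid = "P2", age = 30, sex = "M", drugs = "naproxen"),
    list(id = "R3", pid = "P3", age = 30, sex = "F", drugs = c("hydrocortisone", "unknownium")),
    list(id = "R4", pid = "P4", age = 50, sex = "F", drugs = c("naproxen", "ketorolac", "acetaminophen")),
    list(id = "R5", pid = "P4", age = 50, sex = "F", drugs = c("diclofenac", "ketorolac")),
    list(id = "R6", pid = "P5", age = 10, sex = "M", drugs = c("FERFOLIC", "TYLENOL 500"))))
  idx <- build_alias_index(tiny_concepts())
  co <- apply_exclusion_cascade(toy, idx)
  expect_equal(unlist(co$flow),
               c(n_input = 6, n_missing_demo = 1, n_single_drug = 1,
                 n_no_top_drug = 1, n_retained = 3))
  expect_setequal(co$prescriptions$prescription_id, c("R4", "R5", "R6"))
  expect_equal(co$prescriptions[prescription_id == "R4", drug_count], 3L)
})

test_that("all-clean input retains everything; flow conserves", {
  clean <- make_items(list(
    list(id = "R1", pid = "P1", age = 20, sex = "F", drugs = c("naproxen", "ketorolac")),
    list(id = "R2", pid = "P2", age = 70, sex = "M", drugs = c("diclofenac", "acetaminophen"))))
  idx <- build_alias_index(tiny_concepts())
  co <- apply_exclusion_cascade(clean, idx)
  expect_equal(unlist(co$flow),
               c(n_input = 2, n_missing_demo = 0, n_single_drug = 0,
                 n_no_top_drug = 0, n_retained = 2))
})

test_that("overlapping exclusion reasons land in the first bucket only", {
  both <- make_items(list(
    list(id = "R1", pid = "P1", age = 40, sex = "", drugs = "naproxen")))
  idx <- build_alias_index(tiny_concepts())
  co <- apply_exclusion_cascade(both, idx)
  expect_equal(co$flow$n_missing_demo, 1L)
  expect_equal(co$flow$n_single_drug, 0L)
})

test_that("topical removal precedes the single-drug test by default", {
  it <- make_items(list(
    list(id = "R1", pid = "P1", age = 40, sex = "F",
         drugs = c("naproxen", "HYDROCORTISONE CREAM"))))
  idx <- build_alias_index(tiny_concepts())
  expect_equal(apply_exclusion_cascade(it, idx)$flow$n_single_drug, 1L)
  # whole-prescription mode removes the prescription entirely (single bucket)
  co2 <- apply_exclusion_cascade(it, idx, topical_removal = "prescription")
  expect_equal(co2$flow$n_single_drug, 1L)
  expect_equal(co2$flow$n_retained, 0L)
  # "after" mode: raw count 2 passes the single-drug test
  co3 <- apply_exclusion_cascade(it, idx, topical_removal = "after")
  expect_equal(co3$flow$n_single_drug, 0L)
})

test_that("flow conservation holds under fuzzed corruption", {
  idx <- build_alias_index(tiny_concepts())
  drugs <- c("naproxen", "ketorolac", "acetaminophen", "unknownium",
             "HYDROCORTISONE CREAM", "diclofenac")
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    toy <- make_items(lapply(seq_len(n), function(i) {
      list(id = paste0("R", i), pid = paste0("P", sample(1:8, 1)),
           age = if (runif(1) < 0.15) "" else sample(0:100, 1),
           sex = sample(c("M", "F", ""), 1, prob = c(.4, .4, .2)),
           drugs = sample(drugs, sample(1:5, 1), replace = TRUE))
    }))
    co <- apply_exclusion_cascade(toy, idx)
    f <- co$flow
    expect_equal(f$n_input,
                 f$n_missing_demo + f$n_single_drug + f$n_no_top_drug +
                   f$n_retained)
    # patient regrouping: per-patient prescription counts sum to retained
    expect_equal(sum(table(co$prescriptions$patient_id)), f$n_retained)
  }
})

test_that("grouped counts on a synthetic fixture equal generator truth", {
  cfg <- sim_config(seed = 77, n_patients = 420)
  gen <- generate_cohort(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  fwrite(gen$items, f)
  items <- read_prescriptions(f)
  expect_equal(length(unique(items$prescription_id)),
               gen$truth$flow$n_input)
  idx <- build_alias_index(gen$kb$concepts)
  co <- apply_exclusion_cascade(items, idx)
  expect_equal(co$flow$n_missing_demo, gen$truth$flow$n_missing_demo)
  expect_equal(co$flow$n_single_drug, gen$truth$flow$n_single_drug)
  expect_equal(co$flow$n_no_top_drug, gen$truth$flow$n_no_top_drug)
  expect_equal(co$flow$n_retained, gen$truth$flow$n_retained)
  # per-prescription drug counts match the planted systemic item counts
  truth <- gen$truth$prescriptions[bucket == "retained"]
  m <- merge(co$prescriptions[, .(prescription_id, drug_count)],
             truth[, .(prescription_id, drug_count_truth = drug_count)],
             by = "prescription_id")
  expect_equal(m$drug_count, m$drug_count_truth)
})
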