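test_that("the null error model yields documented == truth everywhere", {
  pairs <- generate_cohort(cohort_config(n_patients = 60, seed = 21),
                           null_error_model())
  for (p in pairs) expect_identical(p$documented, p$truth)

  rec <- score_cohort(pairs)
  expect_true(all(rec$epesi_total == rec$ppesi_total))
  expect_true(all(rec$error_components == ""))
  rep <- evaluate_agreement(rec)
  expect_equal(rep$exact_match$proportion, 1)
  expect_equal(rep$kappa$kappa, 1)
  expect_true(all(vapply(rep$component_errors, function(e) e$count, 0) == 0))
})

test_that("saturated cancer omission removes every documented cancer code", {
  g <- default_concept_graph()
  pairs <- generate_cohort(cohort_config(n_patients = 150, seed = 31),
                           error_model(cancer = 1), g)
  doc <- vapply(pairs, function(p) match_category(
    rbind(p$documented$problem_list, p$documented$medical_history),
    "cancer", g)$flag, TRUE)
  tru <- vapply(pairs, function(p) match_category(
    rbind(p$truth$problem_list, p$truth$medical_history),
    "cancer", g)$flag, TRUE)
  expect_equal(sum(doc), 0)
  # truth prevalence unaffected: within 3 binomial SE of the configured 37%
  se <- sqrt(0.37 * 0.63 / 150)
  expect_lt(abs(mean(tru) - 0.37), 3 * se)
})

test_that("cohort marginals track the configuration (study conditions)", {
  n <- 500
  pairs <- generate_cohort(cohort_config(n_patients = n, seed = 17))
  g <- default_concept_graph()
  tol <- function(p) 3 * sqrt(p * (1 - p) / n)
  truths <- lapply(pairs, `[[`, "truth")
  prev <- function(cat) mean(vapply(truths, function(s) match_category(
    rbind(s$problem_list, s$medical_history), cat, g)$flag, TRUE))
  expect_lt(abs(prev("cancer") - 0.37), tol(0.37))
  expect_lt(abs(prev("heart_failure") - 0.176), tol(0.176))
  expect_lt(abs(prev("chronic_lung_disease") - 0.41), tol(0.41))
  expect_lt(abs(mean(vapply(truths, function(s) s$prior_encounter_count == 0, TRUE)) - 0.10),
            tol(0.10))
  expect_lt(abs(mean(vapply(truths, function(s)
    s$sex_assigned_at_birth == "male", TRUE)) - 0.438), tol(0.438))
  ages <- vapply(truths, function(s) s$age_years, 0L)
  expect_gt(mean(ages), 58.2 - 3 * 17.7 / sqrt(n))
  expect_lt(mean(ages), 58.2 + 3 * 17.7 / sqrt(n) + 1)  # +1: truncation at 18 shifts up
  expect_true(all(ages >= 18))
})

test_that("identical configuration and seed reproduce the cohort byte-for-byte", {
  cfg <- cohort_config(n_patients = 40, seed = 99)
  p1 <- generate_cohort(cfg)
  p2 <- generate_cohort(cfg)
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_snapshots(lapply(p1, `[[`, "documented"), f1)
  write_snapshots(lapply(p2, `[[`, "documented"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("score_pair tags exactly the components whose contribution differs", {
  g <- toy_graph()
  truth <- make_snapshot(
    patient_id = "T", age_years = 70,
    medical_history = problem_entries("chf", "history", TT - 86400))
  # only discrepancy: heart-failure code omitted from the documented snapshot
  documented <- truth
  documented$medical_history <- problem_entries()
  rec <- score_pair(list(truth = truth, documented = documented,
                         acute_pe_on_ct = FALSE), g)
  expect_equal(rec$error_components, "heart_failure")
  expect_equal(rec$ppesi_total - rec$epesi_total, 10)

  # omitted cancer code AND a late RR sample: two tags
  truth2 <- make_snapshot(
    patient_id = "T2", age_years = 70,
    problem_list = problem_entries("lung_ca", "active", TT - 86400),
    vitals = rbind(normal_vitals(), vital_samples(TT - 300, "RR", 34)))
  doc2 <- truth2
  doc2$problem_list <- problem_entries()
  doc2$vitals <- rbind(normal_vitals(), vital_samples(TT + 1800, "RR", 34))
  rec2 <- score_pair(list(truth = truth2, documented = doc2, acute_pe_on_ct = FALSE), g)
  expect_setequal(strsplit(rec2$error_components, ";")[[1]], c("cancer", "vitals"))
  expect_equal(rec2$ppesi_total - rec2$epesi_total, 50)

  # no discrepancy: empty tag set
  rec3 <- score_pair(list(truth = truth, documented = truth, acute_pe_on_ct = FALSE), g)
  expect_equal(rec3$error_components, "")
})

test_that("error records are empty exactly when totals agree", {
  pairs <- generate_cohort(cohort_config(n_patients = 300, seed = 13))
  rec <- score_cohort(pairs)
  expect_identical(rec$error_components == "", rec$epesi_total == rec$ppesi_total)
})

test_that("raising an error probability cannot raise expected accuracy", {
  # common random numbers: same seed, increasing cancer omission
  acc <- vapply(c(0, 0.3, 1), function(p) {
    pairs <- generate_cohort(cohort_config(n_patients = 250, seed = 55),
                             error_model(cancer = p, heart_failure = 0,
                                         chronic_lung_disease = 0, vitals = 0,
                                         sex_conflation = 0))
    rec <- score_cohort(pairs)
    mean(rec$epesi_total == rec$ppesi_total)
  }, 0)
  expect_true(all(diff(acc) <= 0))
  expect_lt(acc[3], acc[1])
})

test_that("agreement records round-trip through CSV", {
  pairs <- generate_cohort(cohort_config(n_patients = 50, seed = 2))
  rec <- score_cohort(pairs)
  f <- withr::local_tempfile(fileext = ".csv")
  write_agreement_records(rec, f)
  expect_equal(read_agreement_records(f), rec)
})

test_that("invalid configuration is rejected", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(p_male = 1.2), "p_male")
  expect_error(error_model(cancer = -0.1), "cancer")
  expect_error(error_model(first_visit_multiplier = 0.5), "multiplier")
})
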