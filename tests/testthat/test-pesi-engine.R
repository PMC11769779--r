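test_that("vital extremes pick the most adverse pre-trigger value per kind", {
  expect_true(all(is.na(vapply(vital_extremes(vital_samples(), TT),
                               function(e) e$value, 0))))

  v <- vital_samples(c(TT - 7200, TT - 3600), c("HR", "HR"), c(80, 115))
  expect_equal(vital_extremes(v, TT)$hr_max$value, 115)

  # a sample charted after the trigger is invisible (documentation latency)
  v <- vital_samples(c(TT - 3600, TT + 600), c("RR", "RR"), c(18, 32))
  ext <- vital_extremes(v, TT)
  expect_equal(ext$rr_max$value, 18)

  # adverse direction: min for SBP/TEMP/SPO2
  v <- vital_samples(rep(TT - 60, 3), c("SBP", "SBP", "TEMP"), c(140, 95, 35.5))
  ext <- vital_extremes(v, TT)
  expect_equal(ext$sbp_min$value, 95)
  expect_equal(ext$temp_min$value, 35.5)
  expect_true(is.na(ext$spo2_min$value))
})

test_that("the oxygen criterion is a literal four-clause disjunction", {
  w <- pesi_weights()
  ext_of <- function(spo2) vital_extremes(
    if (is.na(spo2)) vital_samples() else vital_samples(TT - 600, "SPO2", spo2), TT)

  # SpO2 below 90 on room air
  o <- oxygen_criterion(ext_of(88), oxygen_records(TT - 600, "room_air", 0), 0, TT, w)
  expect_true(o$flag)
  expect_match(o$provenance, "SpO2 88")

  # 2.0 L/min is not > 2
  expect_false(oxygen_criterion(ext_of(94),
    oxygen_records(TT - 600, "nasal_cannula", 2), 0, TT, w)$flag)

  # home O2 3 L/min, on 4 L/min: relative clause fails (4 <= 5) but the
  # absolute clause (4 > 2) fires
  expect_true(oxygen_criterion(ext_of(93),
    oxygen_records(TT - 600, "nasal_cannula", 4), 3, TT, w)$flag)
  # ... unless the absolute clause is suppressed for home-O2 patients
  expect_false(oxygen_criterion(ext_of(93),
    oxygen_records(TT - 600, "nasal_cannula", 4), 3, TT, w,
    suppress_absolute_flow_when_home_o2 = TRUE)$flag)
  # relative clause alone: 6 > 3 + 2
  expect_true(oxygen_criterion(ext_of(93),
    oxygen_records(TT - 600, "nasal_cannula", 6), 3, TT, w,
    suppress_absolute_flow_when_home_o2 = TRUE)$flag)

  # assist device with zero flow
  o <- oxygen_criterion(ext_of(NA), oxygen_records(TT - 600, "bipap", 0), 0, TT, w)
  expect_true(o$flag)
  expect_match(o$provenance, "bipap")

  # post-trigger oxygen records are invisible
  expect_false(oxygen_criterion(ext_of(NA),
    oxygen_records(TT + 600, "ventilator", 10), 0, TT, w)$flag)

  # provenance names the first qualifying datum in time order
  o <- oxygen_criterion(ext_of(85),
    oxygen_records(TT - 7200, "high_flow", 40), 0, TT, w)
  expect_match(o$provenance, "high_flow")
})

test_that("altered mental status: GCS below 14 before trigger, or AMS chief concern", {
  gcs15 <- data.frame(time = TT - 600, value = 15L)
  expect_false(altered_mental_status(gcs15, "chest pain", TT)$flag)

  gcs13 <- data.frame(time = c(TT - 600, TT - 300), value = c(15L, 13L))
  a <- altered_mental_status(gcs13, character(0), TT)
  expect_true(a$flag)
  expect_match(a$provenance, "GCS 13")

  # GCS 13 charted after the trigger does not count
  expect_false(altered_mental_status(
    data.frame(time = TT + 300, value = 13L), character(0), TT)$flag)

  # chief-complaint text match is case-insensitive; coded concept also works
  expect_true(altered_mental_status(gcs15, "ALTERED MENTAL STATUS", TT)$flag)
  expect_true(altered_mental_status(gcs15, "419284004", TT)$flag)
  expect_false(altered_mental_status(gcs15, "altered", TT)$flag)
})

test_that("compute_pesi sums age plus weighted components", {
  g <- toy_graph()
  # 18-year-old with nothing adverse scores exactly her age
  r <- compute_pesi(make_snapshot(age_years = 18), g)
  expect_equal(r$total, 18L)
  expect_equal(r$pesi_class, "I")
  expect_true(r$low_risk)
  expect_true(all(!r$component_flags))
  expect_true(all(r$provenance == "absent"))

  # 60-year-old male with cancer, HR 115, SpO2 88: 60+10+30+20+20 = 140
  s <- make_snapshot(age_years = 60, sex_assigned_at_birth = "male",
                     administrative_sex = "male",
                     problem_list = problem_entries("lung_ca", "active", TT - 86400),
                     vitals = vital_samples(rep(TT - 3600, 5),
                                            c("HR", "RR", "SBP", "TEMP", "SPO2"),
                                            c(115, 16, 120, 37, 88)))
  r <- compute_pesi(s, g)
  expect_equal(r$total, 140L)
  expect_equal(r$pesi_class, "V")
  expect_false(r$low_risk)
  expect_equal(sum(r$component_flags), 4)
  expect_true(all(r$provenance[names(which(r$component_flags))] != "absent"))

  # deterministic: identical result on re-run
  expect_identical(compute_pesi(s, g), r)

  expect_error(compute_pesi(make_snapshot(age_years = 18) |>
                              (\(x) { x$age_years <- 17L; x })(), g), "age")
})

test_that("sex points use sex assigned at birth, falling back to administrative sex", {
  g <- toy_graph()
  s <- make_snapshot(age_years = 40, sex_assigned_at_birth = "unknown",
                     administrative_sex = "male")
  expect_warning(r <- compute_pesi(s, g), "administrative")
  expect_equal(r$total, 50L)
  expect_match(r$provenance[["sex_male"]], "administrative")

  s2 <- make_snapshot(age_years = 40, sex_assigned_at_birth = "female",
                      administrative_sex = "male")
  expect_silent(r2 <- compute_pesi(s2, g))
  expect_equal(r2$total, 40L)
})

test_that("classification boundaries are exact at the published cut points", {
  cl <- classify_pesi(c(65, 66, 85, 86, 105, 106, 125, 126))
  expect_equal(cl$pesi_class, c("I", "II", "II", "III", "III", "IV", "IV", "V"))
  expect_equal(cl$low_risk, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_error(classify_pesi(-1), "non-negative")
})

test_that("classify agrees with a brute-force table on scores 0-300", {
  # independent table built directly from the class definitions
  brute <- function(t) {
    if (t < 66) "I" else if (t <= 85) "II" else if (t <= 105) "III"
    else if (t <= 125) "IV" else "V"
  }
  scores <- 0:300
  got <- classify_pesi(scores)
  expect_equal(got$pesi_class, vapply(scores, brute, ""))
  expect_equal(got$low_risk, scores < 86)
  expect_equal(got$low_risk, got$pesi_class %in% c("I", "II"))
})

test_that("score is monotone under adverse component additions", {
  g <- toy_graph()
  base <- make_snapshot(age_years = 55)
  base_total <- compute_pesi(base, g)$total
  expect_equal(base_total, 55L)  # total >= age, equality iff female unflagged

  worsen <- list(
    function(s) { s$problem_list <- problem_entries("lung_ca", "active", TT - 1); s },
    function(s) { s$medical_history <- problem_entries("chf", "history", TT - 1); s },
    function(s) { s$problem_list <- rbind(s$problem_list,
                                          problem_entries("copd", "active", TT - 1)); s },
    function(s) { s$vitals <- rbind(s$vitals, vital_samples(TT - 10, "HR", 115)); s },
    function(s) { s$vitals <- rbind(s$vitals, vital_samples(TT - 10, "SBP", 90)); s },
    function(s) { s$vitals <- rbind(s$vitals, vital_samples(TT - 10, "RR", 31)); s },
    function(s) { s$vitals <- rbind(s$vitals, vital_samples(TT - 10, "TEMP", 35)); s },
    function(s) { s$vitals <- rbind(s$vitals, vital_samples(TT - 10, "SPO2", 88)); s },
    function(s) { s$gcs_records <- rbind(s$gcs_records,
                                         data.frame(time = TT - 10, value = 12L)); s },
    function(s) { s$oxygen_records <- oxygen_records(TT - 10, "nasal_cannula", 4); s })

  s <- base
  prev <- base_total
  for (w in worsen) {
    s <- w(s)
    tot <- compute_pesi(s, g)$total
    expect_gte(tot, prev)
    prev <- tot
  }
  # every component except male sex flagged:
  # age + 30+10+10+20+30+20+20+60+20
  expect_equal(prev, 55L + 220L)

  # removing an adverse sample never increases the score
  trimmed <- s
  trimmed$vitals <- trimmed$vitals[trimmed$vitals$value != 115, ]
  expect_lte(compute_pesi(trimmed, g)$total, prev)
})

test_that("post-trigger data never changes the score (trigger causality)", {
  g <- toy_graph()
  base <- make_snapshot(age_years = 48)
  r0 <- compute_pesi(base, g)

  late <- base
  late$vitals <- rbind(late$vitals,
                       vital_samples(rep(TT + 300, 3), c("HR", "SBP", "SPO2"),
                                     c(140, 80, 82)))
  late$gcs_records <- rbind(late$gcs_records, data.frame(time = TT + 60, value = 6L))
  late$oxygen_records <- oxygen_records(TT + 120, "ventilator", 12)
  r1 <- compute_pesi(late, g)
  expect_equal(r1$total, r0$total)
  expect_equal(r1$component_flags, r0$component_flags)

  # the same data is seen when rescoring later (the --at semantics)
  r2 <- compute_pesi(late, g, trigger = TT + 3600)
  expect_gt(r2$total, r0$total)
})
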