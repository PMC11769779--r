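#' Synthetic ED cohort configuration
#'
#' Defaults emulate the validation study's cohort: mean age 58.2 (SD 17.7),
#' 43.8% male, comorbidity prevalences of 37% (cancer), 17.6% (heart
#' failure) and 41% (chronic lung disease), 10% of patients presenting for
#' their first encounter in the health system and 8% with acute PE on CT.
#'
#' @param n_patients number of patients.
#' @param age_mean,age_sd,age_min age distribution (normal truncated at
#'   `age_min`), years.
#' @param p_male probability of male sex assigned at birth.
#' @param prev_cancer,prev_heart_failure,prev_chronic_lung_disease true
#'   comorbidity prevalences.
#' @param p_first_visit probability the index ED visit is the patient's
#'   first entry in the EHR (no prior encounters).
#' @param p_acute_pe probability of acute PE on the CT-PE read (carried as a
#'   covariate; it does not influence scoring).
#' @param p_ams probability of altered mental status (split between a low
#'   GCS entry and an AMS chief complaint).
#' @param p_supplemental_o2 probability of a nasal-cannula oxygen record.
#' @param p_assist_device probability of a respiratory-assist device record.
#' @param p_home_o2 probability of a 2 L/min chronic home oxygen requirement.
#' @param vital_distributions named list of `c(mean, sd)` per vital kind;
#'   values are drawn from per-kind truncated normals (no physiologic
#'   coupling between kinds is modeled — the scoring engine only consumes
#'   extremes).
#' @param samples_per_kind flowsheet samples per vital kind before trigger.
#' @param seed RNG seed; identical configuration and seed reproduce the
#'   cohort exactly.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500,
                          age_mean = 58.2, age_sd = 17.7, age_min = 18,
                          p_male = 0.438,
                          prev_cancer = 0.37,
                          prev_heart_failure = 0.176,
                          prev_chronic_lung_disease = 0.41,
                          p_first_visit = 0.10,
                          p_acute_pe = 0.08,
                          p_ams = 0.04,
                          p_supplemental_o2 = 0.12,
                          p_assist_device = 0.03,
                          p_home_o2 = 0.05,
                          vital_distributions = list(
                            HR = c(mean = 88, sd = 18),
                            RR = c(mean = 19, sd = 5),
                            SBP = c(mean = 128, sd = 22),
                            TEMP = c(mean = 36.8, sd = 0.5),
                            SPO2 = c(mean = 96.5, sd = 2.5)),
                          samples_per_kind = 3,
                          seed = NULL) {
  cfg <- list(n_patients = n_patients, age_mean = age_mean, age_sd = age_sd,
              age_min = age_min, p_male = p_male, prev_cancer = prev_cancer,
              prev_heart_failure = prev_heart_failure,
              prev_chronic_lung_disease = prev_chronic_lung_disease,
              p_first_visit = p_first_visit, p_acute_pe = p_acute_pe,
              p_ams = p_ams, p_supplemental_o2 = p_supplemental_o2,
              p_assist_device = p_assist_device, p_home_o2 = p_home_o2,
              vital_distributions = vital_distributions,
              samples_per_kind = samples_per_kind, seed = seed)
  if (!is_count(n_patients) || n_patients < 1)
    stop("cohort_config: n_patients must be a positive integer", call. = FALSE)
  probs <- cfg[grepl("^(p_|prev_)", names(cfg))]
  bad <- names(probs)[vapply(probs, function(p) !is.numeric(p) || is.na(p) || p < 0 || p > 1, TRUE)]
  if (length(bad))
    stop("cohort_config: probabilities must be in [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "cohort_config")
}

#' Documentation-error model
#'
#' Three mechanisms degrade the documented snapshot relative to clinical
#' truth. Comorbidity omission: a patient who truly carries the comorbidity
#' has its coded entries missing from the documented problem list and
#' history (the history "not entered or fully updated" failure mode); the
#' probability is conditional on the comorbidity being present, so omission
#' 1 means no documented snapshot carries the category at all. Vitals
#' latency: an adverse vital measured before the trigger is charted after
#' it, so the abstractor sees it but the calculator never does; this is a
#' per-patient probability. Sex conflation: sex assigned at birth is
#' replaced by a differing gender marker.
#'
#' Defaults are calibrated to the validation study: the observed marginal
#' component error rates (8.4% cancer, 3.2% heart failure, 5.4% chronic
#' lung disease, 4.6% vitals, 0.2% sex) divided, for the comorbidities, by
#' the cohort prevalences (37%, 17.6%, 41%), giving conditional omission
#' probabilities of 0.227, 0.182 and 0.132.
#'
#' First-visit patients have `first_visit_multiplier` times the omission
#' rate of established patients (their records are emptier); the rates are
#' internally normalized so the configured value stays the cohort-wide
#' rate.
#'
#' @param cancer,heart_failure,chronic_lung_disease omission probability for
#'   a patient who truly carries the comorbidity.
#' @param vitals per-patient probability of a late-charted adverse vital.
#' @param sex_conflation probability sex assigned at birth is misdocumented.
#' @param chief_complaint probability the AMS chief-complaint coding is wrong.
#' @param first_visit_multiplier relative comorbidity error rate for
#'   first-visit patients (default 3).
#' @return object of class `error_model`.
#' @export
error_model <- function(cancer = 0.227, heart_failure = 0.182,
                        chronic_lung_disease = 0.132, vitals = 0.046,
                        sex_conflation = 0.002, chief_complaint = 0,
                        first_visit_multiplier = 3) {
  em <- list(cancer = cancer, heart_failure = heart_failure,
             chronic_lung_disease = chronic_lung_disease, vitals = vitals,
             sex_conflation = sex_conflation, chief_complaint = chief_complaint,
             first_visit_multiplier = first_visit_multiplier)
  probs <- em[setdiff(names(em), "first_visit_multiplier")]
  bad <- names(probs)[vapply(probs, function(p) !is.numeric(p) || is.na(p) || p < 0 || p > 1, TRUE)]
  if (length(bad))
    stop("error_model: probabilities must be in [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(first_visit_multiplier) || first_visit_multiplier < 1)
    stop("error_model: first_visit_multiplier must be >= 1", call. = FALSE)
  structure(em, class = "error_model")
}

#' A null error model (documented = truth)
#' @return an [error_model()] with every probability zero.
#' @export
null_error_model <- function() {
  error_model(cancer = 0, heart_failure = 0, chronic_lung_disease = 0,
              vitals = 0, sex_conflation = 0, chief_complaint = 0)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

NONCAT_CODES <- c("38341003", "73211009", "13644009", "49436004", "414545008")

#' Generate a synthetic paired (truth, documented) ED cohort
#'
#' For each patient a complete, timely `truth` snapshot is drawn from the
#' cohort configuration, then a `documented` snapshot is produced by applying
#' the error model — the documented snapshot is what the automated calculator
#' sees at trigger time, the truth snapshot is what a blinded physician
#' abstractor reconstructs. With the null error model the two are identical.
#'
#' @param config a [cohort_config()].
#' @param errors an [error_model()].
#' @param graph a [concept_graph()] supplying concrete comorbidity codes.
#' @return list of pairs; each pair is
#'   `list(truth =, documented =, acute_pe_on_ct =)`. The config and error
#'   model are attached as attributes.
#' @export
generate_cohort <- function(config = cohort_config(), errors = error_model(),
                            graph = default_concept_graph()) {
  stopifnot(inherits(config, "cohort_config"), inherits(errors, "error_model"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  f <- config$p_first_visit
  m <- errors$first_visit_multiplier
  # split the configured rate into (established, first-visit) per-patient
  # probabilities with ratio m, preserving the cohort-wide rate:
  # (1-f)*q + f*m*q = p => q = p/(1 + f*(m-1)); once the first-visit arm
  # saturates at 1 the remainder goes to the established arm, so p = 1
  # means certain omission for everyone
  q_split <- function(p) {
    q0 <- p / (1 + f * (m - 1))
    if (m * q0 <= 1) c(q0, m * q0) else c(max(0, (p - f) / (1 - f)), 1)
  }

  pools <- list(
    cancer = c("363346000", descendants("363346000", graph)),
    heart_failure = c("84114007", descendants("84114007", graph)),
    chronic_lung_disease = c("413839001", descendants("413839001", graph)))
  base_time <- as.POSIXct("2023-01-15 08:00:00", tz = "UTC")

  age <- round(rtruncnorm(n, config$age_mean, config$age_sd, config$age_min, 105))
  male <- runif(n) < config$p_male
  has <- list(cancer = runif(n) < config$prev_cancer,
              heart_failure = runif(n) < config$prev_heart_failure,
              chronic_lung_disease = runif(n) < config$prev_chronic_lung_disease)
  first_visit <- runif(n) < config$p_first_visit
  acute_pe <- runif(n) < config$p_acute_pe
  ams <- runif(n) < config$p_ams
  ams_via_gcs <- runif(n) < 0.5
  suppl <- runif(n) < config$p_supplemental_o2
  assist <- runif(n) < config$p_assist_device
  home_o2 <- ifelse(runif(n) < config$p_home_o2, 2, 0)

  ranges <- list(HR = c(35, 185), RR = c(8, 45), SBP = c(70, 230),
                 TEMP = c(34, 41), SPO2 = c(75, 100))
  vd <- config$vital_distributions
  k_samp <- config$samples_per_kind

  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    trigger <- base_time + (i - 1) * 600
    vt <- trigger - rev(seq_len(k_samp)) * 1800 - round(runif(k_samp, 0, 600))
    kinds <- rep(VITAL_KINDS, each = k_samp)
    vals <- unlist(lapply(VITAL_KINDS, function(k) {
      r <- ranges[[k]]
      v <- rtruncnorm(k_samp, vd[[k]][["mean"]], vd[[k]][["sd"]], r[1], r[2])
      if (k %in% c("HR", "RR", "SBP")) round(v) else round(v, 1)
    }))
    vitals <- fast_df(time = rep(vt, times = length(VITAL_KINDS)),
                      kind = kinds, value = vals)

    ecode <- character(0); estatus <- character(0); edays <- numeric(0)
    for (cat in PESI_CATEGORIES) {
      if (has[[cat]][i]) {
        ecode <- c(ecode, sample(pools[[cat]], 1))
        estatus <- c(estatus, sample(c("active", "history"), 1))
        edays <- c(edays, sample(30:900, 1))
      }
    }
    n_noise <- sample(0:2, 1)
    if (n_noise > 0) {
      ecode <- c(ecode, sample(NONCAT_CODES, n_noise))
      estatus <- c(estatus, rep("active", n_noise))
      edays <- c(edays, sample(30:900, n_noise))
    }
    active <- estatus == "active"
    probs <- fast_df(snomed_code = ecode[active], status = estatus[active],
                     recorded_time = trigger - edays[active] * 86400)
    hist <- fast_df(snomed_code = ecode[!active], status = estatus[!active],
                    recorded_time = trigger - edays[!active] * 86400)

    complaints <- sample(c("chest pain", "dyspnea", "syncope", "cough"), 1)
    gcs_t <- trigger - 3600; gcs_v <- 15L
    if (ams[i]) {
      if (ams_via_gcs[i]) {
        gcs_t <- c(gcs_t, trigger - 1800); gcs_v <- c(gcs_v, sample(8:13, 1))
      } else complaints <- c(complaints, "altered mental status")
    }
    gcs <- fast_df(time = gcs_t, value = gcs_v)

    oxy_t <- trigger - 4200; oxy_d <- "room_air"; oxy_f <- 0
    if (suppl[i]) {
      oxy_t <- c(oxy_t, trigger - 2400); oxy_d <- c(oxy_d, "nasal_cannula")
      oxy_f <- c(oxy_f, sample(1:5, 1))
    }
    if (assist[i]) {
      oxy_t <- c(oxy_t, trigger - 1200)
      oxy_d <- c(oxy_d, sample(c("bipap", "high_flow", "venturi_mask"), 1))
      oxy_f <- c(oxy_f, 10)
    }
    oxy <- fast_df(time = oxy_t, device = oxy_d, flow_lpm = oxy_f)

    truth <- patient_snapshot(
      patient_id = sprintf("SIM%05d", i),
      age_years = age[i],
      sex_assigned_at_birth = if (male[i]) "male" else "female",
      administrative_sex = if (male[i]) "male" else "female",
      problem_list = probs, medical_history = hist,
      chief_complaints = complaints,
      vitals = vitals, oxygen = oxy, gcs = gcs,
      home_o2_lpm = home_o2[i],
      prior_encounter_count = if (first_visit[i]) 0L else 1L + rpois(1, 4),
      trigger_time = trigger, validate = FALSE)

    documented <- truth

    # comorbidity omission for true carriers; first-visit patients at
    # multiplied risk
    for (cat in PESI_CATEGORIES) {
      if (!has[[cat]][i]) next
      q <- q_split(errors[[cat]])[if (first_visit[i]) 2 else 1]
      if (runif(1) < q) {
        members <- category_members(graph, cat)
        drop_cat <- function(p) {
          if (!nrow(p)) return(p)
          p[!(p$snomed_code %in% members), , drop = FALSE]
        }
        documented$problem_list <- drop_cat(documented$problem_list)
        documented$medical_history <- drop_cat(documented$medical_history)
      }
    }

    # vital documentation latency: a transient adverse vital measured before
    # the trigger (visible to the abstractor) but charted after it
    if (runif(1) < errors$vitals) {
      ext <- vital_extremes(truth$vitals, trigger)
      late <- NULL
      if (is.na(ext$hr_max$value) || ext$hr_max$value < 110) {
        late <- list(kind = "HR", value = 112 + sample(0:8, 1))
      } else if (is.na(ext$rr_max$value) || ext$rr_max$value < 30) {
        late <- list(kind = "RR", value = 31 + sample(0:4, 1))
      } else if (is.na(ext$sbp_min$value) || ext$sbp_min$value >= 100) {
        late <- list(kind = "SBP", value = 85 + sample(0:10, 1))
      } else if (is.na(ext$temp_min$value) || ext$temp_min$value >= 36) {
        late <- list(kind = "TEMP", value = 35.2)
      } else if (!oxygen_criterion(ext, truth$oxygen_records, truth$home_o2_lpm,
                                   trigger)$flag) {
        late <- list(kind = "SPO2", value = 85 + sample(0:3, 1))
      }
      if (!is.null(late)) {
        add_sample <- function(v, t) fast_df(
          time = c(v$time, t), kind = c(v$kind, late$kind),
          value = c(v$value, late$value))
        truth$vitals <- add_sample(truth$vitals, trigger - 300)
        documented$vitals <- add_sample(documented$vitals, trigger + 1800)
      }
    }

    if (runif(1) < errors$sex_conflation) {
      documented$sex_assigned_at_birth <-
        if (truth$sex_assigned_at_birth == "male") "female" else "male"
    }

    if (runif(1) < errors$chief_complaint) {
      cc <- documented$chief_complaints
      if (any(tolower(cc) == "altered mental status")) {
        documented$chief_complaints <- cc[tolower(cc) != "altered mental status"]
      } else {
        documented$chief_complaints <- c(cc, "altered mental status")
      }
    }

    pairs[[i]] <- list(truth = truth, documented = documented,
                       acute_pe_on_ct = acute_pe[i])
  }
  attr(pairs, "config") <- config
  attr(pairs, "errors") <- errors
  pairs
}

ERROR_COMPONENT_NAMES <- c("cancer", "heart_failure", "chronic_lung_disease",
                           "vitals", "other")

group_points <- function(res) {
  p <- res$component_points
  c(cancer = unname(p[["cancer"]]),
    heart_failure = unname(p[["heart_failure"]]),
    chronic_lung_disease = unname(p[["chronic_lung_disease"]]),
    vitals = unname(p[["hr_high"]] + p[["sbp_low"]] + p[["rr_high"]] +
                      p[["temp_low"]] + p[["o2_low"]]),
    other = unname(p[["sex_male"]] + p[["altered_mental_status"]]))
}

score_pair_core <- function(pair, graph, weights, boundaries) {
  ppesi <- compute_pesi(pair$truth, graph, weights, boundaries)
  epesi <- compute_pesi(pair$documented, graph, weights, boundaries)
  gp_t <- group_points(ppesi)
  gp_d <- group_points(epesi)
  errs <- ERROR_COMPONENT_NAMES[gp_t != gp_d]
  list(patient_id = pair$truth$patient_id,
       epesi_total = epesi$total, epesi_class = epesi$pesi_class,
       epesi_low_risk = epesi$low_risk,
       ppesi_total = ppesi$total, ppesi_class = ppesi$pesi_class,
       ppesi_low_risk = ppesi$low_risk,
       first_visit = pair$truth$prior_encounter_count == 0L,
       acute_pe_on_ct = isTRUE(pair$acute_pe_on_ct),
       error_components = paste(errs, collapse = ";"))
}

#' Score one (truth, documented) pair into an agreement record
#'
#' The physician gold-standard score (`ppesi_*`) is computed from the truth
#' snapshot, the automated score (`epesi_*`) from the documented snapshot. A
#' component is tagged in `error_components` when its contribution to the
#' documented score differs from its contribution to the truth score —
#' i.e. substituting the component's true value would move the documented
#' total toward the truth total. Vital-sign and oxygenation criteria are
#' pooled as `"vitals"`; sex and mental status as `"other"`.
#'
#' @param pair one element of [generate_cohort()] output.
#' @param graph,weights,boundaries scoring configuration.
#' @return one-row data frame (an agreement record).
#' @export
score_pair <- function(pair, graph = default_concept_graph(),
                       weights = pesi_weights(), boundaries = class_boundaries()) {
  as.data.frame(score_pair_core(pair, graph, weights, boundaries))
}

#' Score a whole simulated cohort
#'
#' @param pairs output of [generate_cohort()].
#' @inheritParams score_pair
#' @return data frame of agreement records, one row per patient.
#' @export
score_cohort <- function(pairs, graph = default_concept_graph(),
                         weights = pesi_weights(), boundaries = class_boundaries()) {
  rows <- lapply(pairs, score_pair_core, graph = graph, weights = weights,
                 boundaries = boundaries)
  data.frame(
    patient_id = vapply(rows, `[[`, "", "patient_id"),
    epesi_total = vapply(rows, `[[`, 0L, "epesi_total"),
    epesi_class = vapply(rows, `[[`, "", "epesi_class"),
    epesi_low_risk = vapply(rows, `[[`, TRUE, "epesi_low_risk"),
    ppesi_total = vapply(rows, `[[`, 0L, "ppesi_total"),
    ppesi_class = vapply(rows, `[[`, "", "ppesi_class"),
    ppesi_low_risk = vapply(rows, `[[`, TRUE, "ppesi_low_risk"),
    first_visit = vapply(rows, `[[`, TRUE, "first_visit"),
    acute_pe_on_ct = vapply(rows, `[[`, TRUE, "acute_pe_on_ct"),
    error_components = vapply(rows, `[[`, "", "error_components"))
}

#' Write agreement records to CSV
#' @param records data frame of agreement records.
#' @param path destination CSV file.
#' @return `path`, invisibly.
#' @export
write_agreement_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read agreement records from CSV
#' @param path CSV file written by [write_agreement_records()].
#' @return data frame of agreement records.
#' @export
read_agreement_records <- function(path) {
  rec <- read.csv(path, colClasses = c(
    patient_id = "character", epesi_total = "integer", epesi_class = "character",
    epesi_low_risk = "logical", ppesi_total = "integer", ppesi_class = "character",
    ppesi_low_risk = "logical", first_visit = "logical",
    acute_pe_on_ct = "logical", error_components = "character"))
  rec$error_components[is.na(rec$error_components)] <- ""
  rec
}
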