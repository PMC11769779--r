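AMS_CONCEPT <- "419284004"   # SNOMED: altered mental status
ASSIST_DEVICES <- c("bipap", "cpap", "venturi_mask", "high_flow", "ventilator")
PESI_COMPONENTS <- c("sex_male", "cancer", "heart_failure", "chronic_lung_disease",
                     "hr_high", "sbp_low", "rr_high", "temp_low",
                     "altered_mental_status", "o2_low")

#' PESI component weights and thresholds
#'
#' The Pulmonary Embolism Severity Index is an additive score: age in years
#' plus fixed points for each adverse binary component. The weights here are
#' the original published index values; they are carried as data so
#' alternative weightings can be configured.
#'
#' | component | criterion | points |
#' |---|---|---|
#' | male sex | | 10 |
#' | history of cancer | | 30 |
#' | history of heart failure | | 10 |
#' | history of chronic lung disease | | 10 |
#' | tachycardia | HR >= 110 /min | 20 |
#' | hypotension | SBP < 100 mmHg | 30 |
#' | tachypnea | RR >= 30 /min | 20 |
#' | hypothermia | temperature < 36 C | 20 |
#' | altered mental status | GCS < 14 or AMS chief complaint | 60 |
#' | hypoxemia | SpO2 < 90 % or supplemental O2 > 2 L/min or assist device | 20 |
#'
#' @return object of class `pesi_weights`: a list with `points` (named
#'   integer vector) and `thresholds` (named numeric vector carrying the
#'   comparison values; directions are fixed as in the table above).
#' @export
pesi_weights <- function() {
  structure(list(
    points = c(sex_male = 10L, cancer = 30L, heart_failure = 10L,
               chronic_lung_disease = 10L, hr_high = 20L, sbp_low = 30L,
               rr_high = 20L, temp_low = 20L, altered_mental_status = 60L,
               o2_low = 20L),
    thresholds = c(hr_high = 110, sbp_low = 100, rr_high = 30, temp_low = 36,
                   spo2_low = 90, supplemental_flow = 2, gcs = 14)
  ), class = "pesi_weights")
}

#' PESI risk-class boundaries
#'
#' Class I: score < 66; class II: 66-85; class III: 86-105; class IV:
#' 106-125; class V: > 125. "Low risk" is score < 86, i.e. classes I-II,
#' the candidate band for outpatient PE management.
#'
#' @return object of class `class_boundaries`.
#' @export
class_boundaries <- function() {
  structure(list(upper = c(I = 65, II = 85, III = 105, IV = 125, V = Inf),
                 low_risk_below = 86),
            class = "class_boundaries")
}

#' Assign PESI risk class and low-risk flag
#'
#' @param total integer score(s), `>= 0`.
#' @param boundaries a [class_boundaries()].
#' @return data frame with columns `pesi_class` (character, `"I"`..`"V"`) and
#'   `low_risk` (logical), one row per score.
#' @export
classify_pesi <- function(total, boundaries = class_boundaries()) {
  if (any(is.na(total)) || any(total < 0))
    stop("classify_pesi: scores must be non-negative", call. = FALSE)
  up <- boundaries$upper
  cls <- names(up)[vapply(total, function(t) which(t <= up)[1], 1L)]
  data.frame(pesi_class = cls, low_risk = total < boundaries$low_risk_below)
}

# scalar fast path used by compute_pesi
classify0 <- function(total, boundaries) {
  up <- boundaries$upper
  list(pesi_class = names(up)[which(total <= up)[1]],
       low_risk = total < boundaries$low_risk_below)
}

#' Most adverse vital values charted before the trigger
#'
#' Peak vitals in the PESI sense: the extremum in the adverse direction for
#' each criterion — highest heart and respiratory rate, lowest systolic blood
#' pressure, temperature and oxygen saturation. Only samples with
#' `time <= trigger` are visible; a sample charted after the trigger is
#' invisible to the calculator (the documentation-latency error source).
#'
#' @param vitals data frame from [vital_samples()].
#' @param trigger trigger timestamp.
#' @return named list (`hr_max`, `rr_max`, `sbp_min`, `temp_min`,
#'   `spo2_min`), each a list with `value` and `time`, or `value = NA` when
#'   no eligible sample exists.
#' @export
vital_extremes <- function(vitals, trigger) {
  trigger <- parse_ts(trigger, "trigger")
  out <- list(hr_max = NULL, rr_max = NULL, sbp_min = NULL,
              temp_min = NULL, spo2_min = NULL)
  spec <- list(hr_max = c("HR", "max"), rr_max = c("RR", "max"),
               sbp_min = c("SBP", "min"), temp_min = c("TEMP", "min"),
               spo2_min = c("SPO2", "min"))
  has <- nrow(vitals) > 0
  if (has) {
    elig <- vitals$time <= trigger
    kind <- vitals$kind
  }
  for (nm in names(spec)) {
    k <- spec[[nm]][1]; dir <- spec[[nm]][2]
    if (has) {
      sel <- which(elig & kind == k)
    } else sel <- integer(0)
    if (!length(sel)) {
      out[[nm]] <- list(value = NA_real_, time = as.POSIXct(NA, tz = "UTC"))
    } else {
      v <- vitals$value[sel]
      i <- if (dir == "max") which.max(v) else which.min(v)
      out[[nm]] <- list(value = v[i], time = vitals$time[sel[i]])
    }
  }
  out
}

#' Hypoxemia / supplemental-oxygen criterion
#'
#' The oxygen-saturation component is positive when any of four clauses
#' holds before the trigger: a pulse-oximetry reading below 90%; oxygen flow
#' above 2 L/min; flow more than 2 L/min above the patient's home oxygen
#' requirement; or a respiratory-assist device (BiPAP, CPAP, venturi mask,
#' high-flow catheter, mechanical ventilator). The clauses are a literal
#' disjunction; for chronic home-oxygen patients the absolute-flow clause can
#' be suppressed with `suppress_absolute_flow_when_home_o2`.
#'
#' @param extremes output of [vital_extremes()].
#' @param oxygen data frame from [oxygen_records()].
#' @param home_o2_lpm chronic home oxygen requirement, L/min.
#' @param trigger trigger timestamp.
#' @param weights a [pesi_weights()] (supplies the thresholds).
#' @param suppress_absolute_flow_when_home_o2 when `TRUE`, the absolute
#'   `> 2 L/min` clause is skipped for patients with `home_o2_lpm > 0`,
#'   leaving the relative clause. Default `FALSE` (literal rule).
#' @return list with `flag` and `provenance` (the first qualifying datum in
#'   time order, or `"absent"`).
#' @export
oxygen_criterion <- function(extremes, oxygen, home_o2_lpm, trigger,
                             weights = pesi_weights(),
                             suppress_absolute_flow_when_home_o2 = FALSE) {
  trigger <- parse_ts(trigger, "trigger")
  th <- weights$thresholds
  hits_t <- as.POSIXct(character(0), tz = "UTC")
  hits_desc <- character(0)
  spo2 <- extremes$spo2_min
  if (!is.na(spo2$value) && spo2$value < th[["spo2_low"]]) {
    hits_t <- c(hits_t, spo2$time)
    hits_desc <- c(hits_desc, sprintf("SpO2 %g%% at %s", spo2$value, format_ts(spo2$time)))
  }
  if (nrow(oxygen)) {
    ok <- oxygen$time <= trigger
    for (i in which(ok)) {
      dev <- oxygen$device[i]; fl <- oxygen$flow_lpm[i]
      abs_clause <- fl > th[["supplemental_flow"]] &&
        !(suppress_absolute_flow_when_home_o2 && home_o2_lpm > 0)
      rel_clause <- fl > home_o2_lpm + th[["supplemental_flow"]]
      dev_clause <- dev %in% ASSIST_DEVICES
      if (abs_clause || rel_clause || dev_clause) {
        hits_t <- c(hits_t, oxygen$time[i])
        hits_desc <- c(hits_desc, sprintf("%s %g L/min at %s", dev, fl,
                                          format_ts(oxygen$time[i])))
      }
    }
  }
  if (!length(hits_t)) return(list(flag = FALSE, provenance = "absent"))
  first <- which.min(hits_t)
  list(flag = TRUE, provenance = hits_desc[first])
}

#' Altered mental status criterion
#'
#' Positive when any Glasgow Coma Scale entry below 14 is charted at or
#' before the trigger, or when the chief complaint carries the
#' altered-mental-status concept — either the SNOMED code (419284004) or the
#' case-insensitive text "altered mental status".
#'
#' @param gcs data frame with columns `time`, `value`.
#' @param chief_complaints character vector of coded chief complaints.
#' @param trigger trigger timestamp.
#' @param gcs_threshold GCS values strictly below this flag AMS (default 14).
#' @return list with `flag` and `provenance`.
#' @export
altered_mental_status <- function(gcs, chief_complaints, trigger,
                                  gcs_threshold = 14) {
  trigger <- parse_ts(trigger, "trigger")
  if (nrow(gcs)) {
    sel <- which(gcs$time <= trigger & gcs$value < gcs_threshold)
    if (length(sel)) {
      i <- sel[which.min(gcs$time[sel])]
      return(list(flag = TRUE,
                  provenance = sprintf("GCS %d at %s", as.integer(gcs$value[i]),
                                       format_ts(gcs$time[i]))))
    }
  }
  cc <- tolower(trimws(chief_complaints))
  hit <- which(cc == "altered mental status" | chief_complaints == AMS_CONCEPT)
  if (length(hit)) {
    return(list(flag = TRUE,
                provenance = sprintf("chief complaint '%s'", chief_complaints[hit[1]])))
  }
  list(flag = FALSE, provenance = "absent")
}

#' Compute the PESI score for one encounter snapshot
#'
#' Derives all 11 PESI variables from the snapshot as of `trigger` (by
#' default the snapshot's own trigger time, i.e. the CT-PE order instant):
#' age and sex from demographics, the three comorbidities by hierarchical
#' concept matching over problem list plus past medical history, the four
#' vital-sign criteria from the most adverse pre-trigger flowsheet values,
#' altered mental status from GCS entries and chief complaint, and the
#' hypoxemia criterion from pulse oximetry and oxygen-support records.
#' Missing vital kinds contribute no points (provenance `"absent"`). The sex
#' component uses sex assigned at birth when known, else the administrative
#' sex with a warning (the two can be conflated in an EHR).
#'
#' @param snapshot a [patient_snapshot()].
#' @param graph a [concept_graph()]; defaults to the packaged illustrative
#'   graph.
#' @param weights a [pesi_weights()].
#' @param boundaries a [class_boundaries()].
#' @param trigger scoring instant; defaults to `snapshot$trigger_time`.
#'   Supplying a later timestamp rescores the encounter after more data has
#'   been charted (e.g. after PE diagnosis).
#' @param statuses problem-entry statuses that count as comorbidity evidence.
#' @param suppress_absolute_flow_when_home_o2 see [oxygen_criterion()].
#' @return object of class `pesi_result`: component flags, per-component
#'   points, total score, class `"I"`-`"V"`, low-risk flag and per-component
#'   provenance.
#' @export
compute_pesi <- function(snapshot,
                         graph = default_concept_graph(),
                         weights = pesi_weights(),
                         boundaries = class_boundaries(),
                         trigger = NULL,
                         statuses = c("active", "history"),
                         suppress_absolute_flow_when_home_o2 = FALSE) {
  age <- snapshot$age_years
  if (is.null(age) || is.na(age)) stop("compute_pesi: age_years missing", call. = FALSE)
  if (age < 18) stop("compute_pesi: age_years must be >= 18", call. = FALSE)
  trigger <- if (is.null(trigger)) snapshot$trigger_time else parse_ts(trigger, "trigger")

  pts <- weights$points
  th <- weights$thresholds
  flags <- setNames(logical(length(PESI_COMPONENTS)), PESI_COMPONENTS)
  prov <- setNames(rep("absent", length(PESI_COMPONENTS)), PESI_COMPONENTS)

  sex <- snapshot$sex_assigned_at_birth
  sex_src <- "sex assigned at birth"
  if (!(sex %in% c("male", "female"))) {
    sex <- snapshot$administrative_sex
    sex_src <- "administrative sex"
    if (sex %in% c("male", "female"))
      warning(sprintf("%s: sex assigned at birth unknown; falling back to administrative sex",
                      snapshot$patient_id), call. = FALSE)
  }
  if (identical(sex, "male")) {
    flags[["sex_male"]] <- TRUE
    prov[["sex_male"]] <- sex_src
  }

  entries <- if (nrow(snapshot$medical_history) == 0) snapshot$problem_list
             else if (nrow(snapshot$problem_list) == 0) snapshot$medical_history
             else rbind(snapshot$problem_list, snapshot$medical_history)
  for (cat in PESI_CATEGORIES) {
    m <- match_category(entries, cat, graph, statuses = statuses)
    if (m$flag) {
      flags[[cat]] <- TRUE
      e <- m$evidence[1, ]
      prov[[cat]] <- sprintf("SNOMED %s (%s, recorded %s)", e$snomed_code,
                             e$status, format_ts(e$recorded_time))
    }
  }

  ext <- vital_extremes(snapshot$vitals, trigger)
  vital_flag <- function(comp, e, cmp, thr, label, unit) {
    if (!is.na(e$value) && cmp(e$value, thr)) {
      flags[[comp]] <<- TRUE
      prov[[comp]] <<- sprintf("%s %g%s at %s", label, e$value, unit, format_ts(e$time))
    }
  }
  vital_flag("hr_high", ext$hr_max, `>=`, th[["hr_high"]], "HR", "/min")
  vital_flag("rr_high", ext$rr_max, `>=`, th[["rr_high"]], "RR", "/min")
  vital_flag("sbp_low", ext$sbp_min, `<`, th[["sbp_low"]], "SBP", " mmHg")
  vital_flag("temp_low", ext$temp_min, `<`, th[["temp_low"]], "Temp", " C")

  ams <- altered_mental_status(snapshot$gcs_records, snapshot$chief_complaints,
                               trigger, gcs_threshold = th[["gcs"]])
  if (ams$flag) {
    flags[["altered_mental_status"]] <- TRUE
    prov[["altered_mental_status"]] <- ams$provenance
  }

  o2 <- oxygen_criterion(ext, snapshot$oxygen_records, snapshot$home_o2_lpm,
                         trigger, weights, suppress_absolute_flow_when_home_o2)
  if (o2$flag) {
    flags[["o2_low"]] <- TRUE
    prov[["o2_low"]] <- o2$provenance
  }

  comp_points <- ifelse(flags, pts[PESI_COMPONENTS], 0L)
  names(comp_points) <- PESI_COMPONENTS
  total <- as.integer(age + sum(comp_points))
  cl <- classify0(total, boundaries)

  structure(list(patient_id = snapshot$patient_id,
                 age_years = age,
                 component_flags = flags,
                 component_points = comp_points,
                 total = total,
                 pesi_class = cl$pesi_class,
                 low_risk = cl$low_risk,
                 provenance = prov),
            class = "pesi_result")
}

#' @export
print.pesi_result <- function(x, ...) {
  cat(sprintf("<pesi_result %s> total %d (age %d), class %s, %s\n",
              x$patient_id, x$total, x$age_years, x$pesi_class,
              if (x$low_risk) "LOW risk" else "HIGH risk"))
  on <- names(x$component_flags)[x$component_flags]
  if (length(on)) {
    for (c in on) cat(sprintf("  +%d %-22s %s\n", x$component_points[[c]], c,
                              x$provenance[[c]]))
  } else cat("  no adverse components\n")
  invisible(x)
}

pesi_result_to_list <- function(r) {
  list(patient_id = r$patient_id,
       age_years = r$age_years,
       total = r$total,
       pesi_class = r$pesi_class,
       low_risk = r$low_risk,
       component_flags = as.list(r$component_flags),
       component_points = as.list(r$component_points),
       provenance = as.list(r$provenance))
}
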