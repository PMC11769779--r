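#' @importFrom stats aov na.omit qbeta qnorm rbinom rnorm runif sd setNames
#'   chisq.test glm binomial coef pnorm rpois
#' @importFrom utils read.csv write.csv head
NULL

SEX_AT_BIRTH <- c("male", "female", "unknown")
ADMIN_SEX <- c("male", "female", "other", "unknown")
PROBLEM_STATUS <- c("active", "resolved", "history")
VITAL_KINDS <- c("HR", "RR", "SBP", "TEMP", "SPO2")
O2_DEVICES <- c("room_air", "nasal_cannula", "venturi_mask", "high_flow",
                "bipap", "cpap", "ventilator", "other")

empty_problems <- function() {
  data.frame(snomed_code = character(0), status = character(0),
              recorded_time = as.POSIXct(character(0), tz = "UTC"))
}
empty_vitals <- function() {
  data.frame(time = as.POSIXct(character(0), tz = "UTC"),
             kind = character(0), value = numeric(0))
}
empty_oxygen <- function() {
  data.frame(time = as.POSIXct(character(0), tz = "UTC"),
             device = character(0), flow_lpm = numeric(0))
}
empty_gcs <- function() {
  data.frame(time = as.POSIXct(character(0), tz = "UTC"), value = integer(0))
}

#' Construct a problem-list entry table
#'
#' @param snomed_code character vector of SNOMED CT concept identifiers.
#' @param status entry status, one of `"active"`, `"resolved"`, `"history"`.
#' @param recorded_time timestamps (`POSIXct` or ISO-8601 strings).
#' @return data frame with one row per entry.
#' @export
problem_entries <- function(snomed_code = character(0),
                            status = "active",
                            recorded_time = as.POSIXct(character(0), tz = "UTC")) {
  n <- length(snomed_code)
  if (n == 0) return(empty_problems())
  data.frame(snomed_code = as.character(snomed_code),
             status = rep_len(as.character(status), n),
             recorded_time = rep_len(parse_ts(recorded_time, "recorded_time"), n))
}

#' Construct a vital-sign flowsheet table
#'
#' @param time timestamps (`POSIXct` or ISO-8601 strings).
#' @param kind one of `"HR"` (beats/min), `"RR"` (breaths/min), `"SBP"` (mmHg),
#'   `"TEMP"` (degrees C), `"SPO2"` (percent).
#' @param value measured values.
#' @return data frame with one row per sample.
#' @export
vital_samples <- function(time = character(0), kind = character(0),
                          value = numeric(0)) {
  if (length(value) == 0) return(empty_vitals())
  data.frame(time = parse_ts(time, "vitals time"),
             kind = as.character(kind), value = as.numeric(value))
}

#' Construct an oxygen-support record table
#'
#' @param time timestamps.
#' @param device delivery device (`"room_air"`, `"nasal_cannula"`,
#'   `"venturi_mask"`, `"high_flow"`, `"bipap"`, `"cpap"`, `"ventilator"`,
#'   `"other"`).
#' @param flow_lpm oxygen flow in liters/minute (0 for room air).
#' @return data frame with one row per record.
#' @export
oxygen_records <- function(time = character(0), device = character(0),
                           flow_lpm = numeric(0)) {
  if (length(device) == 0) return(empty_oxygen())
  n <- length(device)
  data.frame(time = rep_len(parse_ts(time, "oxygen time"), n),
             device = as.character(device),
             flow_lpm = rep_len(as.numeric(flow_lpm), n))
}

#' Construct an ED-encounter snapshot
#'
#' A `patient_snapshot` captures everything an automated PESI calculator can
#' see about one emergency-department encounter at a trigger instant (by
#' default, the moment a CT pulmonary angiogram is ordered): demographics,
#' coded problem list and past medical history, the vital-sign flowsheet,
#' oxygen-support records, Glasgow Coma Scale entries, coded chief complaints,
#' the home oxygen requirement and the count of prior encounters in the
#' health system.
#'
#' @param patient_id opaque identifier string.
#' @param age_years age in whole years; study inclusion requires `>= 18`.
#' @param sex_assigned_at_birth `"male"`, `"female"` or `"unknown"`.
#' @param administrative_sex `"male"`, `"female"`, `"other"` or `"unknown"`.
#' @param problem_list,medical_history data frames as built by
#'   [problem_entries()].
#' @param chief_complaints character vector of coded chief-complaint strings.
#' @param vitals data frame as built by [vital_samples()].
#' @param oxygen data frame as built by [oxygen_records()].
#' @param gcs data frame with columns `time`, `value` (Glasgow Coma Scale,
#'   integer 3-15).
#' @param home_o2_lpm chronic home oxygen requirement, liters/minute.
#' @param prior_encounter_count number of prior encounters in the EHR
#'   (0 means a first visit).
#' @param trigger_time the scoring instant; data timestamped after it is
#'   invisible to the calculator.
#' @param validate check all invariants (default `TRUE`).
#' @return object of class `patient_snapshot`.
#' @export
patient_snapshot <- function(patient_id,
                             age_years,
                             sex_assigned_at_birth = "unknown",
                             administrative_sex = "unknown",
                             problem_list = empty_problems(),
                             medical_history = empty_problems(),
                             chief_complaints = character(0),
                             vitals = empty_vitals(),
                             oxygen = empty_oxygen(),
                             gcs = empty_gcs(),
                             home_o2_lpm = 0,
                             prior_encounter_count = 0,
                             trigger_time,
                             validate = TRUE) {
  s <- structure(list(
    patient_id = as.character(patient_id),
    age_years = as.integer(age_years),
    sex_assigned_at_birth = as.character(sex_assigned_at_birth),
    administrative_sex = as.character(administrative_sex),
    problem_list = problem_list,
    medical_history = medical_history,
    chief_complaints = as.character(chief_complaints),
    vitals = vitals,
    oxygen_records = oxygen,
    gcs_records = gcs,
    home_o2_lpm = as.numeric(home_o2_lpm),
    prior_encounter_count = as.integer(prior_encounter_count),
    trigger_time = parse_ts(trigger_time, "trigger_time")
  ), class = "patient_snapshot")
  if (validate) validate_snapshot(s)
  s
}

#' Validate a patient snapshot
#'
#' Checks every typed invariant: adult age, enum membership, physiologic
#' vital-sign ranges, GCS in 3-15, non-negative oxygen flows and counts.
#' Violations raise an error naming the offending field; nothing is silently
#' clamped.
#'
#' @param s a `patient_snapshot`.
#' @param where optional context (e.g. a record index) prefixed to messages.
#' @return `s`, invisibly, when valid.
#' @export
validate_snapshot <- function(s, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(where, ": ")
  fail <- function(fmt, ...) stop(sprintf(paste0(ctx, fmt), ...), call. = FALSE)

  if (!nzchar(s$patient_id)) fail("patient_id must be non-empty")
  if (!is_count(as.numeric(s$age_years)) || s$age_years < 18)
    fail("age_years must be an integer >= 18, got %s", s$age_years)
  if (!(s$sex_assigned_at_birth %in% SEX_AT_BIRTH))
    fail("sex_assigned_at_birth invalid: '%s'", s$sex_assigned_at_birth)
  if (!(s$administrative_sex %in% ADMIN_SEX))
    fail("administrative_sex invalid: '%s'", s$administrative_sex)
  if (is.na(s$trigger_time)) fail("trigger_time missing")

  for (fld in c("problem_list", "medical_history")) {
    p <- s[[fld]]
    if (nrow(p)) {
      if (any(!nzchar(p$snomed_code) | is.na(p$snomed_code)))
        fail("%s: snomed_code must be non-empty", fld)
      if (any(!(p$status %in% PROBLEM_STATUS)))
        fail("%s: invalid status '%s'", fld,
             p$status[which(!(p$status %in% PROBLEM_STATUS))[1]])
      if (any(is.na(p$recorded_time))) fail("%s: recorded_time missing", fld)
    }
  }

  v <- s$vitals
  if (nrow(v)) {
    if (any(!(v$kind %in% VITAL_KINDS)))
      fail("vitals: unknown kind '%s'", v$kind[which(!(v$kind %in% VITAL_KINDS))[1]])
    if (any(is.na(v$time))) fail("vitals: time missing")
    if (any(is.na(v$value) | !is.finite(v$value))) fail("vitals: value missing")
    chk <- function(kind, ok, what) {
      x <- v$value[v$kind == kind]
      if (length(x) && any(!ok(x))) fail("vitals: %s value out of range (%s): %s",
                                         kind, what, x[which(!ok(x))[1]])
    }
    chk("SPO2", function(x) x >= 0 & x <= 100, "[0, 100] %")
    chk("TEMP", function(x) x >= 25 & x <= 45, "[25, 45] degC")
    chk("HR",  function(x) x > 0, "> 0")
    chk("RR",  function(x) x > 0, "> 0")
    chk("SBP", function(x) x > 0, "> 0")
  }

  o <- s$oxygen_records
  if (nrow(o)) {
    if (any(!(o$device %in% O2_DEVICES)))
      fail("oxygen_records: unknown device '%s'",
           o$device[which(!(o$device %in% O2_DEVICES))[1]])
    if (any(o$flow_lpm < 0)) fail("oxygen_records: flow_lpm must be >= 0")
    if (any(o$device == "room_air" & o$flow_lpm != 0))
      fail("oxygen_records: room_air implies flow_lpm = 0")
  }

  g <- s$gcs_records
  if (nrow(g)) {
    if (any(is.na(g$value) | g$value < 3 | g$value > 15 | g$value != trunc(g$value)))
      fail("gcs_records: GCS value must be an integer in [3, 15], got %s",
           g$value[which(is.na(g$value) | g$value < 3 | g$value > 15)[1]])
  }

  if (!is.numeric(s$home_o2_lpm) || is.na(s$home_o2_lpm) || s$home_o2_lpm < 0)
    fail("home_o2_lpm must be >= 0")
  if (!is_count(as.numeric(s$prior_encounter_count)))
    fail("prior_encounter_count must be a non-negative integer")
  invisible(s)
}

#' @export
print.patient_snapshot <- function(x, ...) {
  cat(sprintf("<patient_snapshot %s> age %d, sex %s, %d problem(s), %d vital sample(s), trigger %s\n",
              x$patient_id, x$age_years, x$sex_assigned_at_birth,
              nrow(x$problem_list) + nrow(x$medical_history),
              nrow(x$vitals), format_ts(x$trigger_time)))
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

problems_to_list <- function(p) {
  if (!nrow(p)) return(list())
  lapply(seq_len(nrow(p)), function(i) list(
    snomed_code = p$snomed_code[i], status = p$status[i],
    recorded_time = format_ts(p$recorded_time[i])))
}

snapshot_to_list <- function(s) {
  list(
    patient_id = s$patient_id,
    age_years = s$age_years,
    sex_assigned_at_birth = s$sex_assigned_at_birth,
    administrative_sex = s$administrative_sex,
    problem_list = problems_to_list(s$problem_list),
    medical_history = problems_to_list(s$medical_history),
    chief_complaints = as.list(s$chief_complaints),
    vitals = if (!nrow(s$vitals)) list() else lapply(seq_len(nrow(s$vitals)),
      function(i) list(time = format_ts(s$vitals$time[i]),
                       kind = s$vitals$kind[i], value = s$vitals$value[i])),
    oxygen_records = if (!nrow(s$oxygen_records)) list() else
      lapply(seq_len(nrow(s$oxygen_records)), function(i) list(
        time = format_ts(s$oxygen_records$time[i]),
        device = s$oxygen_records$device[i],
        flow_lpm = s$oxygen_records$flow_lpm[i])),
    gcs_records = if (!nrow(s$gcs_records)) list() else
      lapply(seq_len(nrow(s$gcs_records)), function(i) list(
        time = format_ts(s$gcs_records$time[i]),
        value = s$gcs_records$value[i])),
    home_o2_lpm = s$home_o2_lpm,
    prior_encounter_count = s$prior_encounter_count,
    trigger_time = format_ts(s$trigger_time)
  )
}

list_to_problems <- function(x, field, line) {
  if (length(x) == 0) return(empty_problems())
  data.frame(
    snomed_code = vapply(x, function(e) as.character(e$snomed_code %||% ""), ""),
    status = normalize_enum(vapply(x, function(e) as.character(e$status %||% "history"), ""),
                            PROBLEM_STATUS, "history", paste0("line ", line, " ", field, " status")),
    recorded_time = parse_ts(vapply(x, function(e) as.character(e$recorded_time %||% NA_character_), ""),
                             paste0("line ", line, " ", field, " recorded_time")))
}

snapshot_from_list <- function(rec, line = NA, temp_unit = "C") {
  need <- function(f) {
    if (is.null(rec[[f]])) stop(sprintf("line %s: missing required field '%s'", line, f),
                                call. = FALSE)
    rec[[f]]
  }
  vit <- rec$vitals %||% list()
  vitals <- if (length(vit) == 0) empty_vitals() else {
    kinds <- vapply(vit, function(v) toupper(as.character(v$kind %||% "")), "")
    keep <- kinds %in% VITAL_KINDS
    if (any(!keep)) warning(sprintf("line %s: dropping vitals with unknown kind %s",
                                    line, paste(sQuote(unique(kinds[!keep])), collapse = ", ")),
                            call. = FALSE)
    vit <- vit[keep]; kinds <- kinds[keep]
    vals <- vapply(vit, function(v) as.numeric(v$value %||% NA_real_), 0)
    if (identical(temp_unit, "F")) vals[kinds == "TEMP"] <- (vals[kinds == "TEMP"] - 32) * 5 / 9
    data.frame(time = parse_ts(vapply(vit, function(v) as.character(v$time %||% NA_character_), ""),
                               paste0("line ", line, " vitals time")),
               kind = kinds, value = vals)
  }
  oxy <- rec$oxygen_records %||% list()
  oxygen <- if (length(oxy) == 0) empty_oxygen() else data.frame(
    time = parse_ts(vapply(oxy, function(o) as.character(o$time %||% NA_character_), ""),
                    paste0("line ", line, " oxygen time")),
    device = normalize_enum(vapply(oxy, function(o) as.character(o$device %||% "other"), ""),
                            O2_DEVICES, "other", paste0("line ", line, " oxygen device")),
    flow_lpm = vapply(oxy, function(o) as.numeric(o$flow_lpm %||% 0), 0))
  gcsl <- rec$gcs_records %||% list()
  gcs <- if (length(gcsl) == 0) empty_gcs() else data.frame(
    time = parse_ts(vapply(gcsl, function(g) as.character(g$time %||% NA_character_), ""),
                    paste0("line ", line, " gcs time")),
    value = vapply(gcsl, function(g) as.numeric(g$value %||% NA_real_), 0))

  s <- patient_snapshot(
    patient_id = as.character(need("patient_id")),
    age_years = need("age_years"),
    sex_assigned_at_birth = normalize_enum(rec$sex_assigned_at_birth %||% "unknown",
                                           SEX_AT_BIRTH, "unknown",
                                           paste0("line ", line, " sex_assigned_at_birth")),
    administrative_sex = normalize_enum(rec$administrative_sex %||% "unknown",
                                        ADMIN_SEX, "unknown",
                                        paste0("line ", line, " administrative_sex")),
    problem_list = list_to_problems(rec$problem_list %||% list(), "problem_list", line),
    medical_history = list_to_problems(rec$medical_history %||% list(), "medical_history", line),
    chief_complaints = unlist(rec$chief_complaints %||% list()) %||% character(0),
    vitals = vitals, oxygen = oxygen, gcs = gcs,
    home_o2_lpm = rec$home_o2_lpm %||% 0,
    prior_encounter_count = rec$prior_encounter_count %||% 0,
    trigger_time = need("trigger_time"),
    validate = FALSE)
  validate_snapshot(s, where = paste0("record at line ", line))
  s
}

#' Read ED-encounter snapshots from disk
#'
#' Two dialects are supported. `"jsonl"` is one JSON object per line with
#' field names exactly as in [patient_snapshot()] and ISO-8601 timestamps.
#' `"csv_bundle"` is a directory of flowsheet-style tables
#' (`patients.csv`, `problems.csv`, `vitals.csv`, `oxygen.csv`, `gcs.csv`,
#' `complaints.csv`) sharing `patient_id` keys.
#'
#' Temperatures are stored in degrees Celsius; a file recorded in Fahrenheit
#' can be declared with `temp_unit = "F"` and is converted at ingest, keeping
#' the scoring engine unit-pure.
#'
#' @param path file (jsonl) or directory (csv_bundle).
#' @param dialect `"jsonl"` or `"csv_bundle"`.
#' @param temp_unit unit of TEMP values in the source file, `"C"` or `"F"`.
#' @return list of `patient_snapshot`, in file order; every snapshot is
#'   validated and violations are reported with their record index.
#' @export
read_snapshots <- function(path, dialect = c("jsonl", "csv_bundle"),
                           temp_unit = c("C", "F")) {
  dialect <- match.arg(dialect)
  temp_unit <- match.arg(temp_unit)
  if (dialect == "jsonl") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines_idx <- which(nzchar(trimws(lines)))
    lapply(lines_idx, function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                      error = function(e) stop(sprintf("line %d: malformed JSON: %s",
                                                       i, conditionMessage(e)), call. = FALSE))
      snapshot_from_list(rec, line = i, temp_unit = temp_unit)
    })
  } else {
    read_csv_bundle(path, temp_unit)
  }
}

#' Write ED-encounter snapshots to disk
#'
#' Inverse of [read_snapshots()]: `read(write(x))` is the identity on valid
#' snapshot lists, and output bytes are stable for a given input (fixed field
#' ordering, ISO-8601 UTC timestamps).
#'
#' @param snapshots list of `patient_snapshot`.
#' @param path destination file (jsonl) or directory (csv_bundle).
#' @param dialect `"jsonl"` or `"csv_bundle"`.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(snapshots, path, dialect = c("jsonl", "csv_bundle")) {
  dialect <- match.arg(dialect)
  if (dialect == "jsonl") {
    lines <- vapply(snapshots, function(s) {
      as.character(jsonlite::toJSON(snapshot_to_list(s), auto_unbox = TRUE,
                                    digits = NA, null = "null"))
    }, "")
    writeLines(lines, path)
  } else {
    write_csv_bundle(snapshots, path)
  }
  invisible(path)
}

BUNDLE_FILES <- c("patients", "problems", "vitals", "oxygen", "gcs", "complaints")

write_csv_bundle <- function(snapshots, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- vapply(snapshots, function(s) s$patient_id, "")
  patients <- data.frame(
    patient_id = ids,
    age_years = vapply(snapshots, function(s) s$age_years, 0L),
    sex_assigned_at_birth = vapply(snapshots, function(s) s$sex_assigned_at_birth, ""),
    administrative_sex = vapply(snapshots, function(s) s$administrative_sex, ""),
    home_o2_lpm = vapply(snapshots, function(s) s$home_o2_lpm, 0),
    prior_encounter_count = vapply(snapshots, function(s) s$prior_encounter_count, 0L),
    trigger_time = vapply(snapshots, function(s) format_ts(s$trigger_time), ""))
  gather <- function(extract) do.call(rbind, lapply(snapshots, extract))
  problems <- gather(function(s) {
    rbind(
      if (nrow(s$problem_list)) cbind(patient_id = s$patient_id, source = "problem_list",
        data.frame(snomed_code = s$problem_list$snomed_code, status = s$problem_list$status,
                   recorded_time = format_ts(s$problem_list$recorded_time))),
      if (nrow(s$medical_history)) cbind(patient_id = s$patient_id, source = "medical_history",
        data.frame(snomed_code = s$medical_history$snomed_code, status = s$medical_history$status,
                   recorded_time = format_ts(s$medical_history$recorded_time))))
  })
  vitals <- gather(function(s) if (nrow(s$vitals))
    data.frame(patient_id = s$patient_id, time = format_ts(s$vitals$time),
               kind = s$vitals$kind, value = s$vitals$value))
  oxygen <- gather(function(s) if (nrow(s$oxygen_records))
    data.frame(patient_id = s$patient_id, time = format_ts(s$oxygen_records$time),
               device = s$oxygen_records$device, flow_lpm = s$oxygen_records$flow_lpm))
  gcs <- gather(function(s) if (nrow(s$gcs_records))
    data.frame(patient_id = s$patient_id, time = format_ts(s$gcs_records$time),
               value = s$gcs_records$value))
  complaints <- gather(function(s) if (length(s$chief_complaints))
    data.frame(patient_id = s$patient_id, complaint = s$chief_complaints))
  tables <- list(patients = patients,
                 problems = problems %||% data.frame(patient_id = character(0)),
                 vitals = vitals %||% data.frame(patient_id = character(0)),
                 oxygen = oxygen %||% data.frame(patient_id = character(0)),
                 gcs = gcs %||% data.frame(patient_id = character(0)),
                 complaints = complaints %||% data.frame(patient_id = character(0)))
  for (nm in BUNDLE_FILES) {
    write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

read_csv_bundle <- function(dir, temp_unit = "C") {
  pfile <- file.path(dir, "patients.csv")
  if (!file.exists(pfile)) stop("csv_bundle: patients.csv not found in ", dir, call. = FALSE)
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) read.csv(f, colClasses = "character") else NULL
  }
  patients <- rd("patients")
  problems <- rd("problems"); vitals <- rd("vitals"); oxygen <- rd("oxygen")
  gcs <- rd("gcs"); complaints <- rd("complaints")
  pick <- function(tab, id) if (is.null(tab) || !nrow(tab)) NULL else tab[tab$patient_id == id, , drop = FALSE]
  lapply(seq_len(nrow(patients)), function(i) {
    id <- patients$patient_id[i]
    pr <- pick(problems, id); vt <- pick(vitals, id); ox <- pick(oxygen, id)
    gc <- pick(gcs, id); cc <- pick(complaints, id)
    mk_problems <- function(src) {
      sub <- if (is.null(pr)) NULL else pr[pr$source == src, , drop = FALSE]
      if (is.null(sub) || !nrow(sub)) return(empty_problems())
      data.frame(snomed_code = sub$snomed_code,
                 status = normalize_enum(sub$status, PROBLEM_STATUS, "history",
                                         paste0(id, " problem status")),
                 recorded_time = parse_ts(sub$recorded_time, paste0(id, " recorded_time")))
    }
    vitdf <- if (is.null(vt) || !nrow(vt)) empty_vitals() else {
      vals <- as.numeric(vt$value)
      kinds <- toupper(vt$kind)
      if (identical(temp_unit, "F")) vals[kinds == "TEMP"] <- (vals[kinds == "TEMP"] - 32) * 5 / 9
      keep <- kinds %in% VITAL_KINDS
      if (any(!keep)) warning(sprintf("%s: dropping vitals with unknown kind %s", id,
                                      paste(sQuote(unique(kinds[!keep])), collapse = ", ")),
                              call. = FALSE)
      data.frame(time = parse_ts(vt$time[keep], paste0(id, " vitals time")),
                 kind = kinds[keep], value = vals[keep])
    }
    s <- patient_snapshot(
      patient_id = id,
      age_years = as.numeric(patients$age_years[i]),
      sex_assigned_at_birth = normalize_enum(patients$sex_assigned_at_birth[i],
                                             SEX_AT_BIRTH, "unknown", "sex_assigned_at_birth"),
      administrative_sex = normalize_enum(patients$administrative_sex[i],
                                          ADMIN_SEX, "unknown", "administrative_sex"),
      problem_list = mk_problems("problem_list"),
      medical_history = mk_problems("medical_history"),
      chief_complaints = if (is.null(cc) || !nrow(cc)) character(0) else cc$complaint,
      vitals = vitdf,
      oxygen = if (is.null(ox) || !nrow(ox)) empty_oxygen() else data.frame(
        time = parse_ts(ox$time, paste0(id, " oxygen time")),
        device = normalize_enum(ox$device, O2_DEVICES, "other", "oxygen device"),
        flow_lpm = as.numeric(ox$flow_lpm)),
      gcs = if (is.null(gc) || !nrow(gc)) empty_gcs() else data.frame(
        time = parse_ts(gc$time, paste0(id, " gcs time")),
        value = as.numeric(gc$value)),
      home_o2_lpm = as.numeric(patients$home_o2_lpm[i]),
      prior_encounter_count = as.numeric(patients$prior_encounter_count[i]),
      trigger_time = patients$trigger_time[i],
      validate = FALSE)
    validate_snapshot(s, where = paste0("patient ", id))
    s
  })
}
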