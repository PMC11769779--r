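#' Deterministic study-replica agreement records
#'
#' Constructs (no RNG involved) 500 paired automated-vs-physician score
#' records whose marginals reproduce the validation study's printed counts
#' simultaneously: 394 exact score matches, 442 class agreements, 477
#' high/low-risk agreements, a 15 vs 8 split of the 23 risk-band
#' discordances (automated score low while gold standard high, and the
#' reverse), automated risk classes of 112/91/84/80/133 patients (203
#' low-risk, 297 high-risk), 50 first-visit patients, 40 with acute PE on
#' CT, and component-error tags of 42 (cancer), 16 (heart failure), 27
#' (chronic lung disease), 23 (vitals) and 1 (other) across the 106
#' mismatched patients.
#'
#' Joint cells the study did not print (which patients combine two error
#' tags, the exact scores behind each agreement cell) are completed
#' minimally: the 109 tags are spread over the 106 mismatched patients by
#' giving exactly three patients a cancer+vitals double error, and every
#' mismatch is the smallest score perturbation its component weight allows.
#' An internal consistency check recomputes every marginal and fails loudly
#' if the construction drifts from the published counts.
#'
#' @return data frame of 500 agreement records (same shape as
#'   [score_cohort()] output).
#' @export
build_study_replica <- function() {
  bnd <- class_boundaries()

  # mismatched patients: n, automated (ePESI) total, gold-standard (pPESI)
  # total, error component tags. Score gaps equal the component weights
  # (cancer 30, heart failure / chronic lung disease / sex 10, vitals 20).
  mism <- rbind(
    # same class, different score
    data.frame(n = 18, epesi = 130, ppesi = 160, comps = "cancer"),
    data.frame(n = 8,  epesi = 40,  ppesi = 50,  comps = "heart_failure"),
    data.frame(n = 4,  epesi = 70,  ppesi = 80,  comps = "heart_failure"),
    data.frame(n = 10, epesi = 90,  ppesi = 100, comps = "chronic_lung_disease"),
    data.frame(n = 6,  epesi = 130, ppesi = 140, comps = "chronic_lung_disease"),
    data.frame(n = 2,  epesi = 130, ppesi = 150, comps = "vitals"),
    # different class, same risk band
    data.frame(n = 3,  epesi = 95,  ppesi = 145, comps = "cancer;vitals"),
    data.frame(n = 10, epesi = 95,  ppesi = 125, comps = "cancer"),
    data.frame(n = 6,  epesi = 110, ppesi = 140, comps = "cancer"),
    data.frame(n = 5,  epesi = 60,  ppesi = 70,  comps = "chronic_lung_disease"),
    data.frame(n = 9,  epesi = 95,  ppesi = 115, comps = "vitals"),
    data.frame(n = 2,  epesi = 55,  ppesi = 75,  comps = "vitals"),
    # risk-band discordant: automated low, gold standard high
    data.frame(n = 5,  epesi = 80,  ppesi = 110, comps = "cancer"),
    data.frame(n = 4,  epesi = 80,  ppesi = 90,  comps = "heart_failure"),
    data.frame(n = 6,  epesi = 80,  ppesi = 100, comps = "vitals"),
    # risk-band discordant: automated high, gold standard low
    data.frame(n = 6,  epesi = 90,  ppesi = 80,  comps = "chronic_lung_disease"),
    data.frame(n = 1,  epesi = 100, ppesi = 80,  comps = "vitals"),
    data.frame(n = 1,  epesi = 90,  ppesi = 80,  comps = "other"))

  # exact matches fill each automated risk class up to its published count
  class_target <- c(I = 112, II = 91, III = 84, IV = 80, V = 133)
  mism_expanded <- mism[rep(seq_len(nrow(mism)), mism$n), ]
  mism_class <- classify_pesi(mism_expanded$epesi, bnd)$pesi_class
  exact_n <- class_target - as.vector(table(factor(mism_class, names(class_target))))

  exact_scores <- list(I = c(38, 45, 52, 58, 65),
                       II = c(68, 72, 76, 80, 84),
                       III = c(88, 92, 96, 100, 104),
                       IV = c(108, 112, 116, 120, 124),
                       V = c(128, 135, 142, 155, 170))
  exact_tot <- unlist(lapply(names(class_target), function(cl)
    rep_len(exact_scores[[cl]], exact_n[[cl]])), use.names = FALSE)

  n_exact <- length(exact_tot)
  n_mism <- nrow(mism_expanded)
  epesi <- c(exact_tot, mism_expanded$epesi)
  ppesi <- c(exact_tot, mism_expanded$ppesi)
  comps <- c(rep("", n_exact), mism_expanded$comps)

  ecl <- classify_pesi(epesi, bnd)
  pcl <- classify_pesi(ppesi, bnd)

  n <- n_exact + n_mism
  first_visit <- logical(n)
  first_visit[seq_len(32)] <- TRUE                       # established-record matches
  first_visit[n_exact + seq_len(18)] <- TRUE             # comorbidity-error mismatches
  acute_pe <- logical(n)
  acute_pe[100 + seq_len(33)] <- TRUE
  acute_pe[n_exact + 18 + seq_len(7)] <- TRUE

  rec <- data.frame(
    patient_id = sprintf("R%03d", seq_len(n)),
    epesi_total = as.integer(epesi),
    epesi_class = ecl$pesi_class,
    epesi_low_risk = ecl$low_risk,
    ppesi_total = as.integer(ppesi),
    ppesi_class = pcl$pesi_class,
    ppesi_low_risk = pcl$low_risk,
    first_visit = first_visit,
    acute_pe_on_ct = acute_pe,
    error_components = comps)

  check_replica(rec)
  rec
}

has_component <- function(records, comp) {
  vapply(strsplit(records$error_components, ";", fixed = TRUE),
         function(x) comp %in% x, TRUE)
}

check_replica <- function(rec) {
  must <- function(cond, what) if (!cond) stop("study replica inconsistent: ", what,
                                               call. = FALSE)
  exact <- rec$epesi_total == rec$ppesi_total
  class_agree <- rec$epesi_class == rec$ppesi_class
  binary_agree <- rec$epesi_low_risk == rec$ppesi_low_risk
  must(nrow(rec) == 500, "n != 500")
  must(sum(exact) == 394, "exact matches != 394")
  must(sum(class_agree) == 442, "class agreements != 442")
  must(sum(binary_agree) == 477, "risk-band agreements != 477")
  must(sum(!binary_agree & rec$epesi_low_risk) == 15, "ePESI-low discordant != 15")
  must(sum(!binary_agree & !rec$epesi_low_risk) == 8, "ePESI-high discordant != 8")
  must(sum(rec$epesi_low_risk) == 203, "low-risk count != 203")
  cls <- table(factor(rec$epesi_class, c("I", "II", "III", "IV", "V")))
  must(all(cls == c(112, 91, 84, 80, 133)), "class distribution off")
  must(sum(rec$first_visit) == 50, "first-visit count != 50")
  must(sum(rec$acute_pe_on_ct) == 40, "acute-PE count != 40")
  counts <- vapply(ERROR_COMPONENT_NAMES, function(c) sum(has_component(rec, c)), 0)
  must(all(counts == c(42, 16, 27, 23, 1)), "component-error counts off")
  must(all(exact == (rec$error_components == "")), "error tags inconsistent with totals")
  must(all(!exact | class_agree) && all(!class_agree | binary_agree),
       "agreement nesting violated")
  invisible(rec)
}
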