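#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact two-sided interval from beta-distribution quantiles:
#' `lo = qbeta(alpha/2, k, n-k+1)` (0 when `k = 0`) and
#' `hi = qbeta(1-alpha/2, k+1, n-k)` (1 when `k = n`). Always contains
#' `k/n`; coverage is at least the nominal level (exact intervals are
#' conservative).
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `>= 1`.
#' @param level two-sided confidence level in (0, 1).
#' @return named numeric vector `c(lo, hi)`.
#' @export
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (!is_count(k) || !is_count(n) || n < 1) stop("k, n must be counts, n >= 1", call. = FALSE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Cohen's kappa with large-sample confidence interval
#'
#' Chance-corrected agreement between two raters over the same items:
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginal products. The interval uses the standard large-sample standard
#' error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`, clamped to `[-1, 1]`.
#' When both raters use a single shared label (`p_e = 1`) kappa is
#' undefined and reported as `NA` with a note.
#'
#' @param a,b label vectors of equal length over a shared label universe.
#' @param level confidence level.
#' @return list with `kappa`, `se`, `ci` (`c(lo, hi)`), `p_observed`,
#'   `p_expected`, `n` and (when undefined) `note`.
#' @export
cohen_kappa <- function(a, b, level = 0.95) {
  if (length(a) != length(b)) stop("cohen_kappa: length mismatch", call. = FALSE)
  n <- length(a)
  if (n < 1) stop("cohen_kappa: empty input", call. = FALSE)
  lv <- sort(unique(c(as.character(a), as.character(b))))
  fa <- factor(as.character(a), lv); fb <- factor(as.character(b), lv)
  tab <- table(fa, fb)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    return(list(kappa = NA_real_, se = NA_real_, ci = c(lo = NA_real_, hi = NA_real_),
                p_observed = po, p_expected = pe, n = n,
                note = "undefined: both raters use a single shared label"))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - level) / 2)
  list(kappa = kappa, se = se,
       ci = c(lo = max(-1, kappa - z * se), hi = min(1, kappa + z * se)),
       p_observed = po, p_expected = pe, n = n)
}

#' Odds ratio from univariable logistic regression
#'
#' Maximum-likelihood logistic fit of a binary outcome on an intercept and
#' one binary predictor (iteratively reweighted least squares, tolerance
#' 1e-10, at most 50 iterations), returning the exponentiated slope with
#' Wald confidence interval and p-value. For a single binary predictor with
#' all four contingency cells occupied this equals the cross-product ratio
#' `ad/bc`. An empty cell (separation) or a degenerate input is reported as
#' non-estimable with a diagnostic rather than an error.
#'
#' @param outcome,predictor logical (or 0/1) vectors of equal length.
#' @param level confidence level for the Wald interval.
#' @return list with `or`, `ci` (`c(lo, hi)`), `p`, `n`, `estimable`, and
#'   `diagnostic` when non-estimable.
#' @export
logistic_or <- function(outcome, predictor, level = 0.95) {
  if (length(outcome) != length(predictor)) stop("logistic_or: length mismatch", call. = FALSE)
  outcome <- as.logical(outcome); predictor <- as.logical(predictor)
  keep <- !is.na(outcome) & !is.na(predictor)
  outcome <- outcome[keep]; predictor <- predictor[keep]
  n <- length(outcome)
  not_estimable <- function(msg) list(or = NA_real_, ci = c(lo = NA_real_, hi = NA_real_),
                                      p = NA_real_, n = n, estimable = FALSE,
                                      diagnostic = msg)
  if (n == 0) return(not_estimable("no complete observations"))
  cells <- c(sum(outcome & predictor), sum(outcome & !predictor),
             sum(!outcome & predictor), sum(!outcome & !predictor))
  if (length(unique(outcome)) < 2) return(not_estimable("outcome takes a single value"))
  if (length(unique(predictor)) < 2) return(not_estimable("predictor takes a single value"))
  if (any(cells == 0))
    return(not_estimable(sprintf("empty 2x2 cell (a=%d b=%d c=%d d=%d): odds ratio not estimable (separation)",
                                 cells[1], cells[2], cells[3], cells[4])))
  fit <- glm(outcome ~ predictor, family = binomial(),
             control = list(epsilon = 1e-10, maxit = 50))
  sm <- summary(fit)$coefficients
  b <- sm["predictorTRUE", "Estimate"]
  se <- sm["predictorTRUE", "Std. Error"]
  if (!fit$converged || abs(b) > 15)
    return(not_estimable("fit did not converge (quasi-separation)"))
  z <- qnorm(1 - (1 - level) / 2)
  list(or = exp(b), ci = c(lo = exp(b - z * se), hi = exp(b + z * se)),
       p = sm["predictorTRUE", "Pr(>|z|)"], n = n, estimable = TRUE)
}

#' Bland-Altman agreement statistics
#'
#' Paired-difference summary for two measurements of the same quantity: the
#' mean difference (bias), the SD of the differences, and the 95% limits of
#' agreement `mean +/- 1.96 SD`. The per-point `(mean, difference)` series
#' used for plotting is returned alongside.
#'
#' @param a,b numeric score vectors of equal length (`>= 2`).
#' @return list with `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`, `n`
#'   and `points` (data frame with columns `mean`, `difference`).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("bland_altman: length mismatch", call. = FALSE)
  if (length(a) < 2) stop("bland_altman: need at least 2 pairs", call. = FALSE)
  d <- a - b
  md <- mean(d); sdd <- sd(d)
  list(mean_diff = md, sd_diff = sdd,
       loa_lower = md - 1.96 * sdd, loa_upper = md + 1.96 * sdd,
       n = length(a),
       points = data.frame(mean = (a + b) / 2, difference = d))
}

#' Full agreement validation of automated vs gold-standard scores
#'
#' Assembles the complete validation report from paired agreement records:
#' exact score agreement with exact binomial CI, risk-class and high/low-risk
#' agreement, the split of risk-band discordances by direction, Cohen's
#' kappa over risk classes, univariable logistic odds ratios for agreement
#' predictors, Bland-Altman statistics on the raw scores, the per-component
#' error table (denominator: all records), and a homogeneity test across the
#' component error proportions.
#'
#' The nesting invariant — an exact score match implies a class match
#' implies a risk-band match — is asserted on every evaluation.
#'
#' @param records data frame of agreement records ([score_cohort()],
#'   [build_study_replica()] or [read_agreement_records()]).
#' @param predictors subset of `c("low_risk", "first_visit")`; `low_risk`
#'   uses the gold-standard flag. Each is fitted in its own univariable
#'   model with exact-score agreement as the outcome.
#' @param level confidence level used throughout.
#' @param homogeneity `"chisq"` (default) tests homogeneity of the component
#'   error proportions with a chi-square test on the per-patient binary
#'   error indicators; `"anova"` fits a one-way ANOVA to the same indicators
#'   stacked by component.
#' @return object of class `agreement_report`.
#' @export
evaluate_agreement <- function(records,
                               predictors = c("low_risk", "first_visit"),
                               level = 0.95,
                               homogeneity = c("chisq", "anova")) {
  homogeneity <- match.arg(homogeneity)
  if (is.null(records) || nrow(records) == 0)
    stop("evaluate_agreement: no records", call. = FALSE)
  predictors <- match.arg(predictors, several.ok = TRUE)
  n <- nrow(records)
  exact <- records$epesi_total == records$ppesi_total
  class_agree <- records$epesi_class == records$ppesi_class
  binary_agree <- records$epesi_low_risk == records$ppesi_low_risk
  if (any(exact & !class_agree) || any(class_agree & !binary_agree))
    stop("agreement nesting violated: a score match must imply a class match, a class match a risk-band match",
         call. = FALSE)

  ors <- lapply(predictors, function(p) {
    x <- switch(p, low_risk = records$ppesi_low_risk, first_visit = records$first_visit)
    c(list(predictor = p), logistic_or(exact, x, level = level))
  })
  names(ors) <- predictors

  comp_counts <- vapply(ERROR_COMPONENT_NAMES,
                        function(c) sum(has_component(records, c)), 0)
  homogeneity_p <- if (sum(comp_counts) == 0) NA_real_ else if (homogeneity == "chisq") {
    suppressWarnings(chisq.test(rbind(comp_counts, n - comp_counts))$p.value)
  } else {
    ind <- unlist(lapply(ERROR_COMPONENT_NAMES,
                         function(c) as.numeric(has_component(records, c))))
    comp <- factor(rep(ERROR_COMPONENT_NAMES, each = n))
    summary(aov(ind ~ comp))[[1]][["Pr(>F)"]][1]
  }

  structure(list(
    n = n,
    exact_match = list(k = sum(exact), proportion = mean(exact), level = level,
                       ci = exact_binomial_ci(sum(exact), n, level)),
    class_agreement = list(k = sum(class_agree), proportion = mean(class_agree),
                           ci = exact_binomial_ci(sum(class_agree), n, level)),
    binary_agreement = list(k = sum(binary_agree), proportion = mean(binary_agree),
                            ci = exact_binomial_ci(sum(binary_agree), n, level)),
    discordant = list(epesi_low = sum(!binary_agree & records$epesi_low_risk),
                      epesi_high = sum(!binary_agree & !records$epesi_low_risk)),
    kappa = cohen_kappa(records$epesi_class, records$ppesi_class, level),
    odds_ratios = ors,
    bland_altman = bland_altman(records$epesi_total, records$ppesi_total),
    component_errors = lapply(setNames(nm = ERROR_COMPONENT_NAMES), function(c)
      list(count = unname(comp_counts[c]), proportion = unname(comp_counts[c]) / n)),
    homogeneity_p = homogeneity_p,
    homogeneity_method = homogeneity
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  pct <- function(p) sprintf("%.1f%%", 100 * p)
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  exact score match : %d/%d = %s (%d%% CI %s-%s)\n",
              x$exact_match$k, x$n, pct(x$exact_match$proportion),
              round(100 * x$exact_match$level),
              pct(x$exact_match$ci[["lo"]]), pct(x$exact_match$ci[["hi"]])))
  cat(sprintf("  risk-class match  : %d/%d = %s\n", x$class_agreement$k, x$n,
              pct(x$class_agreement$proportion)))
  cat(sprintf("  high/low match    : %d/%d = %s (discordant: %d scored low, %d scored high)\n",
              x$binary_agreement$k, x$n, pct(x$binary_agreement$proportion),
              x$discordant$epesi_low, x$discordant$epesi_high))
  if (!is.na(x$kappa$kappa))
    cat(sprintf("  class kappa       : %.3f (CI %.3f-%.3f)\n", x$kappa$kappa,
                x$kappa$ci[["lo"]], x$kappa$ci[["hi"]]))
  for (o in x$odds_ratios) {
    if (isTRUE(o$estimable))
      cat(sprintf("  OR (%s)%s: %.2f (CI %.2f-%.2f, p = %.3g)\n", o$predictor,
                  strrep(" ", max(0, 11 - nchar(o$predictor))), o$or,
                  o$ci[["lo"]], o$ci[["hi"]], o$p))
    else
      cat(sprintf("  OR (%s): not estimable (%s)\n", o$predictor, o$diagnostic))
  }
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman      : bias %.2f, LoA [%.2f, %.2f]\n",
              ba$mean_diff, ba$loa_lower, ba$loa_upper))
  errs <- vapply(x$component_errors, function(e) e$count, 0)
  if (sum(errs) > 0) {
    cat("  component errors  :",
        paste(sprintf("%s %d (%s)", names(errs), errs, pct(errs / x$n)), collapse = ", "),
        sprintf("\n  homogeneity p     : %.3g (%s)\n", x$homogeneity_p, x$homogeneity_method))
  } else cat("  component errors  : none\n")
  invisible(x)
}

report_to_list <- function(x) {
  list(
    n = x$n,
    exact_match = list(k = x$exact_match$k, proportion = x$exact_match$proportion,
                       level = x$exact_match$level,
                       ci_lo = unname(x$exact_match$ci[["lo"]]),
                       ci_hi = unname(x$exact_match$ci[["hi"]])),
    class_agreement = list(k = x$class_agreement$k,
                           proportion = x$class_agreement$proportion,
                           ci_lo = unname(x$class_agreement$ci[["lo"]]),
                           ci_hi = unname(x$class_agreement$ci[["hi"]])),
    binary_agreement = list(k = x$binary_agreement$k,
                            proportion = x$binary_agreement$proportion,
                            ci_lo = unname(x$binary_agreement$ci[["lo"]]),
                            ci_hi = unname(x$binary_agreement$ci[["hi"]])),
    discordant = x$discordant,
    kappa = list(point = x$kappa$kappa, se = x$kappa$se,
                 ci_lo = unname(x$kappa$ci[["lo"]]), ci_hi = unname(x$kappa$ci[["hi"]])),
    odds_ratios = lapply(unname(x$odds_ratios), function(o) list(
      predictor = o$predictor, or = o$or, ci_lo = unname(o$ci[["lo"]]),
      ci_hi = unname(o$ci[["hi"]]), p = o$p, estimable = isTRUE(o$estimable),
      diagnostic = o$diagnostic %||% NULL)),
    bland_altman = list(mean_diff = x$bland_altman$mean_diff,
                        sd_diff = x$bland_altman$sd_diff,
                        loa_lower = x$bland_altman$loa_lower,
                        loa_upper = x$bland_altman$loa_upper),
    component_errors = x$component_errors,
    homogeneity_p = x$homogeneity_p,
    homogeneity_method = x$homogeneity_method)
}

#' Serialize an agreement report to JSON
#'
#' The JSON document mirrors the report structure (the Bland-Altman point
#' series is omitted; export it separately with [write.csv()] from
#' `report$bland_altman$points`). [read_agreement_report()] restores a
#' numerically identical report summary.
#'
#' @param report an `agreement_report`.
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a serialized agreement report
#' @param path JSON file written by [write_agreement_report()].
#' @return nested list mirroring the report fields.
#' @export
read_agreement_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
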