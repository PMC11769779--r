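test_that("exact binomial CI matches the study interval and handles boundaries", {
  expect_equal(unname(exact_binomial_ci(0, 10)[1]), 0)
  expect_equal(unname(exact_binomial_ci(10, 10)[2]), 1)

  ci <- exact_binomial_ci(394, 500, 0.95)
  # published: 74.9% - 82.3%
  expect_lt(abs(ci[["lo"]] - 0.749), 0.002)
  expect_lt(abs(ci[["hi"]] - 0.823), 0.002)

  expect_error(exact_binomial_ci(5, 4), "exceed")
  expect_error(exact_binomial_ci(1, 10, level = 1), "level")
})

test_that("exact binomial CI agrees with a binomial-CDF bisection oracle", {
  set.seed(404)
  for (i in 1:40) {
    n <- sample(1:400, 1)
    k <- sample(0:n, 1)
    ci <- exact_binomial_ci(k, n, 0.95)
    oracle <- ci_bisect(k, n, 0.95)
    expect_lt(abs(ci[["lo"]] - oracle[1]), 1e-8)
    expect_lt(abs(ci[["hi"]] - oracle[2]), 1e-8)
    # the interval always contains the point estimate
    expect_lte(ci[["lo"]], k / n); expect_gte(ci[["hi"]], k / n)
  }
  # and with the standard library implementation
  bt <- binom.test(33, 40)$conf.int
  ci <- exact_binomial_ci(33, 40)
  expect_equal(unname(ci), as.vector(bt), tolerance = 1e-12)
})

test_that("exact intervals are conservative: empirical coverage at least nominal", {
  set.seed(11)
  for (p in c(0.1, 0.5, 0.9)) {
    k <- rbinom(2000, 100, p)
    lo <- ifelse(k == 0, 0, qbeta(0.025, k, 100 - k + 1))
    hi <- ifelse(k == 100, 1, qbeta(0.975, k + 1, 100 - k))
    covered <- mean(lo <= p & p <= hi)
    expect_gte(covered, 0.95)
  }
})

test_that("Cohen's kappa: agreement, disagreement, degenerate input", {
  a <- c("I", "II", "V", "II", "III", "I")
  k <- cohen_kappa(a, a)
  expect_equal(k$kappa, 1)
  expect_equal(k$p_observed, 1)

  # zero agreement with balanced symmetric marginals
  k2 <- cohen_kappa(c("x", "y", "x", "y"), c("y", "x", "y", "x"))
  expect_equal(k2$kappa, -1)

  k3 <- cohen_kappa(c("a", "a"), c("a", "a"))
  expect_true(is.na(k3$kappa))
  expect_match(k3$note, "undefined")

  expect_error(cohen_kappa(1:3, 1:2), "length")
})

test_that("kappa matches direct-from-definition evaluation on random tables", {
  # oracle: explicit double loop over the contingency table
  kappa_direct <- function(a, b) {
    lv <- unique(c(a, b)); n <- length(a)
    po <- mean(a == b)
    pe <- 0
    for (l in lv) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
    (po - pe) / (1 - pe)
  }
  set.seed(88)
  for (i in 1:50) {
    n <- sample(2:50, 1)
    a <- sample(c("pos", "neg"), n, replace = TRUE)
    b <- sample(c("pos", "neg"), n, replace = TRUE)
    if (length(unique(c(a, b))) < 2 || mean(a == b) == 1) next
    expect_equal(cohen_kappa(a, b)$kappa, kappa_direct(a, b), tolerance = 1e-12)
    # invariant to consistent relabeling
    expect_equal(cohen_kappa(chartr("pn", "qz", a), chartr("pn", "qz", b))$kappa,
                 cohen_kappa(a, b)$kappa, tolerance = 1e-12)
  }
})

test_that("logistic OR equals the 2x2 cross-product ratio", {
  v <- table_to_vectors(10, 10, 10, 10)
  expect_equal(logistic_or(v$outcome, v$predictor)$or, 1, tolerance = 1e-9)

  v <- table_to_vectors(30, 10, 15, 45)
  fit <- logistic_or(v$outcome, v$predictor)
  expect_equal(fit$or, 9, tolerance = 1e-6)
  expect_true(fit$estimable)
  expect_lt(fit$p, 0.001)

  set.seed(31)
  for (i in 1:50) {
    cells <- sample(1:40, 4, replace = TRUE)
    v <- table_to_vectors(cells[1], cells[2], cells[3], cells[4])
    fit <- logistic_or(v$outcome, v$predictor)
    expect_equal(fit$or, cells[1] * cells[4] / (cells[2] * cells[3]),
                 tolerance = 1e-6)
    # swapping the exposed level inverts the OR
    flipped <- logistic_or(v$outcome, !v$predictor)
    expect_equal(flipped$or, 1 / fit$or, tolerance = 1e-6)
  }
})

test_that("separation and degenerate tables are reported, not crashed on", {
  v <- table_to_vectors(10, 10, 0, 10)
  v$outcome <- rep(c(TRUE, TRUE, FALSE, FALSE), c(10, 10, 0, 10))
  v$predictor <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 10, 0, 10))
  fit <- logistic_or(v$outcome, v$predictor)
  expect_false(fit$estimable)
  expect_match(fit$diagnostic, "empty")

  fit2 <- logistic_or(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_false(fit2$estimable)
  expect_match(fit2$diagnostic, "outcome")
})

test_that("Bland-Altman statistics match the direct formulas", {
  x <- c(80, 95, 120, 66)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_upper - ba$loa_lower, 0)

  ba2 <- bland_altman(x + 5, x)
  expect_equal(ba2$mean_diff, 5)
  expect_equal(ba2$sd_diff, 0)

  set.seed(64)
  a <- rnorm(100, 100, 30); b <- a + rnorm(100, -2, 6)
  ba3 <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba3$mean_diff, mean(d))
  expect_equal(ba3$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba3$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba3$points$mean, (a + b) / 2)
  expect_error(bland_altman(1:3, 1:2), "length")
})

test_that("evaluate_agreement asserts the agreement nesting invariant", {
  rec <- build_study_replica()
  rep <- evaluate_agreement(rec)
  expect_lte(rep$exact_match$k, rep$class_agreement$k)
  expect_lte(rep$class_agreement$k, rep$binary_agreement$k)
  expect_lte(rep$binary_agreement$k, rep$n)

  corrupt <- rec
  corrupt$epesi_class[corrupt$epesi_total == corrupt$ppesi_total][1] <- "V"
  expect_error(evaluate_agreement(corrupt), "nesting")

  expect_error(evaluate_agreement(rec[0, ]), "no records")
})

test_that("agreement reports serialize to JSON and back without loss", {
  rep <- evaluate_agreement(build_study_replica())
  f <- withr::local_tempfile(fileext = ".json")
  write_agreement_report(rep, f)
  back <- read_agreement_report(f)
  expect_equal(back$n, rep$n)
  expect_equal(back$exact_match$proportion, rep$exact_match$proportion)
  expect_equal(back$exact_match$ci_lo, unname(rep$exact_match$ci[["lo"]]))
  expect_equal(back$kappa$point, rep$kappa$kappa)
  expect_equal(back$bland_altman$sd_diff, rep$bland_altman$sd_diff)
  expect_equal(back$component_errors$cancer$count, 42)
  expect_equal(back$odds_ratios[[1]]$or, rep$odds_ratios$low_risk$or)
})

test_that("the chi-square and ANOVA homogeneity variants both flag heterogeneity", {
  rec <- build_study_replica()
  p_chi <- evaluate_agreement(rec, homogeneity = "chisq")$homogeneity_p
  p_aov <- evaluate_agreement(rec, homogeneity = "anova")$homogeneity_p
  expect_lt(p_chi, 0.001)
  expect_lt(p_aov, 0.001)
})
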