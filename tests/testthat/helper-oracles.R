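# Independent oracles used by several test files.

# Exact binomial CI by bisection on the binomial CDF (no beta quantiles):
# lower bound solves P(X >= k | p) = alpha/2, upper solves P(X <= k | p) = alpha/2.
ci_bisect <- function(k, n, level = 0.95, tol = 1e-12) {
  alpha <- 1 - level
  bisect <- function(f) {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else bisect(function(p) (1 - pbinom(k - 1, n, p)) - alpha / 2)
  upper <- if (k == n) 1 else bisect(function(p) alpha / 2 - pbinom(k, n, p))
  c(lower, upper)
}

# expand a 2x2 table (a: outcome+/pred+, b: outcome+/pred-, c: outcome-/pred+,
# d: outcome-/pred-) into observation vectors
table_to_vectors <- function(a, b, c, d) {
  list(outcome = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
       predictor = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)))
}
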