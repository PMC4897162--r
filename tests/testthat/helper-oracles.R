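# Independent oracles used across tests.

# Development coefficient by an independent route: the estimator is the log
# of the through-origin least-squares slope of m(k) on m(k-1).
oracle_development <- function(mg) {
  L <- length(mg)
  fit <- stats::lm(y ~ 0 + x, data = data.frame(x = mg[-L], y = mg[-1]))
  log(unname(stats::coef(fit)[1]))
}

# Amplitude by ordinary simple regression (with intercept) of the
# accumulated sequence on the exponential regressor.
oracle_amplitude <- function(a, acc) {
  k <- seq.int(2, length(acc) + 1)
  fit <- stats::lm(y ~ x, data = data.frame(x = exp(a * (k - 1)), y = acc))
  unname(stats::coef(fit)["x"])
}

# Transition counts by cross-tabulation of the lagged path.
oracle_transition_counts <- function(path, r, m) {
  from <- factor(path[seq_len(length(path) - r)], levels = 1:m)
  to <- factor(path[seq_len(length(path) - r) + r], levels = 1:m)
  unclass(table(from, to))
}

table3_space <- function() {
  state_space_fixed(c(0.60, 0.75, 0.90, 1.05, 1.20))
}
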