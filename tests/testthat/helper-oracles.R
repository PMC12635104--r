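# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Conjugate-normal posterior for a constant scalar state observed with known
# per-observation noise: the closed form a zero-process-noise filter must
# reproduce.
conjugate_posterior <- function(p0, q0, mu, sigma) {
  prec <- 1 / q0^2 + sum(1 / sigma^2)
  list(p = (p0 / q0^2 + sum(mu / sigma^2)) / prec,
       q = sqrt(1 / prec))
}

# Exhaustive signed-rank oracle: two-sided p-value by enumerating all 2^n
# sign assignments of the (tie-free) absolute differences.
wilcoxon_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12, !any(duplicated(abs(d))))
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  centre <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% rk)
  mean(abs(w_all - centre) >= abs(w_obs - centre) - 1e-9)
}

# Equivalent-diameter of the bright structure in a noise-free phantom
# render, by pixel counting.
measured_diameter <- function(pixels, threshold = 0.5) {
  2 * sqrt(sum(pixels > threshold) / pi)
}

make_records <- function(predicted, reference, ...) {
  data.frame(predicted_ga_days = predicted, reference_ga_days = reference, ...)
}
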