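# Independent oracles used against the package implementations.

# Bisection solver for the closed-association mass balance
# c = m (c_s + N K c_s^N), independent of the package's Newton/log-space
# path.
oracle_subunit_conc <- function(c_total, K, N, m = 2) {
  if (c_total == 0) return(0)
  f <- function(cs) m * (cs + N * K * cs^N) - c_total
  lo <- 0
  hi <- c_total / m
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Closed-form onset: at oligomer mass fraction t,
# c_s = (t / ((1 - t) N K))^(1/(N-1)) and c = m c_s / (1 - t).
oracle_onset <- function(K, N, t, m = 2) {
  cs <- (t / ((1 - t) * N * K))^(1 / (N - 1))
  m * cs / (1 - t)
}

# decay_fit stub for regression-level tests
make_decay_fit <- function(gamma, q, beta = 0.9) {
  structure(list(beta = beta, gamma = gamma, q = q,
                 residual_rms = 0, n_used = NA_integer_),
            class = "decay_fit")
}
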