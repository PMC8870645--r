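# Shared fixtures, all generated in code.

# Exponentially prolonged pulse: a unit event at `onset` whose activity is
# sustained by a recurrent self-connection `lam` (no firing-rate floor).
prolonged_pulse <- function(n, onset, lam = 0.8) {
  x <- numeric(n)
  x[onset:n] <- lam^(0:(n - onset))
  x
}

# Accumulate the reduced STDP rule over a pair of activity histories.
reduced_over_history <- function(v, u, p = stdp_params(), dt = 1) {
  dw <- 0
  for (t in 2:length(v)) {
    dw <- stdp_reduced_update(dw, v[t], v[t - 1], u[t], u[t - 1], p, dt)
  }
  dw
}

# A fixed zero-mean input sample with distinct second-moment eigenvalues,
# plus its empirical second-moment matrix (the brute-force Oja oracle).
oja_fixture <- function(n = 200, seed = 42) {
  set.seed(seed)
  U <- cbind(stats::rnorm(n, 0, sqrt(3)), stats::rnorm(n, 0, 1),
             stats::rnorm(n, 0, sqrt(0.5)))
  list(U = U, M = crossprod(U) / n)
}

# Angle between two directions (sign-invariant), in radians.
direction_angle <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))))
}

# Noise-free four-class prototype set shared across assembly tests.
clean_protos <- function() make_prototypes(4, 64, sigma_noise = 0, seed = 1)
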