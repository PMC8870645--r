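test_that("oja_update matches hand-evaluated cases", {
  p <- oja_params(tau_w = 1, beta = 1)
  expect_equal(oja_update(c(0, 0), v = 1, u = c(1, 0), p, dt = 1), c(1, 0))
  w <- c(0.4, -0.2)
  expect_equal(oja_update(w, v = 0, u = c(3, 7), p, dt = 1), w)
  # general algebra at one step
  expect_equal(oja_update(c(1, 1), v = 2, u = c(1, 2), oja_params(2, 0.5), 0.1),
               c(1, 1) + (0.1 / 2) * (2 * c(1, 2) - 0.5 * 4 * c(1, 1)))
  expect_error(oja_update(c(1, 2), 1, c(1, 2, 3), p, 1), "length")
  expect_error(oja_update(c(1), 1, c(1), p, dt = -1), "dt")
})

test_that("Oja converges to the leading eigenvector of the second moment", {
  fx <- oja_fixture()
  e1 <- eigen(fx$M)$vectors[, 1]
  w <- c(1, 1, 1) / sqrt(3)
  dt <- 5e-5
  n <- nrow(fx$U)
  p <- oja_params()
  for (k in seq_len(round(8 / dt))) {
    u <- fx$U[((k - 1) %% n) + 1, ]
    w <- oja_update(w, sum(w * u), u, p, dt)
  }
  expect_lt(direction_angle(w, e1), 1e-3)
  expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-3)
})

test_that("Oja norm stays bounded under self-generated activity", {
  set.seed(7)
  p <- oja_params()
  w <- c(0.1, 0.1, 0.1)
  sup_norm <- 0
  for (k in 1:1e5) {
    u <- rnorm(3)
    w <- oja_update(w, sum(w * u), u, p, dt = 0.01)
    sup_norm <- max(sup_norm, sqrt(sum(w^2)))
  }
  expect_lt(sup_norm, 10)
})

test_that("bcm_update matches hand cases and is synchronous", {
  p <- bcm_params(tau_w = 1, tau_theta = 1)
  # v = theta kills the weight derivative
  out <- bcm_update(c(0.3, 0.3), theta = 2, v = 2, u = c(1, 1), p, dt = 1)
  expect_equal(out$w, c(0.3, 0.3))
  # pure LTP sign case
  out <- bcm_update(c(0, 0), theta = 0, v = 1, u = c(1, 0), p, dt = 1)
  expect_equal(out$w, c(1, 0))
  # synchronous: theta update uses pre-update v^2 - theta
  out <- bcm_update(c(0), theta = 1, v = 3, u = c(1), bcm_params(1, 4), dt = 1)
  expect_equal(out$theta, 1 + (9 - 1) / 4)
  expect_error(bcm_update(c(1, 2), 0, 1, c(1), p, 1), "length")
})

test_that("BCM threshold follows its closed-form exponential", {
  tau_theta <- 1
  v <- 2
  dt <- 1e-4
  p <- bcm_params(tau_w = 1, tau_theta = tau_theta)
  # local (per-step) agreement: one update from the exact value
  times <- seq(0, 5, by = 0.25)
  for (t0 in times) {
    theta_exact <- v^2 + (0 - v^2) * exp(-t0 / tau_theta)
    stepped <- bcm_update(0, theta_exact, v, 0, p, dt)$theta
    exact_next <- v^2 + (0 - v^2) * exp(-(t0 + dt) / tau_theta)
    expect_lt(abs(stepped - exact_next), 1e-6)
  }
  # global trajectory: theta ~ v^2 after 10 tau, and |theta - v^2| decays
  # monotonically
  theta <- 0
  dt <- 1e-3
  gap <- abs(theta - v^2)
  monotone <- TRUE
  for (k in seq_len(round(10 * tau_theta / dt))) {
    theta <- bcm_update(0, theta, v, 0, p, dt)$theta
    g <- abs(theta - v^2)
    if (g > gap + 1e-12) monotone <- FALSE
    gap <- g
  }
  expect_true(monotone)
  expect_equal(theta, 4, tolerance = 1e-3)
})

test_that("stdp_reduced_update reproduces the signed one-step rule", {
  expect_equal(
    stdp_reduced_update(0, v_t = 1, v_prev = 0, u_t = 0, u_prev = 1,
                        stdp_params(h = c(1, 0))), 1)
  expect_equal(
    stdp_reduced_update(0, v_t = 0, v_prev = 1, u_t = 1, u_prev = 0,
                        stdp_params(h = c(1, -1))), -1)
  # constant activity cancels under the antisymmetric rule
  for (c0 in c(0.2, 1, 3)) {
    expect_equal(
      stdp_reduced_update(0.5, c0, c0, c0, c0, stdp_params(h = c(1, -1))),
      0.5)
  }
  # tau_w and dt scale the increment
  expect_equal(
    stdp_reduced_update(0, 1, 0, 0, 1, stdp_params(c(1, 0), tau_w = 4),
                        dt = 2), 0.5)
  expect_error(stdp_params(h = c(2, 0)))
})

test_that("stdp_window_H is odd, decays as a/tau and cuts off at tau_max", {
  win <- stdp_window(a = 1 / 40, tau_max = 50, eps = 1)
  expect_equal(stdp_window_H(20, win), 0.00125)
  expect_equal(stdp_window_H(-20, win), -0.00125)
  expect_equal(stdp_window_H(80, win), 0)
  expect_equal(stdp_window_H(0, win), 0)
  taus <- seq(-60, 60, by = 0.5)
  expect_equal(stdp_window_H(-taus, win), -stdp_window_H(taus, win))
  # eps regularizes near zero: |H| never exceeds a/eps
  expect_true(all(abs(stdp_window_H(taus, win)) <= win$a / win$eps))
})

test_that("integral STDP oracle gives LTP for pre-before-post, LTD reversed", {
  win <- stdp_window()
  n <- 120
  u <- prolonged_pulse(n, 10)        # presynaptic first
  v <- prolonged_pulse(n, 15)
  expect_gt(stdp_integral_update(0, v, u, win), 0)
  expect_lt(stdp_integral_update(0, u, v, win), 0)   # post first
  expect_equal(stdp_integral_update(0.3, numeric(n), numeric(n), win), 0.3)
  expect_error(stdp_integral_update(0, numeric(5), numeric(6), win), "grid")
})

test_that("reduced rule sign matches the quadrature oracle for all two-pulse separations", {
  win <- stdp_window()   # 50 ms cutoff, 1 ms grid
  n <- 160
  p <- stdp_params(h = c(1, -1))
  for (sep in 1:50) {
    u <- prolonged_pulse(n, 10)
    v <- prolonged_pulse(n, 10 + sep)
    expect_equal(sign(reduced_over_history(v, u, p)),
                 sign(stdp_integral_update(0, v, u, win)),
                 label = paste("pre-first separation", sep))
    expect_equal(sign(reduced_over_history(u, v, p)),
                 sign(stdp_integral_update(0, u, v, win)),
                 label = paste("post-first separation", sep))
  }
})
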