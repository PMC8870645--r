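#' Oja rule parameters
#'
#' @param tau_w Weight time constant (positive). The effective learning rate
#'   is `dt / tau_w`; the default `tau_w = 1` leaves the rate under the
#'   control of `dt`.
#' @param beta Norm-penalty coefficient (positive). With `beta = 1` the rule
#'   drives the weight vector towards unit norm.
#' @return A list of class `oja_params`.
#' @export
oja_params <- function(tau_w = 1, beta = 1) {
  stopifnot(is.numeric(tau_w), tau_w > 0, is.numeric(beta), beta > 0)
  structure(list(tau_w = tau_w, beta = beta), class = "oja_params")
}

#' BCM rule parameters
#'
#' @param tau_w Weight time constant (positive).
#' @param tau_theta Time constant of the sliding threshold (positive).
#' @param theta0 Initial threshold value (non-negative).
#' @return A list of class `bcm_params`.
#' @export
bcm_params <- function(tau_w = 1, tau_theta = 1, theta0 = 0) {
  stopifnot(is.numeric(tau_w), tau_w > 0,
            is.numeric(tau_theta), tau_theta > 0,
            is.numeric(theta0), theta0 >= 0)
  structure(list(tau_w = tau_w, tau_theta = tau_theta, theta0 = theta0),
            class = "bcm_params")
}

#' Reduced-STDP rule parameters
#'
#' The reduced rule collapses the continuous STDP window into a two-entry
#' sign vector `h`: the weight change is
#' `(dt/tau_w) * (h[1] * v(t) u(t-1) + h[2] * v(t-1) u(t))`.
#' `h = c(1, -1)` recovers the antisymmetric LTP/LTD rule; `h = c(1, 0)`
#' keeps only the potentiation term.
#'
#' @param h Length-2 vector with entries in `{-1, 0, 1}`.
#' @param tau_w Weight time constant (positive).
#' @return A list of class `stdp_params`.
#' @export
stdp_params <- function(h = c(1, -1), tau_w = 1) {
  stopifnot(is.numeric(h), length(h) == 2L, all(h %in% c(-1, 0, 1)),
            is.numeric(tau_w), tau_w > 0)
  structure(list(h = as.numeric(h), tau_w = tau_w), class = "stdp_params")
}

#' Continuous STDP window parameters
#'
#' The temporal window is `H(tau) = sign(tau) * a / max(|tau|, eps)` for
#' `0 < |tau| <= tau_max` and 0 beyond the cutoff: potentiation decays as
#' the inverse of the pre-before-post lag, depression mirrors it with
#' opposite sign, and no plasticity occurs outside a 50 ms window. The
#' divergence at `tau -> 0` is regularized by `eps`.
#'
#' @param a Window amplitude (positive; default 1/40).
#' @param tau_max Cutoff lag in milliseconds (positive; default 50).
#' @param eps Regularization floor for `|tau|` near 0 (positive; default 1).
#' @return A list of class `stdp_window`.
#' @export
stdp_window <- function(a = 1 / 40, tau_max = 50, eps = 1) {
  stopifnot(is.numeric(a), a > 0, is.numeric(tau_max), tau_max > 0,
            is.numeric(eps), eps > 0)
  structure(list(a = a, tau_max = tau_max, eps = eps), class = "stdp_window")
}

#' Oja weight update
#'
#' One forward-Euler step of the Oja rule
#' `tau_w dw/dt = v u - beta v^2 w`: Hebbian growth plus a norm penalty
#' that keeps the weight vector bounded (for `beta = 1` it converges to the
#' unit-norm leading eigenvector of the input second-moment matrix).
#'
#' @param w Weight vector.
#' @param v Postsynaptic activity (scalar).
#' @param u Presynaptic activity vector, same length as `w`.
#' @param p An [oja_params()] bundle.
#' @param dt Step size (positive).
#' @return Updated weight vector.
#' @export
oja_update <- function(w, v, u, p = oja_params(), dt = 1) {
  stopifnot(inherits(p, "oja_params"), is.numeric(v), length(v) == 1L,
            is.numeric(dt), length(dt) == 1L)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (length(w) != length(u)) {
    stop("`w` and `u` must have the same length", call. = FALSE)
  }
  euler_step(w, (v * u - p$beta * v^2 * w) / p$tau_w, dt)
}

#' BCM weight and threshold update
#'
#' One synchronous forward-Euler step of the BCM pair
#' `tau_w dw/dt = v u (v - theta)` and `tau_theta dtheta/dt = v^2 - theta`.
#' Both updates use the pre-update values of `w` and `theta`, so the order
#' of the two lines cannot matter. Activity above the sliding threshold
#' potentiates, below it depresses, and the threshold itself chases `v^2`.
#'
#' @param w Weight vector.
#' @param theta Current sliding threshold (scalar).
#' @param v Postsynaptic activity (scalar).
#' @param u Presynaptic activity vector, same length as `w`.
#' @param p A [bcm_params()] bundle.
#' @param dt Step size (positive).
#' @return List with elements `w` (updated weights) and `theta` (updated
#'   threshold).
#' @export
bcm_update <- function(w, theta, v, u, p = bcm_params(), dt = 1) {
  stopifnot(inherits(p, "bcm_params"), is.numeric(theta), length(theta) == 1L,
            is.numeric(v), length(v) == 1L, is.numeric(dt), dt > 0)
  if (length(w) != length(u)) {
    stop("`w` and `u` must have the same length", call. = FALSE)
  }
  list(
    w = euler_step(w, v * u * (v - theta) / p$tau_w, dt),
    theta = euler_step(theta, (v^2 - theta) / p$tau_theta, dt)
  )
}

#' Reduced one-step STDP update
#'
#' The extreme discretization of the STDP integral: only activities one
#' step apart interact, through the sign vector `h`. With `h = c(1, -1)`
#' the change is `(dt/tau_w) * (v(t) u(t-1) - v(t-1) u(t))` — potentiation
#' when the presynaptic neuron led, depression when it lagged.
#'
#' @param w Current weight (scalar or array; updated elementwise).
#' @param v_t,v_prev Postsynaptic activity at the current and previous step.
#' @param u_t,u_prev Presynaptic activity at the current and previous step.
#' @param p An [stdp_params()] bundle.
#' @param dt Step size (positive).
#' @return Updated weight, same shape as `w`.
#' @export
stdp_reduced_update <- function(w, v_t, v_prev, u_t, u_prev,
                                p = stdp_params(), dt = 1) {
  stopifnot(inherits(p, "stdp_params"), is.numeric(dt), dt > 0)
  w + (dt / p$tau_w) * (p$h[1] * v_t * u_prev + p$h[2] * v_prev * u_t)
}

#' Evaluate the continuous STDP window
#'
#' @param tau Lag(s) `t_post - t_pre` in milliseconds; vectorized.
#' @param win An [stdp_window()] bundle.
#' @return `H(tau)`: positive for small positive lags, negative for small
#'   negative lags (odd symmetry), zero at 0 and beyond the cutoff.
#' @export
stdp_window_H <- function(tau, win = stdp_window()) {
  stopifnot(inherits(win, "stdp_window"), is.numeric(tau))
  out <- sign(tau) * win$a / pmax(abs(tau), win$eps)
  out[abs(tau) > win$tau_max] <- 0
  out
}

#' Quadrature STDP update over activity histories
#'
#' Brute-force evaluation of the windowed STDP integral
#' `tau_w dw/dt = int_0^inf H(tau) v(t) u(t - tau) + H(-tau) v(t - tau) u(t) dtau`
#' accumulated over a pair of sampled activity histories. The lag integral
#' is a rectangle-rule sum on the sampling grid, truncated at the window
#' cutoff; samples before the start of the histories are treated as silent.
#' This is the reference against which the reduced one-step rule is
#' cross-checked.
#'
#' @param w Current weight (scalar).
#' @param v_history,u_history Numeric vectors: post- and presynaptic
#'   activities sampled on the same grid with spacing `dt`.
#' @param win An [stdp_window()] bundle (lags in the same time unit as `dt`).
#' @param tau_w Weight time constant (positive).
#' @param dt Grid spacing (positive).
#' @return Updated weight after integrating over the whole history.
#' @export
stdp_integral_update <- function(w, v_history, u_history,
                                 win = stdp_window(), tau_w = 1, dt = 1) {
  stopifnot(inherits(win, "stdp_window"), is.numeric(dt), dt > 0,
            is.numeric(tau_w), tau_w > 0)
  if (length(v_history) != length(u_history)) {
    stop("histories must be sampled on the same grid", call. = FALSE)
  }
  n <- length(v_history)
  k_max <- floor(win$tau_max / dt)
  H_pos <- stdp_window_H(seq_len(k_max) * dt, win)
  acc <- 0
  for (t in seq_len(n)[-1]) {
    ks <- seq_len(min(k_max, t - 1L))
    acc <- acc +
      v_history[t] * sum(H_pos[ks] * u_history[t - ks]) -
      sum(H_pos[ks] * v_history[t - ks]) * u_history[t]
  }
  w + (dt * dt / tau_w) * acc
}
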