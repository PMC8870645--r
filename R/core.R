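#' Clipped linear activation
#'
#' Piecewise-linear activation used by every rate unit in the package:
#' values above 1 saturate at 1, values in `[l, 1]` pass through unchanged,
#' and values below the firing threshold `l` are silenced to 0. The default
#' threshold `l = 0.1` is the value used in all shipped experiment
#' configurations.
#'
#' @param x Numeric vector (or matrix) of pre-activation values.
#' @param l Firing threshold, a single number in `[0, 1)`.
#' @return Object of the same shape as `x` with entries in `{0} U [l, 1]`.
#' @examples
#' sigma_l(c(1.5, 0.5, 0.05), l = 0.1)
#' @export
sigma_l <- function(x, l = 0.1) {
  stopifnot(is.numeric(x), is.numeric(l), length(l) == 1L)
  if (is.na(l) || l < 0 || l >= 1) {
    stop("`l` must lie in [0, 1)", call. = FALSE)
  }
  out <- x
  out[x > 1] <- 1
  out[x < l] <- 0
  out
}

#' Weight-clipping read function
#'
#' Returns an independent copy of a weight matrix with every entry clipped
#' into `[0, 1]` (the zero-threshold special case of [sigma_l()]). Raw
#' learned weights may grow beyond `[0, 1]`; the network dynamics only ever
#' see weights through this read function, so the caller's matrix is never
#' mutated.
#'
#' @param W Numeric matrix (or vector) of raw synaptic weights; all entries
#'   must be finite.
#' @return A clipped copy of `W`, entries in `[0, 1]`.
#' @examples
#' kappa(matrix(c(1.3, -0.2, 0.7, 0), 2, 2))
#' @export
kappa <- function(W) {
  stopifnot(is.numeric(W))
  if (!all(is.finite(W))) {
    stop("`W` must contain only finite entries", call. = FALSE)
  }
  pmin(pmax(W, 0), 1)
}

#' Heaviside step with threshold
#'
#' Binary readout used to decide presence/absence of a stimulus. The
#' boundary `x == theta_H` returns 1: a response exactly at threshold counts
#' as recognized, so recognition sets are closed.
#'
#' @param x Numeric vector.
#' @param theta_H Threshold (finite scalar, or vector recycled against `x`).
#' @return Vector of 0/1 values.
#' @export
heaviside <- function(x, theta_H) {
  stopifnot(is.numeric(x), is.numeric(theta_H), all(is.finite(theta_H)))
  as.numeric(x >= theta_H)
}

#' Linear firing-rate response
#'
#' The elementary rate neuron: activity is `f(w . u)` for presynaptic
#' activities `u`, weights `w` and activation `f`.
#'
#' @param w Numeric weight vector.
#' @param u Numeric vector of presynaptic activities, same length as `w`.
#' @param f Activation function; defaults to the identity.
#' @return A single number, `f(sum(w * u))`.
#' @export
linear_rate <- function(w, u, f = identity) {
  stopifnot(is.numeric(w), is.numeric(u))
  if (length(w) != length(u)) {
    stop("`w` and `u` must have the same length", call. = FALSE)
  }
  f(sum(w * u))
}

#' Forward Euler step
#'
#' Discretizes the continuous-time plasticity rules with a single explicit
#' Euler update `state + dt * derivative`.
#'
#' @param state Numeric vector of state values.
#' @param derivative Numeric vector of time derivatives, same shape.
#' @param dt Step size, a positive number.
#' @return Updated state vector.
#' @export
euler_step <- function(state, derivative, dt) {
  stopifnot(is.numeric(state), is.numeric(derivative),
            is.numeric(dt), length(dt) == 1L, dt > 0)
  if (length(state) != length(derivative)) {
    stop("`state` and `derivative` must have the same shape", call. = FALSE)
  }
  state + dt * derivative
}

#' Simulation clock
#'
#' A trivial discrete clock: `step` counts ticks from 0 and `dt` gives the
#' amount of protocol time (seconds) represented by one tick.
#'
#' @param dt Seconds per step, positive.
#' @return An object of class `sim_clock` with fields `step` and `dt`.
#' @export
sim_clock <- function(dt = 1) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  structure(list(step = 0L, dt = dt), class = "sim_clock")
}

#' Advance a simulation clock by one tick
#'
#' @param clock A [sim_clock()] object.
#' @return The clock with `step` incremented by 1.
#' @export
tick <- function(clock) {
  stopifnot(inherits(clock, "sim_clock"))
  clock$step <- clock$step + 1L
  clock
}
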