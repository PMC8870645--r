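#' Construct a temporal-difference reward circuit
#'
#' The TD circuit attaches a tapped delay line ("temporal chain") of length
#' `T` to each of the `K` ring neurons: the first chain slot mirrors the
#' ring activity and every slot hands its content to the next one each
#' step, so slot `j` holds the ring activity from `j - 1` steps ago. A
#' collector neuron sums weighted slot-to-slot activity differences,
#' `y(t) = sum_ij w[i, j] (x[i, j](t) - x[i, j](t - 1))`, and the
#' dopaminergic unit reports the prediction error `z(t) = reward(t) + y(t)`.
#' The chain weights `w` learn with `w <- w + alpha * x(t - 1) * z(t)`;
#' the collector-to-z and reward-to-z connections are fixed at 1.
#'
#' @param K Number of stimulus channels (ring neurons).
#' @param T_chain Number of delay slots per channel. Default 10, which at
#'   1 s/step covers the 7 s maximum reward delay of the shipped protocol.
#' @param alpha Learning rate (positive). Default 0.2.
#' @return An object of class `tdl_state` with fields `x`, `x_prev`
#'   (K x T chain activities), `w` (K x T weights), `alpha`, `reward`,
#'   `y`, `z`.
#' @export
tdl_state <- function(K, T_chain = 10L, alpha = 0.2) {
  stopifnot(is.numeric(K), K >= 1, K == as.integer(K),
            is.numeric(T_chain), T_chain >= 1, T_chain == as.integer(T_chain),
            is.numeric(alpha), alpha > 0)
  K <- as.integer(K); T_chain <- as.integer(T_chain)
  structure(
    list(x = matrix(0, K, T_chain), x_prev = matrix(0, K, T_chain),
         w = matrix(0, K, T_chain), alpha = alpha,
         reward = 0, y = 0, z = 0),
    class = "tdl_state"
  )
}

#' @export
print.tdl_state <- function(x, ...) {
  cat(sprintf("<tdl_state> K = %d, T = %d, alpha = %g, z = %g\n",
              nrow(x$x), ncol(x$x), x$alpha, x$z))
  invisible(x)
}

#' Shift the temporal chains one step
#'
#' Each chain slot takes the value its predecessor held last step; the
#' first slot takes the current ring activity; the oldest slot's content
#' drops off the end. The pre-shift chain is kept in `x_prev` for the
#' collector and the learning rule.
#'
#' @param state A [tdl_state()].
#' @param ring_activity Length-`K` vector of current ring activities.
#' @return The updated `tdl_state`.
#' @export
shift_chains <- function(state, ring_activity) {
  stopifnot(inherits(state, "tdl_state"))
  K <- nrow(state$x); Tc <- ncol(state$x)
  if (length(ring_activity) != K) {
    stop("`ring_activity` must have length K", call. = FALSE)
  }
  state$x_prev <- state$x
  if (Tc > 1L) state$x[, 2:Tc] <- state$x_prev[, 1:(Tc - 1L), drop = FALSE]
  state$x[, 1L] <- ring_activity
  state
}

#' Collector-neuron activity
#'
#' `y(t) = sum_ij w[i, j] * (x[i, j](t) - x[i, j](t - 1))`: the weighted
#' change in chain activity, i.e. the change in predicted value.
#'
#' @param state A [tdl_state()] whose chains have been shifted this step.
#' @return The collector activity `y` (scalar).
#' @export
collector <- function(state) {
  stopifnot(inherits(state, "tdl_state"))
  sum(state$w * (state$x - state$x_prev))
}

#' Dopaminergic-unit activity
#'
#' `z(t) = reward(t) + y(t)`, the reward-prediction error. It is not
#' clipped: omission of an expected reward must be able to drive `z`
#' negative so that the learning rule can weaken the prediction.
#'
#' @param state A [tdl_state()] with current `reward` and `y`.
#' @return The dopaminergic activity `z` (scalar).
#' @export
dopamine <- function(state) {
  stopifnot(inherits(state, "tdl_state"))
  state$reward + state$y
}

#' TD learning step on the chain weights
#'
#' `w[i, j] <- w[i, j] + alpha * x_prev[i, j] * z`. Only chain weights
#' learn; the unit connections from the collector and the reward neuron to
#' `z` are fixed.
#'
#' @param state A [tdl_state()] with `z` computed for the current step.
#' @return The updated `tdl_state`.
#' @export
tdl_learn <- function(state) {
  stopifnot(inherits(state, "tdl_state"))
  state$w <- state$w + state$alpha * state$x_prev * state$z
  state
}

#' Advance the TD circuit one step
#'
#' Composes shift -> collector -> dopamine -> (optionally) learn for one
#' step of ring input and reward.
#'
#' @param state A [tdl_state()].
#' @param ring_activity Length-`K` vector of current ring activities.
#' @param reward Reward-neuron activity this step (0 or 1 in the shipped
#'   protocols).
#' @param learn Logical: apply the TD weight update?
#' @return The updated `tdl_state` (with fields `y`, `z`, `reward` set for
#'   this step).
#' @export
tdl_step <- function(state, ring_activity, reward = 0, learn = TRUE) {
  state <- shift_chains(state, ring_activity)
  state$reward <- reward
  state$y <- collector(state)
  state$z <- dopamine(state)
  if (learn) state <- tdl_learn(state)
  state
}

#' Run one conditioning trial through the TD circuit
#'
#' A trial presents stimulus `stimulus_index` as a one-step unit pulse into
#' its chain at trial step 1 and, if `rewarded`, a one-step unit reward
#' `delay` steps after onset. The trial window is long enough
#' (`delay + T + 1` steps) for the pulse to traverse the whole chain and
#' drop off, so consecutive trials start from empty chains.
#'
#' @param state A [tdl_state()].
#' @param stimulus_index Channel receiving the pulse, or `NA` for a blank
#'   trial (no stimulus).
#' @param delay Reward delay in steps; must be smaller than the chain
#'   length `T`.
#' @param rewarded Logical.
#' @param learn Logical: apply TD updates during the trial?
#' @return List with elements `state` (final `tdl_state`) and `z_trace`
#'   (per-step dopaminergic activity; entry 1 is stimulus onset, entry
#'   `1 + delay` is the reward time).
#' @export
tdl_trial <- function(state, stimulus_index, delay, rewarded = TRUE,
                      learn = TRUE) {
  stopifnot(inherits(state, "tdl_state"))
  Tc <- ncol(state$x)
  if (delay >= Tc) stop("`delay` must be smaller than the chain length",
                        call. = FALSE)
  K <- nrow(state$x)
  n_steps <- delay + Tc + 1L
  z_trace <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    ring_activity <- numeric(K)
    if (t == 1L && !is.na(stimulus_index)) ring_activity[stimulus_index] <- 1
    reward <- if (rewarded && t == 1L + delay) 1 else 0
    state <- tdl_step(state, ring_activity, reward, learn)
    z_trace[t] <- state$z
  }
  list(state = state, z_trace = z_trace)
}
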