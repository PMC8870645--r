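#' Construct a recurrent Ring
#'
#' The Ring is a fully connected recurrent layer of `K` stimulus-selective
#' rate neurons. Its connectivity matrix `S` carries a fixed self-connection
#' `lam` on the diagonal — an active neuron left alone decays geometrically,
#' `r(t + tau) = lam^tau`, which keeps it firing a few seconds after its
#' stimulus disappears — while the off-diagonal entries are learned with the
#' reduced STDP rule and encode temporal succession between stimuli. Raw
#' weights are stored unclipped; the dynamics read them through [kappa()].
#'
#' @param K Number of neurons (positive integer).
#' @param lam Shared diagonal self-connection, in `[0, 1)`. Default 0.8 so
#'   that residual activity survives the 2-3 step delays used in the
#'   shipped protocols.
#' @return An object of class `ring_state` with fields `S` (K x K raw
#'   weights), `lam`, `r_now` and `r_prev` (activity vectors, all zero).
#' @export
ring_state <- function(K, lam = 0.8) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 1, K == as.integer(K),
            is.numeric(lam), length(lam) == 1L, lam >= 0, lam < 1)
  K <- as.integer(K)
  S <- matrix(0, K, K)
  diag(S) <- lam
  structure(
    list(S = S, lam = lam, r_now = numeric(K), r_prev = numeric(K)),
    class = "ring_state"
  )
}

#' @export
print.ring_state <- function(x, ...) {
  cat(sprintf("<ring_state> K = %d, lambda = %g\n", nrow(x$S), x$lam))
  cat("  r_now: ", paste(signif(x$r_now, 3), collapse = " "), "\n")
  invisible(x)
}

#' Advance the Ring one step
#'
#' Ring dynamics: `r(t+1) = sigma_l(kappa(S) r(t) + input_drive)`. The
#' previous activity vector is retained in `r_prev` for the STDP update;
#' weights are untouched.
#'
#' @param state A [ring_state()].
#' @param input_drive External drive vector of length `K`, entries in
#'   `[0, 1]` (typically the binary recognition vector of the perception
#'   layer). Defaults to no drive.
#' @param l Firing threshold of the activation, see [sigma_l()].
#' @return The updated `ring_state`.
#' @export
ring_step <- function(state, input_drive = numeric(nrow(state$S)), l = 0.1) {
  stopifnot(inherits(state, "ring_state"))
  K <- nrow(state$S)
  if (length(input_drive) != K) {
    stop("`input_drive` must have length K", call. = FALSE)
  }
  r_new <- sigma_l(as.numeric(kappa(state$S) %*% state$r_now) + input_drive, l)
  state$r_prev <- state$r_now
  state$r_now <- r_new
  state
}

#' Apply STDP learning to the Ring's cross-connections
#'
#' Updates every off-diagonal entry `S[j, i]` with the reduced STDP rule,
#' taking neuron `j` as postsynaptic and neuron `i` as presynaptic:
#' `dS[j, i] = (dt/tau_w) * (h1 r_j(t) r_i(t-1) + h2 r_j(t-1) r_i(t))`.
#' The diagonal self-connections are never modified. Raw weights may leave
#' `[0, 1]`; clipping happens only at read time in [ring_step()].
#'
#' @param state A [ring_state()] whose `r_prev` holds the previous step's
#'   activities.
#' @param p An [stdp_params()] bundle.
#' @param dt Step size (positive).
#' @return The updated `ring_state`.
#' @export
ring_learn <- function(state, p = stdp_params(), dt = 1) {
  stopifnot(inherits(state, "ring_state"), inherits(p, "stdp_params"))
  dS <- (dt / p$tau_w) * (
    p$h[1] * outer(state$r_now, state$r_prev) +
    p$h[2] * outer(state$r_prev, state$r_now)
  )
  diag(dS) <- 0
  state$S <- state$S + dS
  state
}

#' Precedence specification for a stimulus pair
#'
#' Declares that stimulus `j` follows stimulus `i` within a delay window of
#' `[T1, T2]` steps.
#'
#' @param i Index of the predecessor neuron.
#' @param j Index of the successor neuron (different from `i`).
#' @param T1,T2 Integer delay window bounds, `1 <= T1 <= T2`.
#' @return An object of class `precedence_spec`.
#' @export
precedence_spec <- function(i, j, T1 = 1L, T2 = T1) {
  stopifnot(is.numeric(i), is.numeric(j), i != j,
            is.numeric(T1), is.numeric(T2),
            T1 >= 1, T2 >= T1, T1 == as.integer(T1), T2 == as.integer(T2))
  structure(list(i = as.integer(i), j = as.integer(j),
                 T1 = as.integer(T1), T2 = as.integer(T2)),
            class = "precedence_spec")
}

#' Present a stimulus pair to the Ring
#'
#' One training presentation of the temporal succession `i` then `j`,
#' treated as an isolated trial from rest: the ring's activities are reset
#' to quiescence, neuron `i` receives a one-step unit drive, the ring
#' advances freely for the drawn delay, then neuron `j` receives a
#' one-step unit drive, with the STDP update applied after each of these
#' steps. Learning is confined to the driven window; the residual decay
#' after a presentation does not update weights, so a learned forward
#' association cannot potentiate itself by replay during the inter-trial
#' lull (which would otherwise defeat the depression balance of
#' `h = c(1, -1)` under mixed-order training).
#'
#' @param state A [ring_state()].
#' @param spec A [precedence_spec()]. When `T1 < T2` the delay is drawn
#'   uniformly from `[T1, T2]` using the session RNG; with `T1 == T2` the
#'   presentation is fully deterministic.
#' @param p An [stdp_params()] bundle.
#' @param l Firing threshold.
#' @param dt Step size.
#' @return The updated `ring_state`.
#' @export
present_pair <- function(state, spec, p = stdp_params(), l = 0.1, dt = 1) {
  stopifnot(inherits(state, "ring_state"), inherits(spec, "precedence_spec"))
  K <- nrow(state$S)
  if (spec$i > K || spec$j > K) stop("spec indices exceed K", call. = FALSE)
  delay <- if (spec$T1 == spec$T2) spec$T1 else
    sample(seq(spec$T1, spec$T2), 1L)
  state$r_now <- numeric(K)
  state$r_prev <- numeric(K)
  drive <- function(idx) {
    d <- numeric(K)
    if (!is.na(idx)) d[idx] <- 1
    d
  }
  advance <- function(state, idx) {
    state <- ring_step(state, drive(idx), l)
    ring_learn(state, p, dt)
  }
  state <- advance(state, spec$i)
  for (s in seq_len(delay - 1L)) state <- advance(state, NA)
  advance(state, spec$j)
}

#' Probe the Ring for a learned succession
#'
#' With learning frozen, drives neuron `i` with a one-step unit input from
#' a quiescent copy of the ring and returns the successor activities one
#' step later. Used to test whether `i`'s activation alone recalls its
#' learned successor. The caller's state is not modified.
#'
#' @param state A [ring_state()].
#' @param i Index of the driven neuron.
#' @param l Firing threshold.
#' @return Numeric vector: ring activity one step after `i` was driven.
#' @export
ring_probe <- function(state, i, l = 0.1) {
  stopifnot(inherits(state, "ring_state"))
  K <- nrow(state$S)
  probe <- state
  probe$r_now <- numeric(K)
  probe$r_prev <- numeric(K)
  d <- numeric(K)
  d[i] <- 1
  probe <- ring_step(probe, d, l)
  probe <- ring_step(probe, numeric(K), l)
  probe$r_now
}
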