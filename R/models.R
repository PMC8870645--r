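#' Assemble Ring Model A
#'
#' Model A couples an Oja-trained perception layer to the Ring and predicts
#' reward with a single readout neuron `z`: `z` is connected to every ring
#' neuron through STDP-learned weights `wz` and to itself with the fixed
#' recurrent weight `lam` (the same self-decay as the ring neurons). A
#' presented reward clamps `z = 1`, and the reduced STDP rule (with `h =
#' c(1, 0)` by default, potentiation only) then strengthens `wz` for ring
#' neurons that were active on the previous step. Because the reward link
#' only potentiates, a learned reward association cannot be unlearned by
#' reward omission — the behavioural contrast that motivates Model B.
#'
#' @param K Number of stimulus classes.
#' @param ell Feature dimension of the perception layer.
#' @param lam Ring self-connection.
#' @param ring_h Sign vector of the ring's STDP rule. The default
#'   `c(1, -1)` learns strictly forward successions (depression cancels
#'   reverse-order associations), which keeps learned pairs from becoming
#'   self-sustaining attractors.
#' @param reward_h Sign vector of the reward-link STDP rule; default
#'   `c(1, 0)` (potentiation only).
#' @param tau_w STDP weight time constant.
#' @return An object of class `model_a` with fields `layer`, `ring`, `wz`,
#'   `z`, `z_prev`, `ring_p`, `reward_p`, `l`.
#' @export
model_a <- function(K, ell = 64L, lam = 0.8, ring_h = c(1, -1),
                    reward_h = c(1, 0), tau_w = 1) {
  structure(
    list(
      layer = hebbian_layer(K, ell, rule = "oja"),
      ring = ring_state(K, lam),
      wz = numeric(K),
      z = 0, z_prev = 0,
      ring_p = stdp_params(h = ring_h, tau_w = tau_w),
      reward_p = stdp_params(h = reward_h, tau_w = tau_w),
      l = 0.1
    ),
    class = "model_a"
  )
}

#' Assemble Ring Model B
#'
#' Model B couples a BCM-trained perception layer to the Ring and replaces
#' Model A's single reward neuron with the temporal-difference circuit:
#' every ring neuron feeds a tapped delay line whose first slot mirrors
#' its activity, and the dopaminergic unit `z` reports the
#' reward-prediction error. TD learning both builds reward predictions and
#' dismantles them when the reward stops arriving.
#'
#' @param K Number of stimulus classes.
#' @param ell Feature dimension of the perception layer.
#' @param lam Ring self-connection.
#' @param ring_h Sign vector of the ring's STDP rule (see [model_a()]).
#' @param tau_w STDP weight time constant.
#' @param T_chain Delay-line length per stimulus.
#' @param alpha TD learning rate.
#' @return An object of class `model_b` with fields `layer`, `ring`,
#'   `tdl`, `ring_p`, `l`.
#' @export
model_b <- function(K, ell = 64L, lam = 0.8, ring_h = c(1, -1), tau_w = 1,
                    T_chain = 10L, alpha = 0.2) {
  structure(
    list(
      layer = hebbian_layer(K, ell, rule = "bcm"),
      ring = ring_state(K, lam),
      tdl = tdl_state(K, T_chain, alpha),
      ring_p = stdp_params(h = ring_h, tau_w = tau_w),
      l = 0.1
    ),
    class = "model_b"
  )
}

#' @export
print.model_a <- function(x, ...) {
  cat(sprintf("<model_a> K = %d, z = %g, |wz| = %g\n",
              nrow(x$ring$S), x$z, sqrt(sum(x$wz^2))))
  invisible(x)
}

#' @export
print.model_b <- function(x, ...) {
  cat(sprintf("<model_b> K = %d, T = %d, z = %g\n",
              nrow(x$ring$S), ncol(x$tdl$x), x$tdl$z))
  invisible(x)
}

#' Advance Ring Model A one step
#'
#' Pipeline: recognize the frame, drive the ring with the binary
#' recognition vector, then update the reward neuron
#' `z <- sigma_l(lam * z + wz . r + reward)`; a presented reward clamps
#' `z = 1`. With learning on, the ring's cross-connections and the reward
#' link `wz` both receive their reduced-STDP updates (for `wz`: post = z,
#' pre = ring activity).
#'
#' @param model A [model_a()].
#' @param frame Feature vector of length `ell`.
#' @param reward_on Logical: is a reward presented this step?
#' @param learning_on Logical: apply plasticity this step?
#' @param dt Step size.
#' @return The updated `model_a` (fields `v` and `z` reflect this step).
#' @export
model_a_step <- function(model, frame, reward_on = FALSE, learning_on = TRUE,
                         dt = 1) {
  stopifnot(inherits(model, "model_a"))
  v <- recognize(model$layer, frame)
  model$ring <- ring_step(model$ring, v, model$l)
  z_new <- if (reward_on) 1 else
    sigma_l(model$ring$lam * model$z + sum(model$wz * model$ring$r_now),
            model$l)
  model$z_prev <- model$z
  model$z <- z_new
  if (learning_on) {
    model$ring <- ring_learn(model$ring, model$ring_p, dt)
    model$wz <- stdp_reduced_update(
      model$wz,
      v_t = model$z, v_prev = model$z_prev,
      u_t = model$ring$r_now, u_prev = model$ring$r_prev,
      p = model$reward_p, dt = dt
    )
  }
  model$v <- v
  model
}

#' Advance Ring Model B one step
#'
#' Pipeline: recognize the frame, drive the ring, shift the TD chains with
#' the new ring activity, compute the collector and dopaminergic
#' activities, and (with learning on) apply the ring STDP and TD weight
#' updates.
#'
#' @param model A [model_b()].
#' @param frame Feature vector of length `ell`.
#' @param reward_on Logical: is a reward presented this step?
#' @param learning_on Logical: apply plasticity this step?
#' @param dt Step size.
#' @return The updated `model_b` (fields `v` and `z` reflect this step).
#' @export
model_b_step <- function(model, frame, reward_on = FALSE, learning_on = TRUE,
                         dt = 1) {
  stopifnot(inherits(model, "model_b"))
  v <- recognize(model$layer, frame)
  model$ring <- ring_step(model$ring, v, model$l)
  model$tdl <- tdl_step(model$tdl, model$ring$r_now,
                        reward = as.numeric(reward_on),
                        learn = learning_on)
  if (learning_on) {
    model$ring <- ring_learn(model$ring, model$ring_p, dt)
  }
  model$v <- v
  model$z <- model$tdl$z
  model
}

#' Run a single stimulus trial against a model
#'
#' Presents one stimulus for `dur` steps (noise-free prototype frames,
#' unless a noisy `frame_fun` is supplied), optionally delivering one-step
#' unit reward pulses at the given delays after onset, then lets the model
#' run on background frames until residual ring activity and chain content
#' have drained. Useful for conditioning, extinction and probe trials
#' outside the full protocol engine.
#'
#' @param model A `model_a` or `model_b`.
#' @param proto A `stimulus_prototype` to present.
#' @param dur Presentation length in steps.
#' @param reward_delays Integer vector of reward pulse times (steps after
#'   onset), or `integer(0)` for an unrewarded trial.
#' @param learning_on Logical; `FALSE` turns the trial into a frozen probe.
#' @param tail_steps Background steps appended after stimulus offset.
#' @param dt Step size.
#' @return List with elements `model` (updated) and `z_trace` (per-step
#'   reward-prediction signal; entry 1 is stimulus onset).
#' @export
run_trial <- function(model, proto, dur = 10L, reward_delays = integer(0),
                      learning_on = TRUE, tail_steps = 31L, dt = 1) {
  stopifnot(inherits(proto, "stimulus_prototype"))
  ell <- length(proto$mu)
  n_steps <- dur + tail_steps
  z_trace <- numeric(n_steps)
  for (t in seq_len(n_steps) - 1L) {
    frame <- if (t < dur) observe(proto) else
      observe(NULL, ell = ell, sigma_noise = proto$sigma_noise)
    reward_on <- t %in% reward_delays
    model <- if (inherits(model, "model_a")) {
      model_a_step(model, frame, reward_on, learning_on, dt)
    } else {
      model_b_step(model, frame, reward_on, learning_on, dt)
    }
    z_trace[t + 1L] <- model_z(model)
  }
  list(model = model, z_trace = z_trace)
}

#' Train a model's perception layer by naming
#'
#' Applies `reps` supervised naming steps per class with noise-free
#' prototype frames, and calibrates the Oja readout threshold afterwards.
#'
#' @param model A `model_a` or `model_b`.
#' @param protos List of `stimulus_prototype` objects, one per class.
#' @param reps Naming repetitions per class.
#' @param dt Step size.
#' @return The model with a trained perception layer.
#' @export
teach_names <- function(model, protos, reps = 5L, dt = 1) {
  for (s in seq_along(protos)) {
    for (k in seq_len(reps)) {
      model$layer <- learn_label(model$layer, protos[[s]]$mu, s, dt)
    }
  }
  if (model$layer$rule == "oja") {
    model$layer <- calibrate_theta_H(model$layer, protos)
  }
  model
}

#' Read the model's reward-prediction signal
#'
#' @param model A `model_a` or `model_b`.
#' @return The current dopaminergic/reward-neuron activity `z`.
#' @export
model_z <- function(model) {
  if (inherits(model, "model_a")) model$z else model$tdl$z
}

#' Serialize a model state to a JSON checkpoint
#'
#' Captures every matrix, threshold and scalar needed to resume a run.
#'
#' @param model A `model_a` or `model_b`.
#' @param path Optional file path; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
model_to_json <- function(model, path = NULL) {
  kind <- if (inherits(model, "model_a")) "A" else "B"
  payload <- list(kind = kind, l = model$l,
                  ring = list(S = model$ring$S, lam = model$ring$lam,
                              r_now = model$ring$r_now,
                              r_prev = model$ring$r_prev),
                  layer = list(H = model$layer$H, rule = model$layer$rule,
                               theta = model$layer$theta,
                               theta_H = model$layer$theta_H),
                  ring_h = model$ring_p$h, tau_w = model$ring_p$tau_w)
  if (kind == "A") {
    payload$wz <- model$wz
    payload$z <- model$z
    payload$z_prev <- model$z_prev
    payload$reward_h <- model$reward_p$h
  } else {
    payload$tdl <- list(x = model$tdl$x, x_prev = model$tdl$x_prev,
                        w = model$tdl$w, alpha = model$tdl$alpha,
                        reward = model$tdl$reward, y = model$tdl$y,
                        z = model$tdl$z)
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           matrix = "rowmajor", na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Restore a model state from a JSON checkpoint
#'
#' @param json JSON string or path produced by [model_to_json()].
#' @return A `model_a` or `model_b` object.
#' @export
model_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  K <- length(p$ring$r_now)
  ell <- ncol(p$layer$H)
  restore_ring <- function(m) {
    m$ring$S[] <- as.matrix(p$ring$S)
    m$ring$r_now <- as.numeric(p$ring$r_now)
    m$ring$r_prev <- as.numeric(p$ring$r_prev)
    m$layer$H[] <- p$layer$H
    m$layer$theta <- as.numeric(p$layer$theta)
    m$layer$theta_H <- if (is.null(p$layer$theta_H)) NA_real_ else
      as.numeric(p$layer$theta_H)
    m$l <- p$l
    m
  }
  if (p$kind == "A") {
    m <- model_a(K, ell, lam = p$ring$lam, ring_h = p$ring_h,
                 reward_h = p$reward_h, tau_w = p$tau_w)
    m <- restore_ring(m)
    m$wz <- as.numeric(p$wz)
    m$z <- p$z
    m$z_prev <- p$z_prev
  } else {
    m <- model_b(K, ell, lam = p$ring$lam, ring_h = p$ring_h,
                 tau_w = p$tau_w, T_chain = ncol(p$tdl$x),
                 alpha = p$tdl$alpha)
    m <- restore_ring(m)
    m$tdl$x[] <- p$tdl$x
    m$tdl$x_prev[] <- p$tdl$x_prev
    m$tdl$w[] <- p$tdl$w
    m$tdl$reward <- p$tdl$reward
    m$tdl$y <- p$tdl$y
    m$tdl$z <- p$tdl$z
  }
  m
}
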