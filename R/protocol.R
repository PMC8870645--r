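#' Stimulus letter labels
#'
#' Stimuli are labelled A, B, C, ... in index order (falling back to
#' `s<i>` beyond 26 classes).
#'
#' @param i Integer index vector.
#' @return Character vector of labels.
#' @export
stimulus_label <- function(i) {
  ifelse(i <= 26L, LETTERS[i], paste0("s", i))
}

new_events <- function(t_start = integer(0), t_end = integer(0),
                       kind = character(0), stimulus = integer(0)) {
  data.frame(t_start = as.integer(t_start), t_end = as.integer(t_end),
             kind = as.character(kind), stimulus = as.integer(stimulus),
             stringsAsFactors = FALSE)
}

#' Build the in-silico sensory-preconditioning protocol
#'
#' Expands an [experiment_config()] into a deterministic, time-sorted
#' event table with four stages:
#'
#' 1. *Naming*: every stimulus is shown with its name (a one-step label
#'    event at onset), `naming_reps` times.
#' 2. *Preconditioning*: the pairs in `pair_order` are presented in
#'    alternation, the second member immediately after the first
#'    (half-open intervals, zero gap), `precond_reps` trials per pair.
#' 3. *Conditioning*: the second member of the first pair is shown with
#'    one-step reward pulses at the configured delays after onset; the
#'    second member of the second pair is shown unrewarded; trials
#'    alternate, `conditioning_reps` per stimulus.
#' 4. *Probe*: the two pair *predecessors* are probed (unrewarded, marked
#'    with `probe_marker` so the runner freezes learning), followed by
#'    `reminder_reps` reminder presentations each of the conditioned
#'    stimulus (rewarded) and the control (unrewarded), also under probe
#'    markers.
#'
#' All trials are separated by the configured inter-trial gap. Event
#' generation uses no randomness: the table is a pure function of `cfg`.
#'
#' @param cfg An [experiment_config()].
#' @return A data.frame of events with columns `t_start`, `t_end` (steps,
#'   0-based, half-open), `kind` (`show`, `label`, `reward`,
#'   `probe_marker`) and `stimulus` (index, `NA` for markers without one).
#' @export
build_protocol <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  validate_config(cfg)
  dur <- as.integer(round(cfg$stimulus_duration_s / cfg$dt))
  gap <- as.integer(ceiling(cfg$inter_trial_gap_s / cfg$dt))
  ev <- new_events()
  t <- 0L
  add <- function(t_start, t_end, kind, stimulus = NA_integer_) {
    ev <<- rbind(ev, new_events(t_start, t_end, kind, stimulus))
  }

  # stage 1: naming
  for (s in seq_len(cfg$K)) {
    for (rep in seq_len(cfg$naming_reps)) {
      add(t, t + dur, "show", s)
      add(t, t + 1L, "label", s)
      t <- t + dur + gap
    }
  }

  # stage 2: preconditioning pairs, alternating
  for (rep in seq_len(cfg$precond_reps)) {
    for (pair in cfg$pair_order) {
      add(t, t + dur, "show", pair[1])
      add(t + dur, t + 2L * dur, "show", pair[2])
      t <- t + 2L * dur + gap
    }
  }

  # stage 3: conditioning (rewarded) and control (unrewarded), alternating
  conditioned <- cfg$pair_order[[1]][2]
  control <- cfg$pair_order[[2]][2]
  delays <- as.integer(round(cfg$reward_delays_s / cfg$dt))
  for (rep in seq_len(cfg$conditioning_reps)) {
    add(t, t + dur, "show", conditioned)
    for (d in delays) add(t + d, t + d + 1L, "reward", conditioned)
    t <- t + dur + gap
    add(t, t + dur, "show", control)
    t <- t + dur + gap
  }

  # stage 4: probes of the pair predecessors, then reminders
  for (pair in cfg$pair_order) {
    add(t, t + dur, "show", pair[1])
    add(t, t + dur, "probe_marker", pair[1])
    t <- t + dur + gap
  }
  for (rep in seq_len(cfg$reminder_reps)) {
    add(t, t + dur, "show", conditioned)
    add(t, t + dur, "probe_marker", conditioned)
    for (d in delays) add(t + d, t + d + 1L, "reward", conditioned)
    t <- t + dur + gap
    add(t, t + dur, "show", control)
    add(t, t + dur, "probe_marker", control)
    t <- t + dur + gap
  }

  ev <- ev[order(ev$t_start, ev$t_end), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "horizon") <- t
  attr(ev, "naming_end") <- if (cfg$naming_reps > 0)
    max(ev$t_end[ev$kind == "label"]) else 0L
  ev
}

#' Build a model from an experiment configuration
#'
#' @param cfg An [experiment_config()].
#' @param kind `"A"` (Oja perception, single STDP reward neuron) or `"B"`
#'   (BCM perception, temporal-difference circuit).
#' @return A `model_a` or `model_b` object.
#' @export
build_model <- function(cfg, kind = c("A", "B")) {
  kind <- match.arg(kind)
  if (kind == "A") {
    m <- model_a(cfg$K, cfg$ell, lam = cfg$lam, ring_h = cfg$h,
                 tau_w = cfg$tau_w)
    if (!is.na(cfg$theta_H)) m$layer$theta_H <- cfg$theta_H
  } else {
    m <- model_b(cfg$K, cfg$ell, lam = cfg$lam, ring_h = cfg$h,
                 tau_w = cfg$tau_w, T_chain = cfg$T_chain,
                 alpha = cfg$alpha)
  }
  m$l <- cfg$l
  m
}

#' Run a protocol against a model
#'
#' Advances the simulation clock step by step over the event table:
#' each step it synthesizes the observation frame (prototype plus noise,
#' or background noise when nothing is shown), applies any naming event to
#' the perception layer, and advances the model with the reward flag of
#' the step. Learning is frozen during probe-marker windows. For an Oja
#' model with uncalibrated `theta_H`, the ring receives no recognition
#' drive during the naming stage and the threshold is calibrated at half
#' the weakest trained prototype response once naming ends.
#'
#' The full run is reproducible: prototypes and the observation noise
#' stream are derived from `cfg$seed` alone.
#'
#' @param model A `model_a` or `model_b` (typically from [build_model()]).
#' @param events Event table from [build_protocol()], sorted by `t_start`.
#' @param cfg The [experiment_config()] used to build the events.
#' @param verbose Emit per-stage progress messages?
#' @return A long data.frame of trace records with columns `t`, `signal`,
#'   `value` (signals `v_*`, `r_*`, `z`, and `theta_*` for BCM). The final
#'   model and the event table are attached as attributes `model` and
#'   `events`.
#' @export
run_protocol <- function(model, events, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.unsorted(events$t_start)) {
    stop("`events` must be sorted by t_start", call. = FALSE)
  }
  horizon <- attr(events, "horizon")
  if (is.null(horizon)) horizon <- if (nrow(events)) max(events$t_end) else 0L
  naming_end <- attr(events, "naming_end")
  if (is.null(naming_end)) naming_end <- 0L

  protos <- make_prototypes(cfg$K, cfg$ell, cfg$sigma_noise, cfg$seed)
  is_oja <- model$layer$rule == "oja"
  needs_calibration <- is_oja && is.na(model$layer$theta_H)
  if (needs_calibration) model$layer$theta_H <- Inf

  set.seed(cfg$seed + 1L)
  labels <- stimulus_label(seq_len(cfg$K))
  signals <- c(paste0("v_", labels), paste0("r_", labels), "z")
  if (!is_oja) signals <- c(signals, paste0("theta_", labels))
  values <- matrix(0, nrow = horizon, ncol = length(signals),
                   dimnames = list(NULL, signals))

  for (t in seq_len(horizon) - 1L) {
    if (needs_calibration && t >= naming_end) {
      model$layer <- calibrate_theta_H(model$layer, protos)
      needs_calibration <- FALSE
      if (verbose) {
        message(sprintf("[t=%d] calibrated theta_H = %g", t,
                        model$layer$theta_H))
      }
    }
    active <- events[events$t_start <= t & t < events$t_end, , drop = FALSE]
    shown <- active$stimulus[active$kind == "show"]
    frame <- if (length(shown)) observe(protos[[shown[1]]]) else
      observe(NULL, ell = cfg$ell, sigma_noise = cfg$sigma_noise)
    lab <- active$stimulus[active$kind == "label"]
    if (length(lab)) {
      model$layer <- learn_label(model$layer, frame, lab[1], cfg$dt)
      if (verbose) {
        message(sprintf("[t=%d] naming step for %s, |H| = %.3f", t,
                        stimulus_label(lab[1]), sqrt(sum(model$layer$H^2))))
      }
    }
    reward_on <- any(active$kind == "reward")
    learning_on <- !any(active$kind == "probe_marker")
    if (verbose && length(shown) &&
        any(active$t_start[active$kind == "show"] == t)) {
      stage <- if (length(lab) || t < naming_end) "naming" else
        if (!learning_on) "probe" else "trial"
      message(sprintf("[t=%d] %s: show %s, |S| = %.3f%s", t, stage,
                      stimulus_label(shown[1]), sqrt(sum(model$ring$S^2)),
                      if (reward_on) ", reward" else ""))
    }
    model <- if (inherits(model, "model_a")) {
      model_a_step(model, frame, reward_on, learning_on, cfg$dt)
    } else {
      model_b_step(model, frame, reward_on, learning_on, cfg$dt)
    }
    row <- c(model$v, model$ring$r_now, model_z(model))
    if (!is_oja) row <- c(row, model$layer$theta)
    values[t + 1L, ] <- row
  }

  traces <- data.frame(
    t = rep(seq_len(horizon) - 1L, times = length(signals)),
    signal = rep(signals, each = horizon),
    value = as.vector(values),
    stringsAsFactors = FALSE
  )
  attr(traces, "model") <- model
  attr(traces, "events") <- events
  traces
}

#' Summarize probe windows
#'
#' Extracts the peak reward-prediction signal `z` within every
#' probe-marker window, aggregates it per probed stimulus (maximum over
#' that stimulus's windows) and reports the two transitive-inference
#' contrasts: predecessor-of-conditioned minus predecessor-of-control, and
#' conditioned minus control.
#'
#' @param traces Trace table from [run_protocol()].
#' @param cfg The [experiment_config()] of the run.
#' @param events Event table; defaults to the one attached to `traces`.
#' @return A list with elements `windows` (per-window peak z), `peaks`
#'   (named per-stimulus peak z) and `contrasts` (named numeric vector).
#' @export
probe_summary <- function(traces, cfg, events = attr(traces, "events")) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(events)) stop("`events` are required", call. = FALSE)
  probes <- events[events$kind == "probe_marker", , drop = FALSE]
  if (nrow(probes) == 0) stop("traces contain no probe windows",
                              call. = FALSE)
  z <- traces[traces$signal == "z", , drop = FALSE]
  windows <- do.call(rbind, lapply(seq_len(nrow(probes)), function(k) {
    w <- probes[k, ]
    zw <- z$value[z$t >= w$t_start & z$t < w$t_end]
    data.frame(stimulus = stimulus_label(w$stimulus),
               t_start = w$t_start, t_end = w$t_end,
               peak_z = if (length(zw)) max(zw) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  peaks <- tapply(windows$peak_z, windows$stimulus, max)
  peaks <- stats::setNames(as.numeric(peaks), names(peaks))
  pred1 <- stimulus_label(cfg$pair_order[[1]][1])
  pred2 <- stimulus_label(cfg$pair_order[[2]][1])
  cond <- stimulus_label(cfg$pair_order[[1]][2])
  ctrl <- stimulus_label(cfg$pair_order[[2]][2])
  getz <- function(s) if (s %in% names(peaks)) peaks[[s]] else 0
  contrasts <- c(getz(pred1) - getz(pred2), getz(cond) - getz(ctrl))
  names(contrasts) <- c(paste0("z(", pred1, ")-z(", pred2, ")"),
                        paste0("z(", cond, ")-z(", ctrl, ")"))
  list(windows = windows, peaks = peaks, contrasts = contrasts)
}

#' Write traces, events and summaries to disk
#'
#' @param traces Trace table from [run_protocol()].
#' @param traces_path CSV output path (`t,signal,value` header).
#' @param events_path Optional JSON Lines path (one event per line).
#' @param summary_path Optional JSON path for the [probe_summary()].
#' @param cfg Required when `summary_path` is given.
#' @return `traces_path`, invisibly.
#' @export
write_traces <- function(traces, traces_path, events_path = NULL,
                         summary_path = NULL, cfg = NULL) {
  utils::write.csv(traces[, c("t", "signal", "value")], traces_path,
                   row.names = FALSE, quote = FALSE)
  events <- attr(traces, "events")
  if (!is.null(events_path) && !is.null(events)) {
    lines <- vapply(seq_len(nrow(events)), function(k) {
      jsonlite::toJSON(as.list(events[k, ]), auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(lines, events_path)
  }
  if (!is.null(summary_path)) {
    stopifnot(!is.null(cfg))
    s <- probe_summary(traces, cfg, events)
    jsonlite::write_json(
      list(peaks = as.list(s$peaks), contrasts = as.list(s$contrasts)),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(traces_path)
}

#' Run the full experiment end to end
#'
#' Convenience wrapper: build the protocol, build the model, run it, and
#' summarize the probes.
#'
#' @param cfg An [experiment_config()].
#' @param kind Model kind, `"A"` or `"B"`.
#' @param verbose Emit progress messages?
#' @return A list with elements `traces`, `summary`, `model`, `events`.
#' @export
run_experiment <- function(cfg = experiment_config(), kind = c("A", "B"),
                           verbose = FALSE) {
  kind <- match.arg(kind)
  events <- build_protocol(cfg)
  model <- build_model(cfg, kind)
  traces <- run_protocol(model, events, cfg, verbose = verbose)
  list(traces = traces,
       summary = probe_summary(traces, cfg, events),
       model = attr(traces, "model"),
       events = events)
}
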