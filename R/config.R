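#' Experiment configuration
#'
#' Bundles every tunable of the in-silico sensory-preconditioning
#' experiment. Defaults reproduce the shipped study conditions: four
#' stimuli named A-D, 10 s presentations, inter-trial gaps of 31 s
#' (fixed, to keep runs deterministic), seven preconditioning repetitions
#' per pair, nine conditioning trials with reward pulses 1, 4 and 7 s
#' after onset of the conditioned stimulus, and three reminder trials per
#' conditioned/control stimulus around the probe tests.
#'
#' @param K Number of stimulus classes.
#' @param ell Feature dimension of the perception front end.
#' @param sigma_noise Observation noise s.d.
#' @param lam Ring self-connection, in `[0, 1)`.
#' @param l Firing threshold of the clipped activation.
#' @param theta_H Oja readout threshold; `NA` means calibrate automatically
#'   after the naming stage.
#' @param h Length-2 sign vector of the ring's STDP rule.
#' @param tau_w STDP weight time constant.
#' @param alpha TD learning rate.
#' @param T_chain Delay-line length per stimulus.
#' @param dt Seconds of protocol time per simulation step.
#' @param seed Integer seed for prototype construction and observation
#'   noise.
#' @param naming_reps Supervised naming repetitions per class (stage 1).
#' @param precond_reps Preconditioning trials per pair (6 or 7).
#' @param pair_order List of length-2 integer vectors: the stimulus pairs
#'   presented in succession during preconditioning. The second member of
#'   the first pair is conditioned with reward; the second member of the
#'   second pair is the unrewarded control.
#' @param stimulus_duration_s Stimulus presentation length in seconds.
#' @param inter_trial_gap_s Gap between trials in seconds (> 30).
#' @param conditioning_reps Conditioning trials per stimulus (3 to 9).
#' @param reward_delays_s Reward pulse times (seconds after onset of the
#'   conditioned stimulus); subset of `{1, 4, 7}`.
#' @param reminder_reps Reminder trials per stimulus in the probe stage.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(K = 4L, ell = 64L, sigma_noise = 0.05,
                              lam = 0.8, l = 0.1, theta_H = NA_real_,
                              h = c(1, -1), tau_w = 1, alpha = 0.2,
                              T_chain = 10L, dt = 1, seed = 1L,
                              naming_reps = 5L, precond_reps = 7L,
                              pair_order = list(c(1L, 2L), c(3L, 4L)),
                              stimulus_duration_s = 10,
                              inter_trial_gap_s = 31,
                              conditioning_reps = 9L,
                              reward_delays_s = c(1, 4, 7),
                              reminder_reps = 3L) {
  cfg <- structure(
    list(K = as.integer(K), ell = as.integer(ell),
         sigma_noise = sigma_noise, lam = lam, l = l, theta_H = theta_H,
         h = as.numeric(h), tau_w = tau_w, alpha = alpha,
         T_chain = as.integer(T_chain), dt = dt, seed = as.integer(seed),
         naming_reps = as.integer(naming_reps),
         precond_reps = as.integer(precond_reps),
         pair_order = lapply(pair_order, as.integer),
         stimulus_duration_s = stimulus_duration_s,
         inter_trial_gap_s = inter_trial_gap_s,
         conditioning_reps = as.integer(conditioning_reps),
         reward_delays_s = as.numeric(reward_delays_s),
         reminder_reps = as.integer(reminder_reps)),
    class = "experiment_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(K >= 1, ell >= 2, sigma_noise >= 0,
              lam >= 0, lam < 1, l >= 0, l < 1,
              length(h) == 2L, all(h %in% c(-1, 0, 1)),
              tau_w > 0, alpha > 0, T_chain >= 2, dt > 0,
              naming_reps >= 1)
    if (!(precond_reps %in% 6:7)) {
      stop("`precond_reps` must be 6 or 7", call. = FALSE)
    }
    if (!(conditioning_reps %in% 3:9)) {
      stop("`conditioning_reps` must be between 3 and 9", call. = FALSE)
    }
    if (inter_trial_gap_s <= 30) {
      stop("`inter_trial_gap_s` must exceed 30 s", call. = FALSE)
    }
    if (!all(reward_delays_s %in% c(1, 4, 7))) {
      stop("`reward_delays_s` must be a subset of {1, 4, 7}", call. = FALSE)
    }
    if (max(reward_delays_s) / dt >= T_chain) {
      stop("delay line too short for the largest reward delay", call. = FALSE)
    }
    idx <- unlist(pair_order)
    if (anyDuplicated(idx) || any(idx < 1) || any(idx > K) ||
        !all(lengths(pair_order) == 2L)) {
      stop("`pair_order` must list disjoint in-range stimulus pairs",
           call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> K = %d, dt = %g s/step, seed = %d\n", x$K, x$dt,
    x$seed))
  cat(sprintf("  naming %d reps | precond %d | conditioning %d | reminders %d\n",
              x$naming_reps, x$precond_reps, x$conditioning_reps,
              x$reminder_reps))
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' Keys mirror the arguments of [experiment_config()] field-for-field;
#' missing keys take the defaults and unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(experiment_config, raw)
}

#' Write an experiment configuration to YAML
#'
#' @param cfg An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
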