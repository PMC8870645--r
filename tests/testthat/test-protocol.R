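test_that("experiment_config validates its study-condition invariants", {
  cfg <- experiment_config()
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$stimulus_duration_s, 10)
  expect_error(experiment_config(precond_reps = 5), "precond")
  expect_error(experiment_config(conditioning_reps = 10), "conditioning")
  expect_error(experiment_config(inter_trial_gap_s = 30), "30")
  expect_error(experiment_config(reward_delays_s = c(2)), "delays")
  expect_error(experiment_config(pair_order = list(c(1, 2), c(2, 3))), "pair")
  expect_error(experiment_config(T_chain = 5, reward_delays_s = 7), "delay line")
})

test_that("YAML configs round-trip and unknown keys are rejected", {
  cfg <- experiment_config(seed = 3, precond_reps = 6)
  tmp <- tempfile(fileext = ".yaml")
  write_experiment_config(cfg, tmp)
  back <- read_experiment_config(tmp)
  expect_equal(back$seed, 3L)
  expect_equal(back$precond_reps, 6L)
  expect_equal(back$pair_order, cfg$pair_order)
  writeLines(c("K: 4", "bogus_knob: 1"), tmp)
  expect_error(read_experiment_config(tmp), "bogus_knob")
})

test_that("build_protocol lays out the four stages deterministically", {
  cfg <- experiment_config(precond_reps = 6)
  ev <- build_protocol(cfg)
  expect_identical(ev, build_protocol(cfg))   # pure function of cfg
  # four distinct stimuli are named in stage 1
  labels <- ev[ev$kind == "label", ]
  expect_equal(sort(unique(labels$stimulus)), 1:4)
  # 6 repetitions per pair = 12 pair trials in stage 2
  naming_end <- attr(ev, "naming_end")
  shows <- ev[ev$kind == "show" & ev$t_start >= naming_end, ]
  first_members <- shows[shows$stimulus %in% c(1, 3), ]
  stage2_starts <- head(sort(first_members$t_start), 12)
  expect_equal(length(stage2_starts), 12)
  # paired stimuli follow their predecessors with zero gap
  pair_trials <- shows[shows$t_start %in% stage2_starts, ]
  for (k in seq_len(nrow(pair_trials))) {
    succ <- shows[shows$t_start == pair_trials$t_end[k], ]
    expect_equal(nrow(succ), 1)
    expect_equal(succ$stimulus, pair_trials$stimulus[k] + 1L)
  }
  # rewards attach only to the conditioned stimulus at delays 1, 4, 7
  rewards <- ev[ev$kind == "reward", ]
  expect_true(all(rewards$stimulus == 2))
  onsets <- vapply(rewards$t_start, function(t) {
    s <- shows[shows$stimulus == 2 & shows$t_start <= t & t < shows$t_end, ]
    t - s$t_start[1]
  }, numeric(1))
  expect_true(all(onsets %in% c(1, 4, 7)))
  # probe windows exist for all four stimuli
  probes <- ev[ev$kind == "probe_marker", ]
  expect_equal(sort(unique(probes$stimulus)), 1:4)
})

test_that("consecutive trials are separated by more than 30 seconds", {
  cfg <- experiment_config()
  ev <- build_protocol(cfg)
  shows <- ev[ev$kind == "show", ]
  shows <- shows[order(shows$t_start), ]
  gaps <- shows$t_start[-1] - shows$t_end[-nrow(shows)]
  # zero-gap transitions are the within-trial pair successions; all other
  # separations must exceed the 30 s floor
  expect_true(all(gaps[gaps != 0] > 30 / cfg$dt))
})

test_that("an empty protocol yields all-zero traces", {
  cfg <- experiment_config()
  ev <- build_protocol(cfg)[0, ]
  attr(ev, "horizon") <- 50L
  for (kind in c("A", "B")) {
    m <- build_model(cfg, kind)
    tr <- run_protocol(m, ev, cfg)
    expect_equal(unique(tr$value), 0)
    expect_equal(nrow(tr[tr$signal == "z", ]), 50)
  }
})

test_that("traces are complete and runs are bit-reproducible", {
  cfg <- experiment_config(naming_reps = 1, precond_reps = 6,
                           conditioning_reps = 3, reminder_reps = 1)
  res1 <- run_experiment(cfg, "B")
  res2 <- run_experiment(cfg, "B")
  expect_identical(res1$traces, res2$traces)
  horizon <- attr(res1$events, "horizon")
  # every declared signal has a record at every step
  counts <- table(res1$traces$signal)
  expect_true(all(counts == horizon))
  expect_true(all(res1$traces$t >= 0 & res1$traces$t < horizon))
  # a different seed changes the noise stream but not the trace layout
  res3 <- run_experiment(experiment_config(naming_reps = 1, precond_reps = 6,
                                           conditioning_reps = 3,
                                           reminder_reps = 1, seed = 2), "B")
  expect_equal(dim(res3$traces), dim(res1$traces))
})

test_that("probe summaries report per-stimulus peaks and contrasts", {
  cfg <- experiment_config(naming_reps = 1, precond_reps = 6,
                           conditioning_reps = 3, reminder_reps = 1)
  res <- run_experiment(cfg, "B")
  s <- res$summary
  expect_named(s$contrasts, c("z(A)-z(C)", "z(B)-z(D)"))
  expect_true(all(c("A", "B", "C", "D") %in% names(s$peaks)))
  expect_true(all(s$windows$peak_z[s$windows$stimulus == "C"] <=
                  s$peaks[["C"]]))
  # all-zero z traces give all-zero contrasts
  tr0 <- res$traces
  tr0$value[tr0$signal == "z"] <- 0
  s0 <- probe_summary(tr0, cfg, res$events)
  expect_equal(unname(s0$contrasts), c(0, 0))
  expect_error(probe_summary(res$traces, cfg, res$events[0, ]), "probe")
})

test_that("trace and event files are written in the documented formats", {
  cfg <- experiment_config(naming_reps = 1, precond_reps = 6,
                           conditioning_reps = 3, reminder_reps = 1)
  res <- run_experiment(cfg, "A")
  tdir <- tempfile(); dir.create(tdir)
  tr_path <- file.path(tdir, "traces.csv")
  ev_path <- file.path(tdir, "events.jsonl")
  sm_path <- file.path(tdir, "summary.json")
  write_traces(res$traces, tr_path, ev_path, sm_path, cfg)
  header <- readLines(tr_path, n = 1)
  expect_equal(header, "t,signal,value")
  back <- read.csv(tr_path)
  expect_equal(nrow(back), nrow(res$traces))
  ev_lines <- readLines(ev_path)
  expect_equal(length(ev_lines), nrow(res$events))
  first <- jsonlite::fromJSON(ev_lines[1])
  expect_true(all(c("t_start", "t_end", "kind") %in% names(first)))
  sm <- jsonlite::fromJSON(sm_path)
  expect_true(all(c("peaks", "contrasts") %in% names(sm)))
})
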