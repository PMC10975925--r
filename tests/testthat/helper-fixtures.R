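# Shared simulated sessions, built once per test run. Heavy fixtures are
# memoised so property tests and acceptance checks reuse the same objects.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

run_sim <- function(cfg) {
  sim <- simulate_session(cfg)
  res <- suppressWarnings(run_ipast_pipeline(sim$session))
  list(sim = sim, res = res,
       score = score_detection(res$saccades, res$blinks, sim$truth))
}

# 100 default-condition trials: detection recall/precision/timing (sigma =
# 0.05 deg position noise, slosh on, blinks in the ITI)
fx_detection <- function() fixture("detection", function() {
  run_sim(generator_config(n_trials = 100, seed = 11))
})

# 600 trials spanning 2-15 deg: main-sequence coverage and the paired PSO
# endpoint comparison (>= 500 matched saccades)
fx_msrange <- function() fixture("msrange", function() {
  run_sim(generator_config(n_trials = 600, seed = 13, amplitude_range = c(2, 15)))
})

# every ANTI trial carries an opposed error-then-correct pair
fx_boomerang <- function() fixture("boomerang", function() {
  run_sim(generator_config(n_trials = 60, seed = 5, boomerang_prob = 1))
})

# ordinary saccades only (slosh on): false-split control, >= 500 events
fx_ordinary <- function() fixture("ordinary", function() {
  run_sim(generator_config(n_trials = 320, seed = 7, amplitude_range = c(4, 12)))
})

# full behavioural mix for trial-classification agreement
fx_classify <- function() fixture("classify", function() {
  run_sim(generator_config(n_trials = 1000, seed = 42))
})

# quiet trials for pupillometry parameter recovery (>= 200 eligible)
fx_pupil <- function() fixture("pupil", function() {
  run_sim(generator_config(
    n_trials = 230, seed = 9, blink_rate_per_trial = 0,
    behavior_probs = c(correct = 0.9, direction_error = 0.1, anticipatory = 0,
                       fixation_break = 0, no_saccade = 0, random = 0,
                       never_fixated = 0, eye_loss = 0)
  ))
})

classification_agreement <- function(fx) {
  cls <- fx$res$classifications
  tr <- fx$sim$truth$trials
  mean(cls$category[order(cls$trial_id)] == tr$category[order(tr$trial_id)])
}
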