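# Hand-constructed degree-space sessions for targeted scenarios.

# One quiet 3200 ms trial at 500 Hz: fixation at (0, 0), pupil area 600.
make_quiet_trial <- function(trial_id = 1L, condition = "PRO",
                             stim_side = "right", noise = 0, seed = 1) {
  set.seed(seed)
  t_ms <- seq(-2200, 998, by = 2)
  n <- length(t_ms)
  tibble::tibble(
    trial_id = trial_id, t_ms = t_ms,
    x = rnorm(n, 0, noise), y = rnorm(n, 0, noise),
    a = rep(600, n), valid = TRUE
  )
}

make_trial_row <- function(trial_id = 1L, condition = "PRO",
                           stim_side = "right") {
  tibble::tibble(
    trial_id = trial_id, condition = condition, stim_side = stim_side,
    fix_on_ms = -1200, fix_off_ms = -200, stim_on_ms = 0, trial_end_ms = 998,
    drift_segment = 1L, not_marked = FALSE
  )
}

make_session <- function(samples, trials, units = "deg") {
  ipast_session(samples, trials, screen_geometry(), 500, units = units)
}

# A minimal saccade-table row with the columns classification relies on.
make_saccade_row <- function(trial_id = 1L, onset_ms, amplitude = 10,
                             angle = 0, start_x = 0, start_y = 0,
                             blincade = FALSE) {
  dx <- amplitude * cos(angle * pi / 180)
  dy <- amplitude * sin(angle * pi / 180)
  tibble::tibble(
    trial_id = trial_id, onset_ms = onset_ms, offset_ms = onset_ms + 60,
    duration_ms = 60, start_x = start_x, start_y = start_y,
    end_x = start_x + dx, end_y = start_y + dy,
    amplitude = amplitude, angle = angle, peak_velocity = 300,
    peak_acceleration = 1e4, blincade = blincade, boomerang_half = "none",
    pso_merged = FALSE, lapse_flag = FALSE
  )
}

fx_empty_saccades <- function() {
  make_saccade_row(onset_ms = 0)[0, ]
}

empty_blinks <- function() {
  tibble::tibble(trial_id = integer(), loss_start_ms = numeric(),
                 loss_end_ms = numeric(), blink_start_ms = numeric(),
                 blink_end_ms = numeric(), duration_ms = numeric(),
                 category = character(), partial = logical(),
                 tail = character())
}

# Up-loss-down tracker artefact: an apparent upward movement as the lid
# closes, full pupil loss, and a recovery movement landing `net_dx` to the
# right of the start.
make_artifact_session <- function(net_dx, loss_ms = 100, seed = 1) {
  set.seed(seed)
  t_ms <- seq(-2200, 998, by = 2)
  n <- length(t_ms)
  x <- numeric(n); y <- numeric(n); a <- rep(600, n)
  ramp <- 30
  t1 <- 100; t2 <- t1 + ramp; t3 <- t2 + loss_ms; t4 <- t3 + ramp
  up <- t_ms >= t1 & t_ms < t2
  y[up] <- 3 * (t_ms[up] - t1) / ramp
  y[t_ms >= t2 & t_ms < t3] <- 3
  dn <- t_ms >= t3 & t_ms < t4
  y[dn] <- 3 * (1 - (t_ms[dn] - t3) / ramp)
  x[t_ms >= t3] <- net_dx * pmin(1, (t_ms[t_ms >= t3] - t3) / ramp)
  a[up] <- 600 * (1 - (t_ms[up] - t1) / ramp)
  a[t_ms >= t2 & t_ms < t3] <- 0
  a[dn] <- 600 * (t_ms[dn] - t3) / ramp
  samples <- tibble::tibble(
    trial_id = 1L, t_ms = t_ms,
    x = x + rnorm(n, 0, 0.03), y = y + rnorm(n, 0, 0.03),
    a = a, valid = TRUE
  )
  make_session(samples, make_trial_row())
}
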