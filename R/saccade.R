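#' Per-trial dynamic saccade-detection threshold
#'
#' Estimates background speed noise from a known fixation epoch: samples of
#' the epoch with speed below a fixed 50 deg/s ceiling are taken as noise,
#' and the threshold is `mean + 2.5 * SD` of that noise, floored at
#' 20 deg/s. Noisier trials thereby get a higher threshold and fewer false
#' positives, while the floor keeps microsaccade-scale jitter out on quiet
#' trials.
#'
#' @param speed Speed vector for one trial (deg/s).
#' @param fix_mask Logical mask selecting the fixation-epoch samples.
#' @param k_sd SD multiplier.
#' @param floor_dps Threshold floor (deg/s).
#' @param ceiling_dps Fixed ceiling separating noise from movement (deg/s).
#' @param min_n Minimum qualifying samples; below this the floor is used
#'   with a warning.
#' @return One-row tibble: `value`, `noise_mean`, `noise_sd`,
#'   `n_noise_samples`.
#' @examples
#' dynamic_threshold(rep(5, 300), rep(TRUE, 300))  # floored at 20
#' @export
dynamic_threshold <- function(speed, fix_mask, k_sd = 2.5, floor_dps = 20,
                              ceiling_dps = 50, min_n = 50) {
  noise <- speed[fix_mask & speed < ceiling_dps & is.finite(speed)]
  if (length(noise) < min_n) {
    warn(sprintf("only %d fixation noise samples; threshold set to the %g deg/s floor",
                 length(noise), floor_dps))
    return(tibble(value = floor_dps, noise_mean = NA_real_, noise_sd = NA_real_,
                  n_noise_samples = length(noise)))
  }
  m <- mean(noise); s <- sd_or_zero(noise)
  tibble(value = max(floor_dps, m + k_sd * s), noise_mean = m, noise_sd = s,
         n_noise_samples = length(noise))
}

#' Detect raw supra-threshold speed events
#'
#' A saccade candidate is a maximal run of samples with speed above the
#' threshold that lasts at least `min_dur_ms` (5 samples at 500 Hz). Onset
#' is the first sample of the run; offset is the first sub-threshold sample
#' after it.
#'
#' @param speed Speed vector (deg/s).
#' @param threshold Detection threshold (deg/s).
#' @param rate_hz Sampling rate in Hz.
#' @param min_dur_ms Minimum supra-threshold duration in ms.
#' @return Tibble of candidate index pairs `onset`, `offset`.
#' @export
detect_candidates <- function(speed, threshold, rate_hz = 500, min_dur_ms = 10) {
  min_run <- ceiling(min_dur_ms / 1000 * rate_hz)
  runs <- logical_runs(speed > threshold)
  runs <- runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
  n <- length(speed)
  tibble(onset = runs$start, offset = pmin(runs$end + 1L, n))
}

# Measure one event's kinematics from a trial's sample table (needs x_s,
# y_s, speed, t_ms columns). Indices inclusive.
measure_event <- function(ts, onset, offset, dt) {
  seg <- onset:offset
  sp <- ts$speed[seg]
  acc <- if (length(sp) >= 2L) max(central_velocity(sp, dt)) else NA_real_
  dx <- ts$x_s[offset] - ts$x_s[onset]
  dy <- ts$y_s[offset] - ts$y_s[onset]
  tibble(
    onset_ms = ts$t_ms[onset], offset_ms = ts$t_ms[offset],
    duration_ms = ts$t_ms[offset] - ts$t_ms[onset],
    start_x = ts$x_s[onset], start_y = ts$y_s[onset],
    end_x = ts$x_s[offset], end_y = ts$y_s[offset],
    amplitude = sqrt(dx^2 + dy^2),
    angle = atan2(dy, dx) * 180 / pi,
    peak_velocity = max(sp),
    peak_acceleration = acc,
    onset_idx = onset, offset_idx = offset
  )
}

#' Absorb post-saccadic oscillations into their parent saccades
#'
#' Video-based trackers estimate gaze from the pupil, and inertia of the
#' ocular fluids makes the iris oscillate ("slosh") after the eye itself
#' has stopped. These post-saccadic oscillations (PSOs) appear as small
#' supra-threshold events just after a saccade and leave the
#' threshold-detected endpoint hypermetric. A following event is absorbed
#' into the preceding saccade when it starts within `max_gap_ms` of the
#' saccade's offset, its amplitude lies in `amp_range_deg`, and it is
#' smaller than the saccade itself; absorption extends the offset and end
#' point to the PSO's and is applied iteratively left to right, so a merged
#' saccade can absorb further lobes. The pre-merge ("core") offset and end
#' point are retained for diagnostics and for the boomerang test.
#'
#' @param events Measured event tibble for one trial (as from
#'   [measure_event()] rows), time-ordered.
#' @param ts Trial sample table.
#' @param dt Sample interval in seconds.
#' @param max_gap_ms Maximum gap between saccade offset and PSO onset.
#' @param amp_range_deg Length-2 amplitude window for a PSO.
#' @param losses Optional loss-interval tibble (`loss_start_ms`,
#'   `loss_end_ms`) for the trial: an oscillation is a signal artefact of
#'   the tracked pupil, so absorption never reaches across data loss —
#'   events touching a loss interval are left for blincade resolution.
#' @return Event tibble with `pso_merged`, `pso_end_ms`, `core_offset_ms`,
#'   `core_end_x`, `core_end_y` columns.
#' @export
merge_pso <- function(events, ts, dt, max_gap_ms = 40, amp_range_deg = c(0.5, 5),
                      losses = NULL) {
  events$pso_merged <- FALSE
  events$pso_end_ms <- NA_real_
  events$core_offset_ms <- events$offset_ms
  events$core_offset_idx <- events$offset_idx
  events$core_end_x <- events$end_x
  events$core_end_y <- events$end_y
  if (nrow(events) < 2L) return(events)
  touches_loss <- function(a, b) {
    if (is.null(losses) || !nrow(losses)) return(FALSE)
    any(a <= losses$loss_end_ms & b >= losses$loss_start_ms)
  }
  i <- 1L
  while (i < nrow(events)) {
    gap <- events$onset_ms[i + 1L] - events$offset_ms[i]
    amp_next <- events$amplitude[i + 1L]
    if (gap < max_gap_ms && amp_next >= amp_range_deg[1] &&
        amp_next <= amp_range_deg[2] && amp_next < events$amplitude[i] &&
        !touches_loss(events$onset_ms[i], events$offset_ms[i + 1L])) {
      keep <- events[i, c("core_offset_ms", "core_offset_idx", "core_end_x", "core_end_y")]
      merged <- measure_event(ts, events$onset_idx[i], events$offset_idx[i + 1L], dt)
      events[i, names(merged)] <- merged
      events$pso_merged[i] <- TRUE
      events$pso_end_ms[i] <- merged$offset_ms
      events[i, names(keep)] <- keep
      events <- events[-(i + 1L), , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  events
}

# Direction (deg) of displacement over the first/last `win_ms` of an index
# range, from smoothed positions.
segment_direction <- function(ts, from, to, win_ms, rate_hz, tail = FALSE) {
  k <- max(1L, round(win_ms / 1000 * rate_hz))
  if (tail) {
    i0 <- max(from, to - k); i1 <- to
  } else {
    i0 <- from; i1 <- min(to, from + k)
  }
  atan2(ts$y_s[i1] - ts$y_s[i0], ts$x_s[i1] - ts$x_s[i0]) * 180 / pi
}

#' Split fused "boomerang" saccades at a speed nadir
#'
#' A boomerang saccade is two opposed movements — typically an error toward
#' the stimulus immediately redirected to the correct location — fused into
#' one event because eye speed never drops below the detection threshold at
#' the turn. Left unsplit, it masquerades as a single correct saccade and
#' corrupts trial marking. An event is flagged when, over its core
#' (pre-PSO-merge) extent: (i) the initial and final 10 ms displacement
#' directions differ by more than `min_angle_deg`; (ii) each aligns within
#' `axis_tol_deg` of one of the two opposed task directions, and with
#' different ones; and (iii) its metrics are abnormal — path length
#' exceeding `path_ratio` times the net amplitude, or duration exceeding
#' `dur_ratio` times the main-sequence-typical duration
#' (`dur_slope_ms_per_deg * amplitude + dur_intercept_ms`). A flagged event
#' is split at the deepest local speed nadir strictly between its two
#' largest speed peaks, and each half is re-measured as an independent
#' saccade (`boomerang_half` `"first"`/`"second"`).
#'
#' @param event One event row (with PSO columns from [merge_pso()]).
#' @param ts Trial sample table.
#' @param dt Sample interval in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @param task_axes_deg Directions (deg) of the two opposed task locations.
#' @param min_angle_deg,axis_tol_deg,path_ratio,dur_ratio Criteria knobs.
#' @param dur_slope_ms_per_deg,dur_intercept_ms Typical-duration model.
#' @return Tibble of one (unchanged) or two (split) event rows; unsplit
#'   flagged events carry `boomerang_review = TRUE`.
#' @export
split_boomerang <- function(event, ts, dt, rate_hz = 500,
                            task_axes_deg = c(0, 180),
                            min_angle_deg = 135, axis_tol_deg = 45,
                            path_ratio = 1.5, dur_ratio = 1.5,
                            dur_slope_ms_per_deg = 2.2, dur_intercept_ms = 21) {
  event$boomerang_half <- event$boomerang_half %||% "none"
  event$boomerang_review <- event$boomerang_review %||% FALSE
  on <- event$onset_idx
  off_core <- event$core_offset_idx
  if (off_core - on < 4L) return(event)

  d_init <- segment_direction(ts, on, off_core, 10, rate_hz, tail = FALSE)
  d_final <- segment_direction(ts, on, off_core, 10, rate_hz, tail = TRUE)
  if (angle_diff(d_init, d_final) <= min_angle_deg) return(event)
  ax_init <- which(angle_diff(d_init, task_axes_deg) <= axis_tol_deg)
  ax_final <- which(angle_diff(d_final, task_axes_deg) <= axis_tol_deg)
  if (!length(ax_init) || !length(ax_final) || ax_init[1] == ax_final[1]) return(event)

  seg <- on:off_core
  path <- sum(sqrt(diff(ts$x_s[seg])^2 + diff(ts$y_s[seg])^2))
  net <- sqrt((ts$x_s[off_core] - ts$x_s[on])^2 + (ts$y_s[off_core] - ts$y_s[on])^2)
  core_dur <- ts$t_ms[off_core] - ts$t_ms[on]
  typical <- dur_slope_ms_per_deg * net + dur_intercept_ms
  if (!(path > path_ratio * net || core_dur > dur_ratio * typical)) return(event)

  sp <- ts$speed[seg]
  m <- length(sp)
  is_peak <- c(FALSE, sp[2:(m - 1L)] >= sp[1:(m - 2L)] & sp[2:(m - 1L)] >= sp[3:m], FALSE)
  peaks <- which(is_peak)
  p1 <- which.max(sp)
  # the second peak must be a genuinely separate velocity lobe: the valley
  # between it and the global peak has to dip below half the smaller peak,
  # so noise wiggles riding one lobe are never taken as two peaks
  best <- NA_integer_; best_v <- -Inf
  for (j in peaks) {
    if (j == p1) next
    rng <- if (j < p1) j:p1 else p1:j
    if (length(rng) < 3L) next
    valley <- min(sp[rng])
    if (valley < 0.5 * min(sp[j], sp[p1]) && sp[j] > best_v) {
      best <- j; best_v <- sp[j]
    }
  }
  if (is.na(best)) {
    event$boomerang_review <- TRUE
    return(event)
  }
  top2 <- sort(c(p1, best))
  between <- (top2[1] + 1L):(top2[2] - 1L)
  nadir <- seg[between[which.min(sp[between])]]

  first <- measure_event(ts, on, nadir, dt)
  second <- measure_event(ts, nadir, event$offset_idx, dt)
  halves <- bind_rows(first, second)
  halves$boomerang_half <- c("first", "second")
  halves$boomerang_review <- FALSE
  halves$pso_merged <- c(FALSE, event$pso_merged)
  halves$pso_end_ms <- c(NA_real_, event$pso_end_ms)
  halves$core_offset_ms <- c(first$offset_ms, event$core_offset_ms)
  halves$core_offset_idx <- c(first$offset_idx, event$core_offset_idx)
  halves$core_end_x <- c(first$end_x, event$core_end_x)
  halves$core_end_y <- c(first$end_y, event$core_end_y)
  halves
}

#' Resolve blink-contaminated events ("blincades")
#'
#' An event that overlaps a data-loss interval is tagged as a blincade: a
#' gaze displacement during which tracking was lost. A common tracker
#' artefact is a normal blink rendered as an upward blincade immediately
#' followed by a downward "saccade" as the pupil is reacquired. When such a
#' pair (gap below `max_gap_ms`) returns to within `net_thresh_deg` of its
#' starting point, both events are removed and recorded as a blink; when it
#' lands farther away, the pair is combined into a single blincade spanning
#' both events (its trajectory is taken as the straight line start to end).
#' Blincades stay in the table for behavioural analysis but are excluded
#' from kinematic statistics and the main-sequence fit.
#'
#' @param events Event tibble for one trial.
#' @param losses Tibble of loss intervals (`loss_start_ms`, `loss_end_ms`)
#'   for the trial, e.g. from [detect_blinks()].
#' @param ts Trial sample table.
#' @param dt Sample interval in seconds.
#' @param max_gap_ms Pairing gap for the up/down artefact.
#' @param net_thresh_deg Net-displacement cut between "blink" and
#'   "combined blincade".
#' @param up_tol_deg Tolerance around vertical for the up/down test.
#' @return List: `events` (with `blincade` column, pairs resolved) and
#'   `reclassified_blinks` (events removed as pure blinks).
#' @export
resolve_blincades <- function(events, losses, ts, dt, max_gap_ms = 40,
                              net_thresh_deg = 2, up_tol_deg = 45) {
  events$blincade <- FALSE
  reclass <- tibble(onset_ms = numeric(), offset_ms = numeric())
  if (!nrow(events)) return(list(events = events, reclassified_blinks = reclass))
  if (nrow(losses)) {
    for (k in seq_len(nrow(events))) {
      ov <- events$onset_ms[k] <= losses$loss_end_ms &
        events$offset_ms[k] >= losses$loss_start_ms
      events$blincade[k] <- any(ov)
    }
  }
  i <- 1L
  while (i < nrow(events)) {
    up <- events$blincade[i] && angle_diff(events$angle[i], 90) <= up_tol_deg
    # the recovery movement undoes the artefact's upward displacement; it
    # may carry a real horizontal component (gaze moved during the blink),
    # so it is tested on its vertical return, not on total direction
    dy_up <- events$end_y[i] - events$start_y[i]
    dy_down <- events$end_y[i + 1L] - events$start_y[i + 1L]
    down <- dy_down < 0 && abs(dy_down) >= 0.5 * abs(dy_up)
    gap <- events$onset_ms[i + 1L] - events$offset_ms[i]
    if (nrow(losses)) {
      # time during which the tracker reported nothing does not separate
      # the pair behaviourally: discount loss overlapping the gap
      ov <- pmax(0, pmin(losses$loss_end_ms, events$onset_ms[i + 1L]) -
                   pmax(losses$loss_start_ms, events$offset_ms[i]))
      gap <- gap - sum(ov)
    }
    if (up && down && gap < max_gap_ms) {
      net <- sqrt((events$end_x[i + 1L] - events$start_x[i])^2 +
                    (events$end_y[i + 1L] - events$start_y[i])^2)
      if (net < net_thresh_deg) {
        reclass <- bind_rows(reclass, tibble(onset_ms = events$onset_ms[i],
                                             offset_ms = events$offset_ms[i + 1L]))
        events <- events[-c(i, i + 1L), , drop = FALSE]
        next
      } else {
        comb <- measure_event(ts, events$onset_idx[i], events$offset_idx[i + 1L], dt)
        carry <- events[i, setdiff(names(events), names(comb)), drop = FALSE]
        events[i, names(comb)] <- comb
        events[i, names(carry)] <- carry
        events$blincade[i] <- TRUE
        events$core_offset_ms[i] <- comb$offset_ms
        events$core_offset_idx[i] <- comb$offset_idx
        events$core_end_x[i] <- comb$end_x
        events$core_end_y[i] <- comb$end_y
        events <- events[-(i + 1L), , drop = FALSE]
        next
      }
    }
    i <- i + 1L
  }
  list(events = events, reclassified_blinks = reclass)
}

#' Per-trial detection thresholds for a session
#'
#' @param session An [ipast_session] with kinematics added.
#' @param config Pipeline configuration, see [oculopipe_config()].
#' @return Tibble: `trial_id`, `value`, `noise_mean`, `noise_sd`,
#'   `n_noise_samples`.
#' @export
dynamic_thresholds <- function(session, config = oculopipe_config()) {
  cs <- config$saccade
  epoch <- config$drift$epoch_ms
  map_dfr(session$trials$trial_id, function(id) {
    ts <- trial_samples(session, id)
    if (!nrow(ts)) return(NULL)
    mask <- ts$t_ms >= epoch[1] & ts$t_ms < epoch[2] & ts$valid
    thr <- suppressWarnings(dynamic_threshold(
      ts$speed, mask, cs$k_sd, cs$floor_dps, cs$fixed_ceiling_dps
    ))
    mutate(thr, trial_id = id, .before = 1)
  })
}

#' Detect, merge, split and resolve saccades for a session
#'
#' The complete per-trial saccade chain: dynamic threshold
#' ([dynamic_threshold()]), candidate runs ([detect_candidates()]),
#' kinematic measurement, PSO absorption ([merge_pso()]), boomerang
#' splitting ([split_boomerang()]), and — when a blink table is supplied —
#' blincade resolution ([resolve_blincades()]).
#'
#' @param session An [ipast_session] in degrees with kinematics added.
#' @param blinks Optional blink table from [detect_blinks()].
#' @param config Pipeline configuration, see [oculopipe_config()].
#' @return Tibble of saccade records (one row per movement) with kinematic
#'   metrics and the `pso_merged`, `boomerang_half`, `blincade` flags.
#'   Events removed as tracker-artefact blinks are attached as the
#'   `"reclassified_blinks"` attribute.
#' @export
detect_saccades <- function(session, blinks = NULL, config = oculopipe_config()) {
  stopifnot(inherits(session, "ipast_session"))
  if (!"speed" %in% names(session$samples)) abort("run add_kinematics() first")
  cs <- config$saccade; cp <- config$pso; cbm <- config$boomerang; cbl <- config$blincade
  dt <- session_step_ms(session) / 1000
  rate <- session$rate_hz
  epoch <- config$drift$epoch_ms
  reclass_all <- list()
  out <- map_dfr(session$trials$trial_id, function(id) {
    ts <- trial_samples(session, id)
    if (nrow(ts) < 10L) return(NULL)
    mask <- ts$t_ms >= epoch[1] & ts$t_ms < epoch[2] & ts$valid
    thr <- suppressWarnings(dynamic_threshold(
      ts$speed, mask, cs$k_sd, cs$floor_dps, cs$fixed_ceiling_dps
    ))$value
    cand <- detect_candidates(ts$speed, thr, rate, cs$min_dur_ms)
    if (!nrow(cand)) return(NULL)
    events <- map_dfr(seq_len(nrow(cand)), function(k) {
      measure_event(ts, cand$onset[k], cand$offset[k], dt)
    })
    losses <- if (!is.null(blinks) && nrow(blinks)) {
      blinks %>% filter(.data$trial_id == id)
    } else {
      tibble(loss_start_ms = numeric(), loss_end_ms = numeric())
    }
    events <- merge_pso(events, ts, dt, cp$max_gap_ms, cp$amp_range_deg, losses)
    events$boomerang_half <- "none"
    events$boomerang_review <- FALSE
    events <- map_dfr(seq_len(nrow(events)), function(k) {
      split_boomerang(events[k, ], ts, dt, rate,
                      task_axes_deg = cbm$task_axes_deg,
                      min_angle_deg = cbm$min_angle_deg,
                      axis_tol_deg = cbm$axis_tol_deg,
                      path_ratio = cbm$path_ratio, dur_ratio = cbm$dur_ratio,
                      dur_slope_ms_per_deg = cbm$dur_slope_ms_per_deg,
                      dur_intercept_ms = cbm$dur_intercept_ms)
    })
    res <- resolve_blincades(events, losses, ts, dt, cbl$max_gap_ms,
                             cbl$net_thresh_deg)
    if (nrow(res$reclassified_blinks)) {
      reclass_all[[length(reclass_all) + 1L]] <<-
        mutate(res$reclassified_blinks, trial_id = id, .before = 1)
    }
    events <- res$events
    if (!nrow(events)) return(NULL)
    events$threshold <- thr
    mutate(events, trial_id = id, .before = 1)
  })
  proto <- tibble(
    trial_id = integer(), onset_ms = numeric(), offset_ms = numeric(),
    duration_ms = numeric(), start_x = numeric(), start_y = numeric(),
    end_x = numeric(), end_y = numeric(), amplitude = numeric(),
    angle = numeric(), peak_velocity = numeric(), peak_acceleration = numeric(),
    onset_idx = integer(), offset_idx = integer(), pso_merged = logical(),
    pso_end_ms = numeric(), core_offset_ms = numeric(),
    core_offset_idx = integer(), core_end_x = numeric(), core_end_y = numeric(),
    boomerang_half = character(), boomerang_review = logical(),
    blincade = logical(), threshold = numeric()
  )
  out <- bind_rows(proto, out)
  out$lapse_flag <- FALSE
  out$masez_amp <- NA_real_
  out$masez_dur <- NA_real_
  attr(out, "reclassified_blinks") <- bind_rows(reclass_all)
  out
}
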