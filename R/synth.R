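#' Synthetic-session generator configuration
#'
#' Defines the simulated study conditions for a seeded IPAST session with
#' ground truth. Defaults emulate a typical 500 Hz video-based recording:
#' the canonical trial timeline ([ipast_timeline()]), main-sequence saccade
#' kinematics with raised-cosine velocity profiles obeying
#' `Vp = v_inf * (1 - exp(-A / a0))`, damped-sinusoid post-saccadic
#' oscillations (about 20 Hz, 30 ms decay) whose size scales with
#' `slosh_gain`, blinks rendered as a 30 ms area ramp to zero, 50-150 ms of
#' loss and a recovery ramp (placed in the inter-trial interval, where
#' most participants blink), a fixation-locked pupil
#' constriction/dilation response, and additive Gaussian position noise.
#'
#' @param rate_hz Sampling rate (Hz).
#' @param n_trials Number of trials.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output.
#' @param noise_sd_deg Gaze noise SD per axis (deg).
#' @param slosh_gain PSO amplitude scale in `[0, 1+]`; 0 disables slosh.
#' @param pso_freq_hz,pso_decay_ms PSO frequency and decay constant.
#' @param blink_rate_per_trial Expected blinks per trial (Poisson, capped
#'   at 2).
#' @param blink_gaze_artifact Add the up/down gaze artefact to blinks.
#' @param boomerang_prob Probability that an ANTI trial expresses an
#'   error-then-correct fused ("boomerang") movement.
#' @param amplitude_deg Response saccade amplitude (deg) when
#'   `amplitude_range` is `NULL`.
#' @param amplitude_range Optional length-2 range; amplitudes drawn
#'   uniformly, for main-sequence coverage.
#' @param v_inf,a0 Main-sequence parameters (deg/s and deg).
#' @param pupil_baseline,pupil_constriction,pupil_nadir_ms,pupil_dilation,pupil_onset_ms,pupil_dilation_end_ms
#'   Pupil response: baseline area (px^2 counts), constriction amount,
#'   nadir time and response onset (ms after FIX onset), dilation amount
#'   and its completion time.
#' @param area_noise_sd Pupil-area noise SD (px^2 counts).
#' @param drift_sd_deg Per-segment calibration offset SD (deg).
#' @param drift_segment_trials Trials per drift segment.
#' @param behavior_probs Named probabilities of the behavioural archetypes
#'   `correct`, `direction_error`, `anticipatory`, `fixation_break`,
#'   `no_saccade`, `random`, `never_fixated`, `eye_loss` (must sum to 1).
#' @param geometry A [screen_geometry] for the degree-to-pixel rendering.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(rate_hz = 500, n_trials = 40, seed = 1,
                             noise_sd_deg = 0.05,
                             slosh_gain = 1, pso_freq_hz = 20, pso_decay_ms = 30,
                             blink_rate_per_trial = 0.3,
                             blink_gaze_artifact = FALSE,
                             boomerang_prob = 0,
                             amplitude_deg = 10, amplitude_range = NULL,
                             v_inf = 500, a0 = 12,
                             pupil_baseline = 600, pupil_constriction = 80,
                             pupil_nadir_ms = 600, pupil_dilation = 40,
                             pupil_onset_ms = 250, pupil_dilation_end_ms = 1100,
                             area_noise_sd = 0.5,
                             drift_sd_deg = 0.1, drift_segment_trials = 40,
                             behavior_probs = c(correct = 0.80,
                                                direction_error = 0.06,
                                                anticipatory = 0.04,
                                                fixation_break = 0.04,
                                                no_saccade = 0.02,
                                                random = 0.02,
                                                never_fixated = 0.01,
                                                eye_loss = 0.01),
                             geometry = screen_geometry()) {
  if (abs(sum(behavior_probs) - 1) > 1e-9) abort("behavior_probs must sum to 1")
  if (any(behavior_probs < 0)) abort("behavior_probs must be non-negative")
  stopifnot(rate_hz > 0, n_trials >= 0, noise_sd_deg >= 0, slosh_gain >= 0,
            boomerang_prob >= 0, boomerang_prob <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

# Raised-cosine saccade: displacement along its direction at times tau_ms
# after movement start; NULL profile outside.
saccade_profile <- function(tau_ms, amp, v_peak) {
  d_ms <- 2 * amp / v_peak * 1000
  p <- tau_ms / d_ms
  disp <- ifelse(tau_ms <= 0, 0,
                 ifelse(tau_ms >= d_ms, amp,
                        amp * (p - sin(2 * pi * p) / (2 * pi))))
  list(disp = disp, d_ms = d_ms)
}

#' Measurable amplitude of a commanded saccade
#'
#' Ground-truth event boundaries use the measurable-motion convention: a
#' saccade "starts" and "ends" where its commanded speed crosses the
#' 20 deg/s detection floor, below which commanded motion is
#' indistinguishable from fixational noise. The displacement between those
#' crossings — the commanded amplitude minus the sub-floor creep at each
#' end — is the amplitude a threshold-based detector can observe, and is
#' the domain on which the fitted main sequence is compared against the
#' generative one.
#'
#' @param amp Commanded amplitude(s), deg.
#' @param v_inf,a0 Main-sequence parameters of the generator.
#' @param floor_dps Detection floor (deg/s).
#' @return Measurable amplitude(s), deg.
#' @export
measurable_amplitude <- function(amp, v_inf = 500, a0 = 12, floor_dps = 20) {
  vp <- v_inf * (1 - exp(-amp / a0))
  p <- asin(sqrt(pmin(1, floor_dps / vp))) / pi  # crossing as fraction of duration
  creep <- amp * (p - sin(2 * pi * p) / (2 * pi))
  amp - 2 * creep
}

# First/last time (ms after movement start) at which the commanded speed
# exceeds `floor_dps`; the measurable-onset convention for ground truth.
profile_crossings <- function(amp, v_peak, floor_dps = 20) {
  d_ms <- 2 * amp / v_peak * 1000
  if (v_peak <= floor_dps) return(c(on = 0, off = d_ms))
  tau <- (d_ms / pi) * asin(sqrt(floor_dps / v_peak))
  c(on = tau, off = d_ms - tau)
}

# Damped-sinusoid PSO displacement at tau_ms after the eye stops.
pso_profile <- function(tau_ms, amp_deg, freq_hz, decay_ms) {
  ifelse(tau_ms <= 0, 0,
         amp_deg * exp(-tau_ms / decay_ms) * sin(2 * pi * freq_hz * tau_ms / 1000))
}

#' Simulate a seeded synthetic IPAST session with ground truth
#'
#' Builds each trial's gaze and pupil-area traces from the configured
#' archetype mix, renders them to screen pixels through the configured
#' geometry (so the reader, unit conversion and drift correction are all
#' exercised), and records ground truth for every injected event.
#'
#' Ground-truth saccade onsets/offsets use the measurable-motion
#' convention: the first/last moment the commanded (noise-free) eye speed
#' exceeds the 20 deg/s detection floor, below which the commanded motion
#' is indistinguishable from fixational noise by construction.
#' `signal_offset_ms` additionally waits for the post-saccadic oscillation
#' of the recorded signal to decay below the same floor.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory: the session is also written in both
#'   dialects (`session.asc` and the tabular form) plus `truth.json`.
#' @return List with `session` (an [ipast_session], gaze in pixels) and
#'   `truth` (list of tibbles: `trials`, `saccades`, `blinks`, `pupil`).
#' @export
simulate_session <- function(config = generator_config(), out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  tl <- ipast_timeline()
  step <- 1000 / config$rate_hz
  if (!is.null(config$amplitude_range)) {
    if (max(config$amplitude_range) >= 40) abort("saccade amplitude implausibly large for the screen")
  }
  n_samp <- round(tl$trial_ms / step)
  t_ms <- tl$iti_start_ms + (seq_len(n_samp) - 1L) * step
  set.seed(config$seed)

  truth_sacc <- list(); truth_blink <- list(); truth_trial <- list(); truth_pupil <- list()
  all_samples <- vector("list", config$n_trials)
  trials <- vector("list", config$n_trials)

  behaviors <- if (config$n_trials) {
    sample(names(config$behavior_probs), config$n_trials, replace = TRUE,
           prob = config$behavior_probs)
  } else character()
  n_segs <- max(1L, ceiling(config$n_trials / config$drift_segment_trials))
  drift_offsets <- matrix(rnorm(2L * n_segs, 0, config$drift_sd_deg), ncol = 2)

  for (i in seq_len(config$n_trials)) {
    condition <- sample(c("PRO", "ANTI"), 1)
    stim_side <- sample(c("left", "right"), 1)
    behavior <- behaviors[i]
    if (condition == "ANTI" && behavior %in% c("correct", "direction_error") &&
        runif(1) < config$boomerang_prob) {
      behavior <- "boomerang"
    }
    seg <- ((i - 1L) %/% config$drift_segment_trials) + 1L

    build <- build_trial_trace(t_ms, behavior, condition, stim_side, config, i)
    x <- build$x; y <- build$y; a <- build$a

    # per-segment calibration offset + sample noise, then render to pixels
    drift <- drift_offsets[seg, ]
    x_rec <- x + drift[1] + rnorm(n_samp, 0, config$noise_sd_deg)
    y_rec <- y + drift[2] + rnorm(n_samp, 0, config$noise_sd_deg)
    a_rec <- pmax(0, ifelse(a == 0, 0, a + rnorm(n_samp, 0, config$area_noise_sd)))

    all_samples[[i]] <- tibble(
      trial_id = i, t_ms = t_ms,
      x = deg_to_px_x(x_rec, config$geometry),
      y = deg_to_px_y(y_rec, config$geometry),
      a = a_rec, valid = TRUE
    )
    trials[[i]] <- tibble(
      trial_id = i, condition = condition, stim_side = stim_side,
      fix_on_ms = tl$fix_on_ms, fix_off_ms = tl$fix_off_ms,
      stim_on_ms = tl$stim_on_ms, trial_end_ms = t_ms[n_samp],
      drift_segment = seg, not_marked = FALSE
    )
    truth_trial[[i]] <- tibble(
      trial_id = i, condition = condition, stim_side = stim_side,
      behavior = behavior, category = build$category, srt = build$srt,
      drift_segment = seg, drift_dx = drift[1], drift_dy = drift[2]
    )
    if (nrow(build$saccades)) truth_sacc[[i]] <- mutate(build$saccades, trial_id = i, .before = 1)
    if (nrow(build$blinks)) truth_blink[[i]] <- mutate(build$blinks, trial_id = i, .before = 1)
    truth_pupil[[i]] <- tibble(
      trial_id = i, baseline = config$pupil_baseline,
      constriction = config$pupil_constriction,
      nadir_ms = config$pupil_nadir_ms, dilation = config$pupil_dilation,
      onset_ms = config$pupil_onset_ms,
      eligible_intended = build$pupil_quiet
    )
  }

  session <- ipast_session(
    samples = bind_rows(all_samples), trials = bind_rows(trials),
    geometry = config$geometry, rate_hz = config$rate_hz, units = "px"
  )
  truth <- list(
    trials = bind_rows(truth_trial),
    saccades = bind_rows(truth_sacc) %||% tibble(),
    blinks = bind_rows(truth_blink) %||% tibble(),
    pupil = bind_rows(truth_pupil)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_asc(session, file.path(out_dir, "session.asc"))
    write_session(session, file.path(out_dir, "table"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  list(session = session, truth = truth)
}

# One trial's noise-free deg-space trace plus its ground-truth events.
build_trial_trace <- function(t_ms, behavior, condition, stim_side, config, trial_id) {
  tl <- ipast_timeline()
  n <- length(t_ms)
  x <- numeric(n); y <- numeric(n)
  ecc <- tl$stim_ecc_deg
  stim_dir <- if (stim_side == "right") 0 else 180
  anti_dir <- (stim_dir + 180) %% 360
  sacc_rows <- list()
  pupil_quiet <- TRUE
  category <- NA_character_
  srt <- NA_real_

  amp_of <- function() {
    if (is.null(config$amplitude_range)) config$amplitude_deg
    else runif(1, config$amplitude_range[1], config$amplitude_range[2])
  }
  v_peak_of <- function(amp) config$v_inf * (1 - exp(-amp / config$a0))

  add_sacc <- function(t0, amp, dir_deg, slosh = config$slosh_gain) {
    vp <- v_peak_of(amp)
    pr <- saccade_profile(t_ms - t0, amp, vp)
    ux <- cos(dir_deg * pi / 180); uy <- sin(dir_deg * pi / 180)
    dx <- pr$disp * ux; dy <- pr$disp * uy
    pso_amp <- slosh * (0.3 + 0.05 * amp)
    sig_off_extra <- 0
    if (pso_amp > 0) {
      ps <- pso_profile(t_ms - (t0 + pr$d_ms), pso_amp, config$pso_freq_hz,
                        config$pso_decay_ms)
      dx <- dx + ps * ux; dy <- dy + ps * uy
      v_env <- pso_amp * 2 * pi * config$pso_freq_hz  # peak PSO speed (deg/s)
      if (v_env > 20) sig_off_extra <- config$pso_decay_ms * log(v_env / 20)
    }
    x <<- x + dx; y <<- y + dy
    cr <- profile_crossings(amp, vp, 20)
    tibble(
      onset_ms = t0 + cr[["on"]], offset_ms = t0 + cr[["off"]],
      signal_offset_ms = t0 + pr$d_ms + sig_off_extra,
      amp = amp, dir_deg = dir_deg, v_peak = vp, d_ms = pr$d_ms,
      boomerang = FALSE, pair_id = NA_integer_
    )
  }

  if (behavior == "correct" || behavior == "direction_error") {
    srt <- min(max(rnorm(1, 230, 45), 150), 600)
    amp <- amp_of()
    goal <- if (condition == "PRO") stim_dir else anti_dir
    dir <- if (behavior == "correct") goal else (goal + 180) %% 360
    sacc_rows[[1]] <- add_sacc(srt, amp, dir)
    category <- paste0(
      if (srt <= 89) "Anticipatory " else "",
      if (behavior == "correct") "Correct " else "",
      if (condition == "PRO") "Pro-Saccade" else "Anti-Saccade",
      if (behavior == "direction_error") " Direction Error" else ""
    )
  } else if (behavior == "anticipatory") {
    srt <- runif(1, -90, 70)
    amp <- amp_of()
    goal <- if (condition == "PRO") stim_dir else anti_dir
    correct <- runif(1) < 0.5
    dir <- if (correct) goal else (goal + 180) %% 360
    sacc_rows[[1]] <- add_sacc(srt, amp, dir)
    category <- paste0(
      "Anticipatory ",
      if (correct) "Correct " else "",
      if (condition == "PRO") "Pro-Saccade" else "Anti-Saccade",
      if (!correct) " Direction Error" else ""
    )
  } else if (behavior == "boomerang") {
    srt <- min(max(rnorm(1, 230, 45), 150), 500)
    amp1 <- ecc
    amp2 <- 2 * ecc
    vp1 <- v_peak_of(amp1)
    d1 <- 2 * amp1 / vp1 * 1000
    r1 <- add_sacc(srt, amp1, stim_dir, slosh = 0)
    r2 <- add_sacc(srt + d1, amp2, anti_dir, slosh = config$slosh_gain)
    # vertical velocity bump spanning the turn keeps speed supra-threshold
    bump_w <- 20; bump_v <- 80
    tau <- t_ms - (srt + d1 - bump_w / 2)
    inb <- tau > 0 & tau < bump_w
    y_b <- numeric(n)
    y_b[inb] <- bump_v / 1000 * (tau[inb] / 2 - (bump_w / (4 * pi)) * sin(2 * pi * tau[inb] / bump_w))
    y_b[t_ms >= srt + d1 + bump_w / 2] <- bump_v / 1000 * bump_w / 2
    y <- y + y_b
    r1$boomerang <- TRUE; r2$boomerang <- TRUE
    r1$pair_id <- trial_id; r2$pair_id <- trial_id
    sacc_rows <- list(r1, r2)
    category <- "Anti-Saccade Direction Error"
  } else if (behavior == "fixation_break") {
    t0 <- runif(1, -900, -500)
    amp <- runif(1, 3, 8)
    dir <- sample(c(0, 180), 1)
    sacc_rows[[1]] <- add_sacc(t0, amp, dir)
    category <- "Fixation Break"
    pupil_quiet <- FALSE
  } else if (behavior == "no_saccade") {
    category <- "No Saccade"
  } else if (behavior == "random") {
    srt <- min(max(rnorm(1, 250, 40), 150), 500)
    sacc_rows[[1]] <- add_sacc(srt, 6, sample(c(90, -90), 1))
    category <- "Random Saccade"
  } else if (behavior == "never_fixated") {
    x <- x + 5; y <- y + 3
    category <- "Never Fixated"
    pupil_quiet <- FALSE
  } else if (behavior == "eye_loss") {
    category <- "Eye Loss"
    pupil_quiet <- FALSE
  } else {
    abort(sprintf("unknown behavior archetype '%s'", behavior))
  }

  # saccade start/end ground-truth positions from the noise-free trace
  sacc <- bind_rows(sacc_rows)
  if (nrow(sacc)) {
    idx_at <- function(t) pmin(pmax(1L, round((t - t_ms[1]) / (t_ms[2] - t_ms[1])) + 1L), n)
    settle <- idx_at(sacc$signal_offset_ms + 3 * config$pso_decay_ms)
    sacc$start_x <- x[idx_at(sacc$onset_ms)]
    sacc$start_y <- y[idx_at(sacc$onset_ms)]
    sacc$end_x <- x[settle]
    sacc$end_y <- y[settle]
    if (nrow(sacc) > 1) {  # boomerang halves end where the next begins / at settle
      sacc$end_x[1] <- x[idx_at(sacc$offset_ms[1])]
      sacc$end_y[1] <- y[idx_at(sacc$offset_ms[1])]
    }
  }

  # pupil-area response and blinks
  a <- pupil_curve(t_ms, config)
  blink_rows <- list()
  n_blinks <- min(rpois(1, config$blink_rate_per_trial), 2L)
  if (behavior != "eye_loss" && n_blinks > 0) {
    starts <- sort(runif(n_blinks, -2100, -1750))
    if (n_blinks > 1L) {  # blinks cannot overlap; enforce a refractory gap
      for (b in 2:n_blinks) {
        starts[b] <- max(starts[b], starts[b - 1L] + 300)
      }
    }
    for (b in seq_len(n_blinks)) {
      loss_dur <- runif(1, 50, 150)
      res <- apply_blink(t_ms, a, x, y, starts[b], loss_dur,
                         config$blink_gaze_artifact)
      a <- res$a; x <- res$x; y <- res$y
      blink_rows[[b]] <- tibble(
        loss_start_ms = starts[b] + 30, loss_end_ms = starts[b] + 30 + loss_dur,
        blink_start_ms = starts[b], blink_end_ms = starts[b] + 60 + loss_dur
      )
    }
  }
  if (behavior == "eye_loss") a[t_ms >= -1200 & t_ms <= 600] <- 0

  list(x = x, y = y, a = a, saccades = sacc,
       blinks = bind_rows(blink_rows) %||% tibble(),
       category = category, srt = srt, pupil_quiet = pupil_quiet)
}

# Fixation-locked pupil response in raw area units: flat baseline, a sine
# ramp into the nadir (non-zero initial constriction velocity, smooth
# bottom), then a sine ramp of dilation completing before STIM onset.
pupil_curve <- function(t_ms, config) {
  tau <- t_ms + 1200  # ms after FIX onset
  B <- config$pupil_baseline; C <- config$pupil_constriction
  D <- config$pupil_dilation
  on <- config$pupil_onset_ms; nad <- config$pupil_nadir_ms
  dend <- config$pupil_dilation_end_ms
  a <- rep(B, length(tau))
  con <- tau > on & tau <= nad
  a[con] <- B - C * sin(pi / 2 * (tau[con] - on) / (nad - on))
  dil <- tau > nad & tau <= dend
  a[dil] <- B - C + D * sin(pi / 2 * (tau[dil] - nad) / (dend - nad))
  a[tau > dend] <- B - C + D
  a
}

# Render one blink into the area (and optionally gaze) traces: 30 ms ramp
# to zero, loss, 30 ms recovery ramp; optional up/down gaze artefact.
apply_blink <- function(t_ms, a, x, y, start_ms, loss_dur_ms, gaze_artifact) {
  ramp <- 30
  t1 <- start_ms; t2 <- start_ms + ramp
  t3 <- t2 + loss_dur_ms; t4 <- t3 + ramp
  down <- t_ms >= t1 & t_ms < t2
  lost <- t_ms >= t2 & t_ms < t3
  up <- t_ms >= t3 & t_ms < t4
  a[down] <- a[down] * (1 - (t_ms[down] - t1) / ramp)
  a[lost] <- 0
  a[up] <- a[up] * ((t_ms[up] - t3) / ramp)
  if (gaze_artifact) {
    # tracker drags gaze up as the lid descends, snaps back on reacquisition
    rise <- t_ms >= t1 & t_ms < t3
    y[rise] <- y[rise] + 3 * pmin(1, (t_ms[rise] - t1) / ramp)
    fall <- t_ms >= t3 & t_ms < t4
    y[fall] <- y[fall] + 3 * (1 - (t_ms[fall] - t3) / ramp)
  }
  list(a = a, x = x, y = y)
}

#' Score detected events against generator ground truth
#'
#' Greedy one-to-one matching of detected saccades and blinks to the
#' ground-truth events of the same trial by onset proximity. Reports
#' precision/recall (with the amplitude filter applied to each side of the
#' comparison independently, so a truth event is never penalised for a
#' sub-threshold detection of itself), onset timing errors, endpoint
#' errors with and without PSO absorption, boomerang split recovery, and
#' blink extent containment.
#'
#' @param saccades Detected saccade table (degree space, drift-corrected).
#' @param blinks Detected blink table.
#' @param truth Ground truth from [simulate_session()].
#' @param tol_ms Onset matching tolerance (ms).
#' @param min_amplitude Amplitude filter (deg) for the precision/recall
#'   figures.
#' @return List with elements `saccades` (recall, precision, onset errors,
#'   endpoint errors), `blinks` (recall, precision, containment rate) and
#'   `boomerang` (pair recovery rate, false splits).
#' @export
score_detection <- function(saccades, blinks, truth, tol_ms = 20,
                            min_amplitude = 2) {
  ts <- truth$saccades
  det <- saccades
  onset_err <- numeric(); end_err_merged <- numeric(); end_err_core <- numeric()
  n_true <- 0L; n_true_matched <- 0L
  det$matched <- FALSE
  if (nrow(ts)) {
    for (id in unique(ts$trial_id)) {
      tt <- ts[ts$trial_id == id, ]
      dd_idx <- which(det$trial_id == id)
      used <- rep(FALSE, length(dd_idx))
      for (k in order(tt$onset_ms)) {
        big <- tt$amp[k] >= min_amplitude
        if (big) n_true <- n_true + 1L
        if (!length(dd_idx)) next
        d <- abs(det$onset_ms[dd_idx] - tt$onset_ms[k])
        d[used] <- Inf
        j <- which.min(d)
        if (is.finite(d[j]) && d[j] <= tol_ms) {
          used[j] <- TRUE
          det$matched[dd_idx[j]] <- TRUE
          if (big) {
            n_true_matched <- n_true_matched + 1L
            onset_err <- c(onset_err, d[j])
            ee <- sqrt((det$end_x[dd_idx[j]] - tt$end_x[k])^2 +
                         (det$end_y[dd_idx[j]] - tt$end_y[k])^2)
            ec <- sqrt((det$core_end_x[dd_idx[j]] - tt$end_x[k])^2 +
                         (det$core_end_y[dd_idx[j]] - tt$end_y[k])^2)
            end_err_merged <- c(end_err_merged, ee)
            end_err_core <- c(end_err_core, ec)
          }
        }
      }
    }
  }
  det_big <- det[det$amplitude >= min_amplitude & !det$blincade, , drop = FALSE]
  sacc_score <- list(
    n_true = n_true,
    recall = if (n_true) n_true_matched / n_true else NA_real_,
    precision = if (nrow(det_big)) mean(det_big$matched) else NA_real_,
    onset_err = onset_err,
    onset_p95 = if (length(onset_err)) unname(stats::quantile(onset_err, 0.95)) else NA_real_,
    end_err_merged = mean(end_err_merged),
    end_err_core = mean(end_err_core)
  )

  tb <- truth$blinks
  n_tb <- nrow(tb); n_tb_match <- 0L; contained <- logical()
  dblink <- blinks[blinks$category == "blink", , drop = FALSE]
  dblink$matched <- FALSE
  if (n_tb) {
    for (k in seq_len(n_tb)) {
      cand <- which(dblink$trial_id == tb$trial_id[k] & !dblink$matched &
                      dblink$loss_start_ms <= tb$loss_end_ms[k] + tol_ms &
                      dblink$loss_end_ms >= tb$loss_start_ms[k] - tol_ms)
      if (length(cand)) {
        j <- cand[1]
        dblink$matched[j] <- TRUE
        n_tb_match <- n_tb_match + 1L
        contained <- c(contained,
                       dblink$blink_start_ms[j] <= tb$loss_start_ms[k] + tol_ms / 10 &&
                         dblink$blink_end_ms[j] >= tb$loss_end_ms[k] - tol_ms / 10)
      }
    }
  }
  blink_score <- list(
    n_true = n_tb,
    recall = if (n_tb) n_tb_match / n_tb else NA_real_,
    precision = if (nrow(dblink)) mean(dblink$matched) else NA_real_,
    containment = if (length(contained)) mean(contained) else NA_real_
  )

  pair_ids <- unique(ts$pair_id[!is.na(ts$pair_id)])
  n_pairs <- length(pair_ids); n_split <- 0L
  for (pid in pair_ids) {
    pr <- ts[!is.na(ts$pair_id) & ts$pair_id == pid, ]
    id <- pr$trial_id[1]
    win <- c(min(pr$onset_ms) - tol_ms, max(pr$signal_offset_ms) + 3 * tol_ms)
    dd <- det[det$trial_id == id & det$onset_ms >= win[1] & det$onset_ms <= win[2] &
                det$amplitude >= min_amplitude, , drop = FALSE]
    dx <- dd$end_x - dd$start_x
    if (nrow(dd) >= 2L && any(dx > 0) && any(dx < 0)) n_split <- n_split + 1L
  }
  false_splits <- sum(det$boomerang_half != "none" &
                        !(det$trial_id %in% ts$trial_id[!is.na(ts$pair_id)]))
  list(
    saccades = sacc_score, blinks = blink_score,
    boomerang = list(n_pairs = n_pairs,
                     split_rate = if (n_pairs) n_split / n_pairs else NA_real_,
                     false_splits = false_splits)
  )
}
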