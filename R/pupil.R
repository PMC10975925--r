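#' Pupillometry eligibility per trial
#'
#' Pupil size is sensitive to eye position, movement, and data loss, so the
#' fixation-locked pupil response is only measured on quiet trials: during
#' the fixation-plus-gap window the trial must contain no saccade larger
#' than `radius_deg`, mean gaze must stay within `radius_deg` of the
#' fixation point, and total data loss must stay under `max_loss_ms`.
#'
#' @param session An [ipast_session] in degrees (drift-corrected).
#' @param saccades Saccade table from [detect_saccades()].
#' @param blinks Blink table from [detect_blinks()].
#' @param config Pipeline configuration; the `pupil` block supplies
#'   `center_radius_deg` and `max_loss_ms`.
#' @return Tibble: `trial_id`, `eligible`, `reason` (empty when eligible;
#'   semicolon-joined codes otherwise).
#' @export
trial_eligibility <- function(session, saccades, blinks,
                              config = oculopipe_config()) {
  cp <- config$pupil
  step <- session_step_ms(session)
  map_dfr(seq_len(nrow(session$trials)), function(i) {
    tr <- session$trials[i, ]
    id <- tr$trial_id
    win <- c(tr$fix_on_ms, tr$stim_on_ms)
    ts <- trial_samples(session, id) %>%
      filter(.data$t_ms >= win[1], .data$t_ms < win[2])
    reasons <- character()
    if (!nrow(ts)) {
      reasons <- "no_samples"
    } else {
      sac <- saccades %>%
        filter(.data$trial_id == id, .data$amplitude > cp$center_radius_deg,
               .data$onset_ms < win[2], .data$offset_ms > win[1])
      if (nrow(sac)) reasons <- c(reasons, "saccade>2deg")
      if (sqrt(mean(ts$x)^2 + mean(ts$y)^2) > cp$center_radius_deg) {
        reasons <- c(reasons, "off_center")
      }
      loss_ms <- sum(ts$a == 0 | !ts$valid) * step
      if (loss_ms >= cp$max_loss_ms) reasons <- c(reasons, "loss>=200ms")
    }
    tibble(trial_id = id, eligible = !length(reasons),
           reason = paste(reasons, collapse = ";"))
  })
}

#' Fixation-locked pupil response metrics
#'
#' Measures the stereotyped constriction-then-dilation pupil response to
#' fixation onset on each eligible trial, using the raw pupil area in
#' camera pixel counts. Time below is relative to fixation (FIX) onset;
#' the fixation epoch runs to stimulus onset (1200 ms, including the gap).
#'
#' * `baseline`: mean area over 150-200 ms (before any response);
#' * `min_size`, `max_constriction_time`: nadir of the area over the
#'   fixation epoch (loss samples excluded — a nadir is never taken from
#'   interpolated data) and its time;
#' * `final_size`: mean area over the 150-200 ms before stimulus onset;
#' * `onset_latency`: start of the earliest 20 ms sliding window (after
#'   200 ms) in which every sample deviates from baseline in the same
#'   direction by more than 1.96 baseline SDs; missing if never;
#' * `max_constriction_velocity`: most negative smoothed area derivative
#'   between onset latency and the nadir (area units/s);
#' * `max_dilation_velocity`: most positive between the nadir and stimulus
#'   onset;
#' * `constriction_amount = baseline - min_size`;
#'   `dilation_amount = final_size - min_size`.
#'
#' A loss sample inside the baseline or final averaging window makes the
#' trial's metrics missing (reason `baseline_loss`/`final_loss`).
#'
#' @param session An [ipast_session] (units of `x`/`y` irrelevant; raw `a`
#'   is used).
#' @param eligibility Tibble from [trial_eligibility()]; computed when
#'   `NULL` is not allowed — pass it so reasons propagate.
#' @param config Pipeline configuration (`pupil` block: `window_ms`,
#'   `sig_sd`, `baseline_ms`, `final_ms`).
#' @return Tibble, one row per trial, with the metrics above plus
#'   `eligible` and `reason`; ineligible trials carry missing metrics.
#' @export
pupil_metrics <- function(session, eligibility, config = oculopipe_config()) {
  cp <- config$pupil
  step <- session_step_ms(session)
  dt <- step / 1000
  map_dfr(seq_len(nrow(session$trials)), function(i) {
    tr <- session$trials[i, ]
    id <- tr$trial_id
    el <- eligibility %>% filter(.data$trial_id == id)
    na_row <- tibble(
      trial_id = id, baseline = NA_real_, min_size = NA_real_,
      max_constriction_time = NA_real_, final_size = NA_real_,
      onset_latency = NA_real_, max_constriction_velocity = NA_real_,
      constriction_amount = NA_real_, max_dilation_velocity = NA_real_,
      dilation_amount = NA_real_,
      eligible = el$eligible[1] %||% FALSE, reason = el$reason[1] %||% "no_samples"
    )
    if (!nrow(el) || !el$eligible[1]) return(na_row)

    ts <- trial_samples(session, id) %>%
      filter(.data$t_ms >= tr$fix_on_ms, .data$t_ms < tr$stim_on_ms)
    tau <- ts$t_ms - tr$fix_on_ms  # ms after FIX onset
    lost <- ts$a == 0 | !ts$valid

    in_base <- tau >= cp$baseline_ms[1] & tau <= cp$baseline_ms[2]
    in_final <- tau >= cp$final_ms[1] & tau <= cp$final_ms[2]
    if (any(lost[in_base])) { na_row$reason <- "baseline_loss"; na_row$eligible <- FALSE; return(na_row) }
    if (any(lost[in_final])) { na_row$reason <- "final_loss"; na_row$eligible <- FALSE; return(na_row) }

    baseline <- mean(ts$a[in_base])
    final_size <- mean(ts$a[in_final])
    usable <- which(!lost)
    j_min <- usable[which.min(ts$a[usable])]
    min_size <- ts$a[j_min]
    mct <- tau[j_min]

    base_sd <- sd_or_zero(ts$a[in_base])
    thr <- cp$sig_sd * base_sd
    wlen <- max(1L, round(cp$window_ms / step))
    onset <- NA_real_
    starts <- which(tau > cp$baseline_ms[2] & tau + cp$window_ms <= max(tau))
    dev <- ts$a - baseline
    for (s in starts) {
      idx <- s:(s + wlen - 1L)
      d <- dev[idx]
      if (all(d > thr) || all(d < -thr)) { onset <- tau[s]; break }
    }

    da <- zero_phase_boxcar(central_velocity(ts$a, dt), 3)
    mcv <- NA_real_
    if (!is.na(onset)) {
      seg <- tau >= onset & tau <= mct
      if (any(seg)) mcv <- min(da[seg])
    }
    seg2 <- tau >= mct
    mdv <- if (any(seg2)) max(da[seg2]) else NA_real_

    tibble(
      trial_id = id, baseline = baseline, min_size = min_size,
      max_constriction_time = mct, final_size = final_size,
      onset_latency = onset, max_constriction_velocity = mcv,
      constriction_amount = baseline - min_size,
      max_dilation_velocity = mdv,
      dilation_amount = final_size - min_size,
      eligible = TRUE, reason = ""
    )
  })
}
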