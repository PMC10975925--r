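#' Plot one trial's gaze, speed and pupil traces
#'
#' Faceted time-series view of a single trial: horizontal and vertical
#' gaze, eye speed with the trial's detection threshold, and pupil area;
#' detected saccades and blink extents are shaded when result tables are
#' supplied.
#'
#' @param session An [ipast_session] (degrees, with kinematics for the
#'   speed panel).
#' @param trial_id Trial to plot.
#' @param saccades,blinks Optional detection tables.
#' @param threshold Optional detection threshold (deg/s) to draw.
#' @return A ggplot object.
#' @export
plot_trial <- function(session, trial_id, saccades = NULL, blinks = NULL,
                       threshold = NULL) {
  ts <- trial_samples(session, trial_id)
  if (!nrow(ts)) abort(sprintf("no samples for trial %s", trial_id))
  long <- bind_rows(
    tibble(t_ms = ts$t_ms, value = ts$x, panel = "x (deg)"),
    tibble(t_ms = ts$t_ms, value = ts$y, panel = "y (deg)"),
    if ("speed" %in% names(ts)) tibble(t_ms = ts$t_ms, value = ts$speed, panel = "speed (deg/s)"),
    tibble(t_ms = ts$t_ms, value = ts$a, panel = "pupil area")
  )
  p <- ggplot(long, aes(x = .data$t_ms, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "time from STIM onset (ms)", y = NULL,
         title = sprintf("Trial %s", trial_id)) +
    theme_minimal()
  if (!is.null(saccades)) {
    sc <- saccades %>% filter(.data$trial_id == !!trial_id)
    if (nrow(sc)) {
      p <- p + geom_rect(
        data = tibble(xmin = sc$onset_ms, xmax = sc$offset_ms),
        aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
      )
    }
  }
  if (!is.null(blinks)) {
    bl <- blinks %>% filter(.data$trial_id == !!trial_id)
    if (nrow(bl)) {
      p <- p + geom_rect(
        data = tibble(xmin = bl$blink_start_ms, xmax = bl$blink_end_ms),
        aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.15, fill = "darkorange"
      )
    }
  }
  if (!is.null(threshold)) {
    p <- p + geom_hline(
      data = tibble(panel = "speed (deg/s)", yint = threshold),
      aes(yintercept = .data$yint), linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' Plot the fixation-locked pupil response of eligible trials
#'
#' Overlays the raw pupil-area traces of pupillometry-eligible trials,
#' time-locked to fixation onset, with the baseline and final averaging
#' windows shaded.
#'
#' @param session An [ipast_session].
#' @param metrics Pupil metrics table from [pupil_metrics()].
#' @param config Pipeline configuration (for the window definitions).
#' @return A ggplot object.
#' @export
plot_pupil_response <- function(session, metrics, config = oculopipe_config()) {
  ok <- metrics %>% filter(.data$eligible)
  if (!nrow(ok)) abort("no eligible trials to plot")
  traces <- map_dfr(ok$trial_id, function(id) {
    tr <- session$trials[session$trials$trial_id == id, ]
    ts <- trial_samples(session, id) %>%
      filter(.data$t_ms >= tr$fix_on_ms, .data$t_ms < tr$stim_on_ms)
    tibble(trial_id = id, tau = ts$t_ms - tr$fix_on_ms, a = ts$a)
  })
  wins <- tibble(
    xmin = c(config$pupil$baseline_ms[1], config$pupil$final_ms[1]),
    xmax = c(config$pupil$baseline_ms[2], config$pupil$final_ms[2])
  )
  ggplot(traces, aes(x = .data$tau, y = .data$a, group = .data$trial_id)) +
    geom_rect(data = wins,
              aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
              inherit.aes = FALSE, alpha = 0.2, fill = "grey60") +
    geom_line(alpha = 0.3) +
    labs(x = "time from FIX onset (ms)", y = "pupil area (px counts)",
         title = "Fixation-locked pupil response") +
    theme_minimal()
}
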