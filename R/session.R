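#' IPAST trial timeline constants
#'
#' The canonical trial structure of the interleaved pro/anti-saccade task:
#' a 1000 ms inter-trial interval, a 1000 ms central fixation point whose
#' colour carries the trial instruction, a 200 ms gap, and a peripheral
#' stimulus 10 degrees left or right of fixation; each trial lasts 3200 ms.
#' All per-trial sample times in this package are expressed relative to
#' stimulus (STIM) onset.
#'
#' @return Named list of timing constants in ms (relative to STIM onset
#'   where applicable) and the stimulus eccentricity in degrees.
#' @export
ipast_timeline <- function() {
  list(
    trial_ms = 3200,
    iti_start_ms = -2200,
    fix_on_ms = -1200,
    fix_off_ms = -200,
    stim_on_ms = 0,
    trial_end_ms = 1000,
    stim_ecc_deg = 10
  )
}

#' Construct an eye-tracking session object
#'
#' Bundles per-trial gaze samples, trial metadata, and screen geometry into
#' a single object that the pipeline stages pass along. Samples are stored
#' long (one row per sample), times in ms relative to each trial's stimulus
#' onset.
#'
#' @param samples Tibble with columns `trial_id`, `t_ms`, `x`, `y`, `a`
#'   (pupil area, >= 0, 0 = data loss) and `valid` (logical; `FALSE` marks
#'   repaired or lost samples).
#' @param trials Tibble with one row per trial: `trial_id`, `condition`
#'   (`"PRO"`/`"ANTI"`), `stim_side` (`"left"`/`"right"`), the event times
#'   `fix_on_ms`, `fix_off_ms`, `stim_on_ms`, `trial_end_ms` (ms, relative
#'   to STIM onset), `drift_segment` (integer) and `not_marked` (logical).
#' @param geometry A [screen_geometry] object.
#' @param rate_hz Sampling rate in Hz.
#' @param units `"px"` or `"deg"` — the units of the `x`/`y` columns.
#' @return An object of class `ipast_session`.
#' @export
ipast_session <- function(samples, trials, geometry, rate_hz, units = c("px", "deg")) {
  units <- match.arg(units)
  stopifnot(inherits(geometry, "screen_geometry"))
  samples <- as_tibble(samples)
  trials <- as_tibble(trials)
  need_s <- c("trial_id", "t_ms", "x", "y", "a", "valid")
  if (!all(need_s %in% names(samples))) {
    abort(paste("`samples` must have columns:", paste(need_s, collapse = ", ")))
  }
  need_t <- c("trial_id", "condition", "stim_side", "fix_on_ms", "fix_off_ms",
              "stim_on_ms", "trial_end_ms", "drift_segment", "not_marked")
  if (!all(need_t %in% names(trials))) {
    abort(paste("`trials` must have columns:", paste(need_t, collapse = ", ")))
  }
  if (any(samples$a < 0, na.rm = TRUE)) abort("pupil area `a` must be >= 0")
  structure(
    list(samples = samples, trials = trials, geometry = geometry,
         rate_hz = as.numeric(rate_hz), units = units),
    class = "ipast_session"
  )
}

#' @export
print.ipast_session <- function(x, ...) {
  cat(sprintf(
    "<ipast_session> %d trials, %d samples at %g Hz, gaze in %s\n",
    nrow(x$trials), nrow(x$samples), x$rate_hz, x$units
  ))
  if (any(x$trials$not_marked)) {
    cat(sprintf("  %d trial(s) flagged Not marked\n", sum(x$trials$not_marked)))
  }
  invisible(x)
}

# Sample step in ms.
session_step_ms <- function(session) 1000 / session$rate_hz

# Samples of one trial, ordered by time.
trial_samples <- function(session, id) {
  session$samples %>% filter(.data$trial_id == id) %>% arrange(.data$t_ms)
}
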