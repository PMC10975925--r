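#' Normalize pupil area to a fixed non-zero mean
#'
#' Raw pupil area (camera pixel counts) varies widely between people and
#' recordings. Each trial is rescaled so that the mean of its informative
#' samples — those with area above 10, excluding loss and near-loss values —
#' equals 300 arbitrary units: `a300 = a / mean(a[a > 10]) * 300`. Zeros
#' (data loss) stay zero.
#'
#' @param a Numeric vector of raw pupil area, `>= 0`.
#' @param floor Exclusion threshold for the mean (default 10).
#' @param target Target mean (default 300).
#' @return Normalized vector; all zeros (with a warning) when no sample
#'   exceeds `floor`, which marks a fully lost trial.
#' @examples
#' normalize_area(c(600, 600, 0, 600))  # 300 300 0 300
#' @export
normalize_area <- function(a, floor = 10, target = 300) {
  if (any(a < 0, na.rm = TRUE)) abort("pupil area must be >= 0")
  good <- a > floor & !is.na(a)
  if (!any(good)) {
    warn("no pupil sample above the floor; trial is fully lost")
    return(rep(0, length(a)))
  }
  out <- a / mean(a[good]) * target
  out[is.na(out)] <- 0
  out
}

#' Remove the low-frequency trend from normalized pupil area
#'
#' Builds a model of the slow (luminance/arousal-driven) modulation of the
#' normalized area and subtracts it, so that a fixed threshold can find
#' data-loss excursions regardless of slow drift. Steps: (1) the smoothed
#' per-step area velocity `svel` (3-point zero-phase boxcar of the central
#' difference); (2) a repaired copy of `a300` in which abnormal samples
#' (`|svel| > svel_thresh`, `a300 < area_low`, or `a300 > area_high`) are
#' replaced by linear interpolation between the flanking normal samples
#' (nearest-value extension at trial edges); (3) the repaired copy smoothed
#' with a large 50-point zero-phase boxcar is the trend model; (4)
#' `a_flat = a300 - model + 300`, re-centred so the fixed loss thresholds
#' of [detect_loss()] apply.
#'
#' @param a300 Normalized area from [normalize_area()].
#' @param rate_hz Sampling rate; the per-step velocity threshold is scaled
#'   by `500 / rate_hz` so it describes the same physical event at any rate.
#' @param svel_thresh Velocity threshold in units per step at 500 Hz.
#' @param area_low,area_high Normal-range bounds on `a300`.
#' @param model_w Trend-model smoothing width in samples.
#' @param svel_w Velocity smoothing width in samples.
#' @return List with `a_flat`, `svel`, and the trend `model`.
#' @export
flatten_area <- function(a300, rate_hz = 500, svel_thresh = 1000,
                         area_low = 200, area_high = 400,
                         model_w = 50, svel_w = 3) {
  thr <- svel_thresh * (500 / rate_hz)
  svel <- zero_phase_boxcar(central_velocity(a300, dt = 1), svel_w)
  bad <- abs(svel) > thr | a300 < area_low | a300 > area_high
  repaired <- interp_over(a300, bad)
  model <- zero_phase_boxcar(repaired, model_w)
  list(a_flat = a300 - model + 300, svel = svel, model = model)
}

# Replace TRUE-masked samples by linear interpolation between flanking
# unmasked samples; runs touching an edge are extended from the nearest
# unmasked value. All-masked input falls back to a flat 300.
interp_over <- function(v, bad) {
  if (!any(bad)) return(v)
  if (all(bad)) return(rep(300, length(v)))
  good_idx <- which(!bad)
  out <- v
  out[bad] <- approx(good_idx, v[good_idx], xout = which(bad), rule = 2)$y
  out
}

#' Detect data-loss intervals in flattened pupil area
#'
#' Data loss (blinks, tracker dropouts, lash interference) appears as
#' excursions of the flattened area outside the normal band. Maximal runs
#' with `a_flat < low` or `a_flat > high` are reported; runs separated by
#' less than `merge_gap_ms` are merged, bridging the flicker that borders a
#' single loss event.
#'
#' @param a_flat Flattened area from [flatten_area()].
#' @param rate_hz Sampling rate in Hz.
#' @param low,high Loss thresholds on the flattened area.
#' @param merge_gap_ms Runs closer than this are merged.
#' @return Tibble with `start`, `end` (sample indices, inclusive) and
#'   `tail` (`"low"`, `"high"`, or `"both"` — which side was crossed).
#' @export
detect_loss <- function(a_flat, rate_hz = 500, low = 250, high = 350,
                        merge_gap_ms = 20) {
  step <- 1000 / rate_hz
  lost <- a_flat < low | a_flat > high
  runs <- logical_runs(lost)
  if (!nrow(runs)) return(tibble(start = integer(), end = integer(), tail = character()))
  # merge runs separated by < merge_gap_ms
  merged <- runs[1, ]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap_ms <- (runs$start[k] - merged$end[nrow(merged)] - 1L) * step
      if (gap_ms < merge_gap_ms) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- bind_rows(merged, runs[k, ])
      }
    }
  }
  merged$tail <- vapply(seq_len(nrow(merged)), function(k) {
    seg <- a_flat[merged$start[k]:merged$end[k]]
    lo <- any(seg < low); hi <- any(seg > high)
    if (lo && hi) "both" else if (hi) "high" else "low"
  }, "")
  merged
}

#' Refine a loss interval to the full blink extent
#'
#' The eyelid occludes the pupil progressively, so the recorded area ramps
#' down before the tracker loses the pupil and wavers after it reacquires
#' it: the true blink outlasts the data loss. Using the smoothed absolute
#' area velocity (`savel`, 3-point zero-phase boxcar of `|central
#' difference of a300|`), a per-trial dynamic threshold (mean + 2.5 SD of
#' `savel` over quiescent samples at least `quiet_ms` away from any loss,
#' floored at 2 units/step at 500 Hz) is walked outward from each loss
#' bound while `savel` stays above threshold, up to `cap_ms` in each
#' direction.
#'
#' @param a300 Normalized area vector.
#' @param losses Loss tibble from [detect_loss()].
#' @param rate_hz Sampling rate in Hz.
#' @param quiet_ms Quiescence margin around losses for the noise estimate.
#' @param cap_ms Maximum extent extension on each side.
#' @param k_sd SD multiplier for the dynamic threshold.
#' @param floor_units Threshold floor in units per step at 500 Hz.
#' @return `losses` with added integer columns `blink_start`, `blink_end`
#'   (sample indices of the full extent).
#' @export
refine_blink_extent <- function(a300, losses, rate_hz = 500, quiet_ms = 50,
                                cap_ms = 100, k_sd = 2.5, floor_units = 2) {
  n <- length(a300)
  step <- 1000 / rate_hz
  if (!nrow(losses)) {
    losses$blink_start <- integer(); losses$blink_end <- integer()
    return(losses)
  }
  savel <- zero_phase_boxcar(abs(central_velocity(a300, dt = 1)), 3)
  margin <- ceiling(quiet_ms / step)
  near_loss <- rep(FALSE, n)
  for (k in seq_len(nrow(losses))) {
    lo <- max(1L, losses$start[k] - margin)
    hi <- min(n, losses$end[k] + margin)
    near_loss[lo:hi] <- TRUE
  }
  quiet <- savel[!near_loss]
  if (!length(quiet)) {
    warn("no quiescent samples; blink extents left at the loss bounds")
    losses$blink_start <- losses$start
    losses$blink_end <- losses$end
    return(losses)
  }
  thr <- max(mean(quiet) + k_sd * sd_or_zero(quiet), floor_units * (500 / rate_hz))
  cap <- ceiling(cap_ms / step)
  losses$blink_start <- vapply(seq_len(nrow(losses)), function(k) {
    i <- losses$start[k]
    lim <- max(1L, losses$start[k] - cap)
    while (i > lim && savel[i - 1L] > thr) i <- i - 1L
    i
  }, integer(1))
  losses$blink_end <- vapply(seq_len(nrow(losses)), function(k) {
    i <- losses$end[k]
    lim <- min(n, losses$end[k] + cap)
    while (i < lim && savel[i + 1L] > thr) i <- i + 1L
    i
  }, integer(1))
  losses
}

sd_or_zero <- function(v) if (length(v) > 1L) sd(v) else 0

#' Categorize a data-loss event by its full duration
#'
#' Blinks have stereotypical durations; much shorter losses are tracker
#' flicker and much longer ones are some other interference (e.g. looking
#' away from the camera, lash occlusion).
#'
#' @param duration_ms Full blink-extent duration(s) in ms.
#' @param min_ms,max_ms Blink duration band (defaults 50 and 500 ms).
#' @return Character vector: `"dropout"`, `"blink"`, or `"other_loss"`.
#' @export
categorize_loss <- function(duration_ms, min_ms = 50, max_ms = 500) {
  dplyr::case_when(
    duration_ms < min_ms ~ "dropout",
    duration_ms <= max_ms ~ "blink",
    TRUE ~ "other_loss"
  )
}

#' Detect and categorize blinks for every trial of a session
#'
#' Runs the full pupil-area chain per trial: [normalize_area()],
#' [flatten_area()], [detect_loss()], [refine_blink_extent()] and
#' [categorize_loss()]. A loss is `partial` when the flattened area left
#' the normal band without the raw area ever reaching zero (partial lid
#' occlusion or lash interference).
#'
#' @param session An [ipast_session].
#' @param config Pipeline configuration, see [oculopipe_config()]; only the
#'   `blink` block is used.
#' @return Tibble with one row per loss event: `trial_id`,
#'   `loss_start_ms`, `loss_end_ms`, `blink_start_ms`, `blink_end_ms`,
#'   `duration_ms`, `category`, `partial`, `tail`.
#' @export
detect_blinks <- function(session, config = oculopipe_config()) {
  stopifnot(inherits(session, "ipast_session"))
  cb <- config$blink
  rate <- session$rate_hz
  ids <- session$trials$trial_id
  proto <- tibble(
    trial_id = integer(), loss_start_ms = numeric(), loss_end_ms = numeric(),
    blink_start_ms = numeric(), blink_end_ms = numeric(),
    duration_ms = numeric(), category = character(), partial = logical(),
    tail = character()
  )
  rows <- map_dfr(ids, function(id) {
    ts <- trial_samples(session, id)
    if (nrow(ts) <= 3L * (cb$model_w - 1L)) return(NULL)
    a <- ts$a
    a300 <- suppressWarnings(normalize_area(a, floor = cb$norm_floor, target = cb$norm_target))
    fl <- flatten_area(a300, rate, cb$svel_thresh, cb$area_low, cb$area_high,
                       cb$model_w, cb$svel_w)
    losses <- detect_loss(fl$a_flat, rate, cb$flat_low, cb$flat_high, cb$merge_gap_ms)
    if (!nrow(losses)) return(NULL)
    losses <- refine_blink_extent(a300, losses, rate, cb$quiet_ms, cb$extent_cap_ms,
                                  cb$k_sd, cb$savel_floor)
    t_ms <- ts$t_ms
    step <- 1000 / rate
    tibble(
      trial_id = id,
      loss_start_ms = t_ms[losses$start],
      loss_end_ms = t_ms[losses$end],
      blink_start_ms = t_ms[losses$blink_start],
      blink_end_ms = t_ms[losses$blink_end],
      duration_ms = t_ms[losses$blink_end] - t_ms[losses$blink_start] + step,
      category = categorize_loss(t_ms[losses$blink_end] - t_ms[losses$blink_start] + step,
                                 cb$min_ms, cb$max_ms),
      partial = vapply(seq_len(nrow(losses)), function(k) {
        all(a[losses$start[k]:losses$end[k]] > 0)
      }, logical(1)),
      tail = losses$tail
    )
  })
  bind_rows(proto, rows)
}
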