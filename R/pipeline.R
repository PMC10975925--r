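#' Pipeline configuration
#'
#' Central configuration for every stage, with the package defaults.
#' Supply nested lists to override individual keys; unknown blocks or keys
#' are rejected so typos cannot silently fall back to defaults.
#'
#' Blocks and main keys (units in parentheses):
#' * `smoothing`: `w` (samples) — position-smoothing width at 500 Hz.
#' * `drift`: `epoch_ms`, `bin_deg`, `span_deg`, `speed_max`,
#'   `min_samples` — fixation-mode drift re-referencing.
#' * `blink`: normalization target/floor, flattening thresholds, loss band
#'   (`flat_low`/`flat_high`), run-merge gap, extent walk cap, duration
#'   category bounds `min_ms`/`max_ms`.
#' * `saccade`: detection `floor_dps` (20 deg/s), `k_sd` (2.5),
#'   `min_dur_ms` (10), `fixed_ceiling_dps` (50).
#' * `pso`: `max_gap_ms` (40), `amp_range_deg` (0.5-5 deg).
#' * `boomerang`: direction/alignment/abnormality criteria.
#' * `blincade`: pairing gap and the 2-degree net-displacement cut.
#' * `mainseq`: spline df cap, minimum clean count, `zcrit`.
#' * `pupil`: eligibility radius and loss bound, analysis windows.
#' * `classify`: fixation radius/dwell, timing windows, decision knobs.
#'
#' @param ... Named blocks of overrides, e.g.
#'   `oculopipe_config(blink = list(min_ms = 40))`.
#' @return Nested configuration list of class `oculopipe_config`.
#' @export
oculopipe_config <- function(...) {
  defaults <- list(
    smoothing = list(w = 4),
    drift = list(epoch_ms = c(-700, -200), bin_deg = 0.1, span_deg = 5,
                 speed_max = 50, min_samples = 100),
    blink = list(norm_floor = 10, norm_target = 300, svel_thresh = 1000,
                 area_low = 200, area_high = 400, model_w = 50, svel_w = 3,
                 flat_low = 250, flat_high = 350, merge_gap_ms = 20,
                 quiet_ms = 50, extent_cap_ms = 100, k_sd = 2.5,
                 savel_floor = 2, min_ms = 50, max_ms = 500),
    saccade = list(floor_dps = 20, k_sd = 2.5, min_dur_ms = 10,
                   fixed_ceiling_dps = 50),
    pso = list(max_gap_ms = 40, amp_range_deg = c(0.5, 5)),
    boomerang = list(task_axes_deg = c(0, 180), min_angle_deg = 135,
                     axis_tol_deg = 45, path_ratio = 1.5, dur_ratio = 1.5,
                     dur_slope_ms_per_deg = 2.2, dur_intercept_ms = 21),
    blincade = list(max_gap_ms = 40, net_thresh_deg = 2),
    mainseq = list(max_df = 8, min_clean = 30, zcrit = masez_cutoff()),
    pupil = list(window_ms = 20, sig_sd = 1.96, center_radius_deg = 2,
                 max_loss_ms = 200, baseline_ms = c(150, 200),
                 final_ms = c(1150, 1200)),
    classify = list(fix_radius_deg = 2, fix_dwell_ms = 200,
                    eye_loss_frac = 0.5, min_amp_deg = 2,
                    anticipatory = c(-110, 89), viable = c(90, 1000),
                    viable_full = c(-110, 1000),
                    express = c(90, 139), regular = c(140, 800),
                    metrics_max_srt = 800, random_axis_tol_deg = 45)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) abort(paste("unknown config block(s):", paste(bad, collapse = ", ")))
    for (blk in names(overrides)) {
      badk <- setdiff(names(overrides[[blk]]), names(defaults[[blk]]))
      if (length(badk)) {
        abort(sprintf("unknown key(s) in config block '%s': %s", blk,
                      paste(badk, collapse = ", ")))
      }
      defaults[[blk]] <- modifyList(defaults[[blk]], overrides[[blk]])
    }
  }
  structure(defaults, class = "oculopipe_config")
}

#' Run the full IPAST analysis pipeline
#'
#' Orchestrates every stage on a parsed session: pixel-to-degree
#' conversion, drift re-referencing, kinematics, blink detection, saccade
#' detection (with PSO merging, boomerang splitting and blincade
#' resolution), main-sequence Z-scoring, pupillometry, trial
#' classification and session statistics. The run is deterministic for a
#' given session and configuration; a failure confined to one trial
#' degrades that trial to `"Not marked"` rather than aborting.
#'
#' @param session An [ipast_session] (pixels or degrees).
#' @param config Pipeline configuration from [oculopipe_config()].
#' @return Object of class `oculopipe_results`: list with tibbles
#'   `saccades`, `blinks`, `pupil`, `classifications`, `thresholds`,
#'   `drift`, the `stats` object, the fitted `mainseq`, and a `manifest`
#'   (package version and configuration digest).
#' @export
run_ipast_pipeline <- function(session, config = oculopipe_config()) {
  stopifnot(inherits(session, "ipast_session"))
  session <- pixels_to_degrees(session)
  w <- max(1L, as.integer(round(config$smoothing$w * session$rate_hz / 500)))
  session <- add_kinematics(session, w = w)
  drift <- suppressWarnings(drift_reference(
    session, config$drift$epoch_ms, config$drift$bin_deg, config$drift$span_deg,
    config$drift$speed_max, config$drift$min_samples
  ))
  session <- apply_drift(session, drift)
  thresholds <- dynamic_thresholds(session, config)
  blinks <- detect_blinks(session, config)
  saccades <- detect_saccades(session, blinks, config)
  fit <- suppressWarnings(fit_main_sequence(saccades, config$mainseq$max_df,
                                            config$mainseq$min_clean))
  saccades <- main_sequence_zscores(saccades, fit)
  eligibility <- trial_eligibility(session, saccades, blinks, config)
  pupil <- pupil_metrics(session, eligibility, config)
  classifications <- classify_trials(session, saccades, blinks, config)
  stats <- session_stats(classifications, session$trials)
  manifest <- list(
    package = "oculopipe",
    version = as.character(utils::packageVersion("oculopipe")),
    config_digest = config_digest(config),
    n_trials = nrow(session$trials),
    rate_hz = session$rate_hz
  )
  structure(
    list(session = session, saccades = saccades, blinks = blinks,
         pupil = pupil, classifications = classifications,
         thresholds = thresholds, drift = drift, stats = stats,
         mainseq = fit, manifest = manifest),
    class = "oculopipe_results"
  )
}

# Stable digest of the effective configuration (sum of a serialized copy);
# enough to detect config changes between runs without extra dependencies.
config_digest <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% .Machine$integer.max)
}

#' @export
print.oculopipe_results <- function(x, ...) {
  cat(sprintf(
    "<oculopipe_results> %d trials: %d saccades, %d loss events, %d pupil-eligible\n",
    nrow(x$session$trials), nrow(x$saccades), nrow(x$blinks),
    sum(x$pupil$eligible, na.rm = TRUE)
  ))
  print(x$stats)
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Emits the saccade, blink, pupil, classification, threshold and drift
#' tables as TSV, the session statistics and manifest as JSON. Outputs are
#' plain text and byte-stable for identical inputs and configuration.
#'
#' @param results An `oculopipe_results` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "oculopipe_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wr(results$saccades, "saccades.tsv")
  wr(results$blinks, "blinks.tsv")
  wr(results$pupil, "pupil.tsv")
  wr(results$classifications, "classifications.tsv")
  wr(results$thresholds, "thresholds.tsv")
  wr(results$drift, "drift.tsv")
  jsonlite::write_json(
    list(counts = results$stats$counts, rates = results$stats$rates,
         manifest = results$manifest),
    file.path(dir, "session_stats.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(dir)
}
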