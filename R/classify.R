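#' Timing class of a saccadic reaction time
#'
#' SRT windows relative to stimulus onset: anticipatory saccades launch
#' before visual information could drive them (-110 to 89 ms); express
#' saccades occupy 90-139 ms; regular-latency saccades 140-800 ms; and
#' responses after 800 ms up to the 1000 ms classification bound are late
#' (they classify the trial but are excluded from latency summaries).
#' Anything earlier than -110 ms is a fixation-epoch movement
#' (`"fixation_break"`).
#'
#' @param srt_ms Numeric vector of SRTs in ms relative to STIM onset.
#' @return Character vector: `fixation_break`, `anticipatory`, `express`,
#'   `regular`, `late`, or `NA` beyond 1000 ms.
#' @examples
#' classify_srt(c(89, 90, 139, 140, 800, 801))
#' @export
classify_srt <- function(srt_ms) {
  dplyr::case_when(
    srt_ms < -110 ~ "fixation_break",
    srt_ms <= 89 ~ "anticipatory",
    srt_ms <= 139 ~ "express",
    srt_ms <= 800 ~ "regular",
    srt_ms <= 1000 ~ "late",
    TRUE ~ NA_character_
  )
}

#' The IPAST trial categories
#'
#' @return Character vector of the fourteen trial category names.
#' @export
ipast_categories <- function() {
  c("Not marked",
    "Correct Pro-Saccade", "Correct Anti-Saccade",
    "Pro-Saccade Direction Error", "Anti-Saccade Direction Error",
    "Anticipatory Correct Pro-Saccade", "Anticipatory Correct Anti-Saccade",
    "Anticipatory Pro-Saccade Direction Error",
    "Anticipatory Anti-Saccade Direction Error",
    "Fixation Break", "No Saccade", "Random Saccade",
    "Never Fixated", "Eye Loss")
}

#' First viable saccade of a trial
#'
#' The saccadic reaction time is taken from the first movement after (or
#' anticipating) the stimulus that could express the trial decision: a
#' record — blincades included, since the behaviour is real even when the
#' tracking was lost mid-flight — with amplitude of at least `min_amp_deg`,
#' launched from within `launch_radius_deg` of the fixation point, with
#' onset inside the viable window (-110 to 1000 ms). Earlier large
#' movements during fixation are handled as fixation breaks by
#' [classify_trial()].
#'
#' @param trial_saccades Saccade table rows for one trial, time-ordered.
#' @param min_amp_deg Minimum amplitude (deg).
#' @param launch_radius_deg Maximum start-point distance from fixation.
#' @param window_ms Length-2 viable onset window (ms relative to STIM).
#' @return One saccade row, or `NULL` if none qualifies.
#' @export
first_viable_saccade <- function(trial_saccades, min_amp_deg = 2,
                                 launch_radius_deg = 2,
                                 window_ms = c(-110, 1000)) {
  if (is.null(trial_saccades) || !nrow(trial_saccades)) return(NULL)
  v <- trial_saccades %>%
    arrange(.data$onset_ms) %>%
    filter(.data$amplitude >= min_amp_deg,
           sqrt(.data$start_x^2 + .data$start_y^2) <= launch_radius_deg,
           .data$onset_ms >= window_ms[1], .data$onset_ms <= window_ms[2])
  if (!nrow(v)) return(NULL)
  v[1, ]
}

# Direction of a saccade relative to the two horizontal task locations:
# "left", "right", or NA when > tol off both axes.
horizontal_direction <- function(angle, tol = 45) {
  if (angle_diff(angle, 0) <= tol) return("right")
  if (angle_diff(angle, 180) <= tol) return("left")
  NA_character_
}

#' Classify one IPAST trial
#'
#' Assigns exactly one behavioural category to a trial, in a fixed decision
#' order chosen so that rarer diagnoses cannot mask commoner ones:
#'
#' 1. *Eye Loss* — data loss over more than `eye_loss_frac` of the
#'    fixation-plus-response epoch;
#' 2. *Never Fixated* — gaze never within `fix_radius_deg` of fixation for
#'    a continuous `fix_dwell_ms` during the fixation period;
#' 3. *Fixation Break* — gaze left the fixation window before FIX offset
#'    and did not return before it (a transient break with return sets
#'    `lapse_flag` and the trial is defined by the subsequent behaviour);
#' 4. anticipatory window (-110 to 89 ms): *Anticipatory
#'    Correct/Direction-Error Pro/Anti-Saccade* by condition and direction;
#' 5. viable window (90 to 1000 ms): *Correct/Direction-Error
#'    Pro/Anti-Saccade*;
#' 6. *Random Saccade* — the first movement heads more than 45 degrees off
#'    both horizontal target axes;
#' 7. *No Saccade* — fixation held, no viable movement by 1000 ms.
#'
#' Unresolvable trials return the reserved `"Not marked"`.
#'
#' @param trial One row of `session$trials`.
#' @param ts The trial's samples (degrees, drift-corrected).
#' @param trial_saccades Saccade rows for the trial.
#' @param trial_blinks Blink rows for the trial.
#' @param config Pipeline configuration (`classify` block).
#' @return One-row tibble: `trial_id`, `category`, `first_viable_srt`,
#'   `lapse_flag`.
#' @export
classify_trial <- function(trial, ts, trial_saccades, trial_blinks,
                           config = oculopipe_config()) {
  cc <- config$classify
  id <- trial$trial_id
  out <- function(cat, srt = NA_real_, lapse = FALSE) {
    tibble(trial_id = id, category = cat, first_viable_srt = srt,
           lapse_flag = lapse)
  }
  if (isTRUE(trial$not_marked) || is.null(ts) || !nrow(ts)) return(out("Not marked"))

  resp_end <- cc$viable[2]
  epoch <- ts$t_ms >= trial$fix_on_ms & ts$t_ms <= resp_end
  if (!any(epoch)) return(out("Not marked"))
  lost <- ts$a == 0 | !ts$valid
  if (mean(lost[epoch]) > cc$eye_loss_frac) return(out("Eye Loss"))

  # fixation attainment during the FIX period
  step <- ts$t_ms[2] - ts$t_ms[1]
  dwell_n <- ceiling(cc$fix_dwell_ms / step)
  fix_idx <- which(ts$t_ms >= trial$fix_on_ms & ts$t_ms < trial$fix_off_ms)
  fix_idx <- fix_idx[!lost[fix_idx]]  # loss samples are neutral, not breaks
  if (!length(fix_idx)) return(out("Never Fixated"))
  inside <- sqrt(ts$x[fix_idx]^2 + ts$y[fix_idx]^2) <= cc$fix_radius_deg
  runs <- logical_runs(inside)
  attained <- nrow(runs) && any(runs$end - runs$start + 1L >= dwell_n)
  if (!attained) return(out("Never Fixated"))

  lapse <- FALSE
  first_dwell_end <- runs$end[which(runs$end - runs$start + 1L >= dwell_n)[1]]
  after <- inside[first_dwell_end:length(inside)]
  if (any(!after)) {
    # gaze left the window before FIX offset; did it return?
    if (!after[length(after)]) return(out("Fixation Break"))
    lapse <- TRUE
  }

  v <- first_viable_saccade(
    trial_saccades, cc$min_amp_deg, cc$fix_radius_deg, cc$viable_full
  )
  if (is.null(v)) return(out("No Saccade", lapse = lapse))
  srt <- v$onset_ms
  dir <- horizontal_direction(v$angle, cc$random_axis_tol_deg)
  if (is.na(dir)) return(out("Random Saccade", srt, lapse))
  toward <- dir == trial$stim_side
  pro <- trial$condition == "PRO"
  correct <- (pro && toward) || (!pro && !toward)

  if (srt >= cc$anticipatory[1] && srt <= cc$anticipatory[2]) {
    cat <- if (pro) {
      if (correct) "Anticipatory Correct Pro-Saccade" else "Anticipatory Pro-Saccade Direction Error"
    } else {
      if (correct) "Anticipatory Correct Anti-Saccade" else "Anticipatory Anti-Saccade Direction Error"
    }
    return(out(cat, srt, lapse))
  }
  if (srt >= cc$viable[1] && srt <= cc$viable[2]) {
    cat <- if (pro) {
      if (correct) "Correct Pro-Saccade" else "Pro-Saccade Direction Error"
    } else {
      if (correct) "Correct Anti-Saccade" else "Anti-Saccade Direction Error"
    }
    return(out(cat, srt, lapse))
  }
  out("No Saccade", lapse = lapse)
}

#' Classify every trial of a session
#'
#' Applies [classify_trial()] per trial with fault isolation: any error in
#' a single trial degrades that trial to `"Not marked"` instead of aborting
#' the session.
#'
#' @param session An [ipast_session] in degrees (drift-corrected).
#' @param saccades Saccade table.
#' @param blinks Blink table.
#' @param config Pipeline configuration.
#' @return Tibble: `trial_id`, `category`, `first_viable_srt`,
#'   `lapse_flag`.
#' @export
classify_trials <- function(session, saccades, blinks,
                            config = oculopipe_config()) {
  map_dfr(seq_len(nrow(session$trials)), function(i) {
    tr <- session$trials[i, ]
    tryCatch(
      classify_trial(
        tr, trial_samples(session, tr$trial_id),
        saccades %>% filter(.data$trial_id == tr$trial_id),
        blinks %>% filter(.data$trial_id == tr$trial_id),
        config
      ),
      error = function(e) {
        warn(sprintf("trial %d failed to classify (%s); Not marked",
                     tr$trial_id, conditionMessage(e)))
        tibble(trial_id = tr$trial_id, category = "Not marked",
               first_viable_srt = NA_real_, lapse_flag = FALSE)
      }
    )
  })
}

#' Session-level IPAST behaviour statistics
#'
#' Counts every category by condition and derives the headline rates:
#'
#' * `error_rate` — anti-saccade direction errors in the regular window
#'   divided by *all* anti-saccade trials (fixation breaks, anticipatory
#'   and non-compliance trials included in the denominator);
#' * `error_ratio` — the same errors divided by correct plus direction
#'   error anti trials only ("of the viable anti saccades made, how often
#'   did inhibition fail?");
#' * `non_compliance_rate` — No Saccade, Random Saccade and Never Fixated
#'   trials over all trials;
#' * `fixation_break_rate`, `anticipatory_rate` — over all trials.
#'
#' A zero denominator yields a missing rate.
#'
#' @param classifications Tibble from [classify_trials()].
#' @param trials The session's trial table (for conditions).
#' @return Object of class `ipast_session_stats`: list with `counts`
#'   (tibble condition x category) and `rates` (one-row tibble).
#' @export
session_stats <- function(classifications, trials) {
  joined <- classifications %>%
    left_join(trials %>% select("trial_id", "condition"), by = "trial_id")
  counts <- joined %>%
    dplyr::count(.data$condition, .data$category, name = "n")
  n_of <- function(cond, cat) {
    x <- counts %>% filter(.data$condition %in% cond, .data$category %in% cat)
    sum(x$n)
  }
  n_total <- nrow(joined)
  n_anti <- sum(joined$condition == "ANTI", na.rm = TRUE)
  err <- n_of("ANTI", "Anti-Saccade Direction Error")
  corr <- n_of("ANTI", "Correct Anti-Saccade")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  anticipatory_cats <- grep("^Anticipatory", ipast_categories(), value = TRUE)
  rates <- tibble(
    n_trials = n_total,
    error_rate = rate(err, n_anti),
    error_ratio = rate(err, corr + err),
    non_compliance_rate = rate(
      n_of(c("PRO", "ANTI"), c("No Saccade", "Random Saccade", "Never Fixated")),
      n_total),
    fixation_break_rate = rate(n_of(c("PRO", "ANTI"), "Fixation Break"), n_total),
    anticipatory_rate = rate(n_of(c("PRO", "ANTI"), anticipatory_cats), n_total)
  )
  structure(list(counts = counts, rates = rates), class = "ipast_session_stats")
}

#' @export
print.ipast_session_stats <- function(x, ...) {
  cat("<ipast_session_stats>\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat("\n")
  print(as.data.frame(x$rates), row.names = FALSE)
  invisible(x)
}

#' @export
autoplot.ipast_session_stats <- function(object, ...) {
  d <- object$counts
  d$category <- factor(d$category, levels = ipast_categories())
  ggplot(d, aes(x = .data$category, y = .data$n, fill = .data$condition)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "trials", title = "IPAST trial categories") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
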