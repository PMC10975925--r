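#' Round event timestamps to the sampling grid
#'
#' Event messages are logged asynchronously and need not fall on a sample
#' stamp. This rounds every event time to the nearest multiple of the sample
#' step (`1000 / rate_hz` ms), with exact half-step ties rounded down, so
#' events align deterministically with the eye data.
#'
#' @param events Numeric vector (possibly named) of event times in ms.
#' @param rate_hz Sampling rate in Hz.
#' @return Numeric vector of the same shape, each a multiple of the step.
#' @examples
#' round_events_to_rate(c(1003, 1004), 500)  # 1002, 1004 (tie rounds down)
#' round_events_to_rate(7, 250)              # 8
#' @export
round_events_to_rate <- function(events, rate_hz) {
  step <- 1000 / rate_hz
  step * ceiling(events / step - 0.5)
}

#' Repair a trial's timestamp grid
#'
#' Enforces a strictly increasing, uniform-step timestamp vector for one
#' trial's samples. Duplicated stamps are dropped (the first occurrence is
#' kept). Missing stamps inside gaps of at most `max_gap_ms` are restored by
#' linear interpolation of `x`, `y` and `a`; restored samples are marked
#' `valid = FALSE`. Gaps longer than `max_gap_ms` are treated as genuine
#' data loss rather than stamp glitches: the grid stamps are inserted with
#' the last observed gaze position held, `a = 0`, and `valid = FALSE`, so
#' downstream loss detection sees them.
#'
#' @param samples Tibble for one trial with columns `t_ms`, `x`, `y`, `a`,
#'   `valid`, with `t_ms` non-decreasing.
#' @param rate_hz Sampling rate in Hz.
#' @param max_gap_ms Longest gap (ms) that is repaired by interpolation.
#' @return Tibble with uniform `t_ms` (step `1000 / rate_hz`).
#' @export
repair_timestamps <- function(samples, rate_hz, max_gap_ms = 100) {
  step <- 1000 / rate_hz
  samples <- as_tibble(samples)
  if (is.unsorted(samples$t_ms)) abort("`t_ms` must be non-decreasing before repair")
  keep_extra <- setdiff(names(samples), c("t_ms", "x", "y", "a", "valid"))
  samples <- samples[!duplicated(samples$t_ms), , drop = FALSE]
  n <- nrow(samples)
  if (n < 2L) return(samples)
  grid <- seq(samples$t_ms[1], samples$t_ms[n], by = step)
  if (length(grid) == n && all(abs(grid - samples$t_ms) < 1e-9)) return(samples)

  have <- round((samples$t_ms - grid[1]) / step) + 1L
  out <- tibble(
    t_ms = grid,
    x = NA_real_, y = NA_real_, a = NA_real_,
    valid = FALSE
  )
  out$x[have] <- samples$x
  out$y[have] <- samples$y
  out$a[have] <- samples$a
  out$valid[have] <- samples$valid
  for (col in keep_extra) {
    v <- rep(samples[[col]][1], length(grid))
    v[have] <- samples[[col]]
    out[[col]] <- v
  }

  miss <- which(is.na(out$x))
  if (length(miss)) {
    runs <- logical_runs(seq_along(grid) %in% miss)
    for (k in seq_len(nrow(runs))) {
      i0 <- runs$start[k]; i1 <- runs$end[k]
      lo <- i0 - 1L; hi <- i1 + 1L  # flanking observed samples always exist
      gap_ms <- out$t_ms[hi] - out$t_ms[lo]
      idx <- i0:i1
      if (gap_ms <= max_gap_ms) {
        frac <- (out$t_ms[idx] - out$t_ms[lo]) / gap_ms
        out$x[idx] <- out$x[lo] + frac * (out$x[hi] - out$x[lo])
        out$y[idx] <- out$y[lo] + frac * (out$y[hi] - out$y[lo])
        out$a[idx] <- out$a[lo] + frac * (out$a[hi] - out$a[lo])
      } else {
        out$x[idx] <- out$x[lo]
        out$y[idx] <- out$y[lo]
        out$a[idx] <- 0
      }
    }
  }
  out
}

#' Default event-message patterns for the ASC dialect
#'
#' Maps canonical pipeline event names to regular expressions matched
#' against the text of `MSG` lines. Laboratories use different tag strings;
#' pass a modified copy to [read_session()] to adapt. Patterns for
#' `trial_start`, `condition` and `stim_side` must contain one capture
#' group.
#'
#' @return Named character vector of regular expressions.
#' @export
asc_event_patterns <- function() {
  c(
    trial_start = "^TRIALID\\s+(\\d+)",
    condition = "^TRIAL_CONDITION\\s+(PRO|ANTI)",
    stim_side = "^STIM_SIDE\\s+(left|right)",
    fix_on = "^FIX_?ON\\b",
    fix_off = "^FIX_?OFF\\b",
    stim_on = "^STIM_?ON\\b",
    trial_end = "^TRIAL_?END\\b"
  )
}

# ASC line types that are recognised but carry no information we use.
.asc_noise <- "^(\\*\\*|#|;|SFIX|EFIX|SSACC|ESACC|SBLINK|EBLINK|INPUT|BUTTON|START|END|PRESCALER|VPRESCALER|PUPIL|EVENTS|SAMPLES|MODE)"

#' Read a recorded session
#'
#' Parses a session from either an EyeLink-style ASC text export
#' (whitespace-delimited sample rows `time x y area`, event rows
#' `MSG <time> <text>`) or the package's tabular dialect (a directory
#' holding `samples.tsv` plus a `meta.json` sidecar, as written by
#' [write_session()]). Samples are split into trials at the trial start/end
#' messages, timestamps are repaired to a uniform grid
#' ([repair_timestamps()]), event stamps are rounded to the sampling rate
#' ([round_events_to_rate()]), and each trial's clock is re-zeroed at its
#' STIM onset.
#'
#' Trials missing a required event message are kept but flagged
#' `not_marked` (with a warning) so that one bad trial never aborts a
#' session; downstream classification reports them as `"Not marked"`.
#'
#' @param path File path (ASC) or directory path (table dialect).
#' @param dialect `"asc"` or `"table"`.
#' @param geometry A [screen_geometry]; for the table dialect the sidecar
#'   value is used when this is `NULL`.
#' @param rate_hz Sampling rate; for the table dialect the sidecar value is
#'   used when this is `NULL`.
#' @param patterns Event-name regular expressions, see
#'   [asc_event_patterns()].
#' @param drift_segment_trials Trials per drift-correction segment used to
#'   assign `drift_segment` ids.
#' @return An [ipast_session] with gaze in pixels.
#' @export
read_session <- function(path, dialect = c("asc", "table"), geometry = NULL,
                         rate_hz = 500, patterns = asc_event_patterns(),
                         drift_segment_trials = 40) {
  dialect <- match.arg(dialect)
  if (dialect == "table") {
    return(read_session_table(path))
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(geometry)) geometry <- screen_geometry()
  lines <- readLines(path, warn = FALSE)
  parse_asc_lines(lines, geometry, rate_hz, patterns, drift_segment_trials)
}

parse_asc_lines <- function(lines, geometry, rate_hz, patterns, drift_segment_trials) {
  empty <- ipast_session(
    samples = tibble(trial_id = integer(), t_ms = numeric(), x = numeric(),
                     y = numeric(), a = numeric(), valid = logical()),
    trials = tibble(trial_id = integer(), condition = character(),
                    stim_side = character(), fix_on_ms = numeric(),
                    fix_off_ms = numeric(), stim_on_ms = numeric(),
                    trial_end_ms = numeric(), drift_segment = integer(),
                    not_marked = logical()),
    geometry = geometry, rate_hz = rate_hz, units = "px"
  )
  lines_trim <- trimws(lines)
  nonblank <- which(nzchar(lines_trim))
  if (!length(nonblank)) return(empty)

  is_msg <- startsWith(lines_trim, "MSG")
  is_sample <- grepl("^[0-9]", lines_trim)
  is_noise <- grepl(.asc_noise, lines_trim)
  bad <- nonblank[!(is_msg[nonblank] | is_sample[nonblank] | is_noise[nonblank])]
  if (length(bad)) {
    abort(sprintf("unparseable line %d: %s", bad[1], lines[bad[1]]))
  }

  # samples: time x y area [...]; "." marks a lost coordinate
  sm_idx <- which(is_sample)
  samp <- NULL
  if (length(sm_idx)) {
    fields <- strsplit(lines_trim[sm_idx], "\\s+")
    nf <- lengths(fields)
    if (any(nf < 4L)) {
      i <- sm_idx[which(nf < 4L)[1]]
      abort(sprintf("unparseable line %d: %s", i, lines[i]))
    }
    num <- function(k) {
      v <- vapply(fields, `[[`, "", k)
      suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
    }
    samp <- tibble(t_raw = num(1), x = num(2), y = num(3), a = num(4))
    if (anyNA(samp$t_raw)) {
      i <- sm_idx[which(is.na(samp$t_raw))[1]]
      abort(sprintf("unparseable line %d: %s", i, lines[i]))
    }
    samp$valid <- !(is.na(samp$x) | is.na(samp$y) | is.na(samp$a))
    samp$a[is.na(samp$a)] <- 0
    # lost gaze coordinates: hold last observed position
    for (col in c("x", "y")) {
      v <- samp[[col]]
      if (anyNA(v)) {
        idx <- cummax(ifelse(is.na(v), 0L, seq_along(v)))
        v <- ifelse(idx == 0L, v[which(!is.na(v))[1]], v[pmax(idx, 1L)])
        samp[[col]] <- v
      }
    }
    samp$line <- sm_idx
  }

  msg_idx <- which(is_msg)
  msgs <- NULL
  if (length(msg_idx)) {
    mm <- stringr::str_match(lines_trim[msg_idx], "^MSG\\s+(\\d+)\\s+(.*)$")
    if (anyNA(mm[, 1])) {
      i <- msg_idx[which(is.na(mm[, 1]))[1]]
      abort(sprintf("unparseable line %d: %s", i, lines[i]))
    }
    msgs <- tibble(t_raw = as.numeric(mm[, 2]), text = mm[, 3], line = msg_idx)
  }
  if (is.null(msgs) || !any(grepl(patterns[["trial_start"]], msgs$text))) {
    return(empty)
  }

  t0 <- min(c(samp$t_raw, msgs$t_raw))  # file clock re-zeroed at first stamp
  if (!is.null(samp)) samp$t_raw <- samp$t_raw - t0
  msgs$t_raw <- msgs$t_raw - t0
  msgs$t_raw <- round_events_to_rate(msgs$t_raw, rate_hz)

  starts <- which(grepl(patterns[["trial_start"]], msgs$text))
  trials <- list(); all_samp <- list()
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    i1 <- if (k < length(starts)) starts[k + 1] - 1L else nrow(msgs)
    block <- msgs[i0:i1, ]
    tid <- as.integer(stringr::str_match(block$text[1], patterns[["trial_start"]])[, 2])
    grab <- function(name) {
      j <- which(grepl(patterns[[name]], block$text))
      if (!length(j)) return(NA)
      block$t_raw[j[1]]
    }
    grab_cap <- function(name) {
      j <- which(grepl(patterns[[name]], block$text))
      if (!length(j)) return(NA_character_)
      stringr::str_match(block$text[j[1]], patterns[[name]])[, 2]
    }
    ev <- c(fix_on = grab("fix_on"), fix_off = grab("fix_off"),
            stim_on = grab("stim_on"), trial_end = grab("trial_end"))
    condition <- grab_cap("condition")
    stim_side <- grab_cap("stim_side")
    not_marked <- anyNA(ev) || is.na(condition) || is.na(stim_side)
    if (not_marked) {
      warn(sprintf("trial %d is missing required event stamps; flagged Not marked", tid))
    }

    tr_start <- block$t_raw[1]
    tr_end <- if (!is.na(ev[["trial_end"]])) ev[["trial_end"]] else {
      if (k < length(starts)) msgs$t_raw[starts[k + 1]] else max(samp$t_raw)
    }
    ts <- samp[samp$t_raw >= tr_start & samp$t_raw <= tr_end, , drop = FALSE]
    zero <- if (!is.na(ev[["stim_on"]])) ev[["stim_on"]] else tr_start
    if (nrow(ts)) {
      ts <- tibble(trial_id = tid, t_ms = ts$t_raw - zero, x = ts$x, y = ts$y,
                   a = ts$a, valid = ts$valid)
      ts <- repair_timestamps(ts, rate_hz)
      all_samp[[k]] <- ts
    }
    trials[[k]] <- tibble(
      trial_id = tid, condition = condition, stim_side = stim_side,
      fix_on_ms = ev[["fix_on"]] - zero, fix_off_ms = ev[["fix_off"]] - zero,
      stim_on_ms = ev[["stim_on"]] - zero, trial_end_ms = ev[["trial_end"]] - zero,
      drift_segment = ((k - 1L) %/% drift_segment_trials) + 1L,
      not_marked = not_marked
    )
  }
  ipast_session(
    samples = bind_rows(all_samp), trials = bind_rows(trials),
    geometry = geometry, rate_hz = rate_hz, units = "px"
  )
}

#' Write a session in the tabular dialect
#'
#' Writes `samples.tsv` (long sample table) and `meta.json` (trial metadata,
#' screen geometry, rate, units) into `dir`. [read_session()] with
#' `dialect = "table"` reads it back; the round trip reproduces the session
#' exactly.
#'
#' @param session An [ipast_session].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ipast_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- session$samples
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, file.path(dir, "samples.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    trials = session$trials,
    geometry = unclass(session$geometry),
    rate_hz = session$rate_hz,
    units = session$units
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

read_session_table <- function(dir) {
  sfile <- file.path(dir, "samples.tsv")
  mfile <- file.path(dir, "meta.json")
  if (!file.exists(sfile) || !file.exists(mfile)) {
    abort(sprintf("table dialect expects %s and %s", sfile, mfile))
  }
  samples <- as_tibble(utils::read.table(sfile, header = TRUE, sep = "\t"))
  samples$valid <- as.logical(samples$valid)
  samples$trial_id <- as.integer(samples$trial_id)
  for (col in c("t_ms", "x", "y", "a")) samples[[col]] <- as.numeric(samples[[col]])
  meta <- jsonlite::read_json(mfile, simplifyVector = TRUE)
  trials <- as_tibble(meta$trials)
  trials$not_marked <- as.logical(trials$not_marked)
  geom <- do.call(screen_geometry, meta$geometry)
  ipast_session(samples, trials, geom, meta$rate_hz, units = meta$units)
}

#' Write a session as an ASC-style text export
#'
#' Emits the EyeLink-flavoured text dialect consumed by
#' [read_session()]: `MSG` rows for the task events and whitespace-delimited
#' `time x y area` sample rows (gaze in pixels). Used by the synthetic
#' generator so the reader is exercised end to end.
#'
#' @param session An [ipast_session] with gaze in pixels.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(session, path) {
  stopifnot(inherits(session, "ipast_session"))
  if (session$units != "px") abort("write_asc() expects gaze in pixels")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("** oculopipe ASC export", con)
  offset <- 10000  # arbitrary positive recorder clock origin
  step <- session_step_ms(session)
  for (i in seq_len(nrow(session$trials))) {
    tr <- session$trials[i, ]
    ts <- trial_samples(session, tr$trial_id)
    if (!nrow(ts)) next
    base <- offset - min(ts$t_ms)
    m <- function(t, text) sprintf("MSG %d %s", round(base + t), text)
    writeLines(c(
      m(min(ts$t_ms), sprintf("TRIALID %d", tr$trial_id)),
      m(min(ts$t_ms), sprintf("TRIAL_CONDITION %s", tr$condition)),
      m(min(ts$t_ms), sprintf("STIM_SIDE %s", tr$stim_side)),
      m(tr$fix_on_ms, "FIX_ON"),
      m(tr$fix_off_ms, "FIX_OFF"),
      m(tr$stim_on_ms, "STIM_ON")
    ), con)
    writeLines(sprintf("%d %.4f %.4f %.2f", round(base + ts$t_ms),
                       ts$x, ts$y, ts$a), con)
    writeLines(m(tr$trial_end_ms, "TRIAL_END"), con)
    offset <- base + tr$trial_end_ms + 500  # recorder pause between trials
  }
  invisible(path)
}
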