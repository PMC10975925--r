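#' Fit the main sequence with smoothing splines
#'
#' Saccades obey a stereotyped relation between amplitude, peak velocity
#' and duration (the main sequence). Two cross-sectional penalized cubic
#' smoothing splines are fitted per block — peak velocity against
#' amplitude, and peak velocity against duration — on the clean saccades
#' only (blincades, boomerang halves, and records with missing metrics are
#' excluded). Residual Z-scores from these fits ([main_sequence_zscores()])
#' rank how typical each saccade is for that participant and flag events
#' where the behaviour is real but the instantaneous tracking was fouled.
#'
#' The spline smoothness is constrained to at most `max_df` effective
#' degrees of freedom, giving a near-smooth monotone curve over the
#' amplitude range; the realized degrees of freedom are recorded in the
#' fit.
#'
#' @param saccades Saccade table from [detect_saccades()].
#' @param max_df Maximum effective degrees of freedom per spline.
#' @param min_clean Minimum number of clean saccades required; below this
#'   the fit is flagged unusable and Z-scores come back missing.
#' @return An object of class `oculo_mainseq`.
#' @export
fit_main_sequence <- function(saccades, max_df = 8, min_clean = 30) {
  clean <- saccades %>%
    filter(!.data$blincade, .data$boomerang_half == "none",
           is.finite(.data$amplitude), is.finite(.data$peak_velocity),
           is.finite(.data$duration_ms))
  obj <- structure(
    list(fit_amp = NULL, fit_dur = NULL, sigma_amp = NA_real_,
         sigma_dur = NA_real_, n_clean = nrow(clean), ok = FALSE,
         df_amp = NA_real_, df_dur = NA_real_),
    class = "oculo_mainseq"
  )
  if (nrow(clean) < min_clean) {
    warn(sprintf("only %d clean saccades (< %d); main-sequence fit skipped",
                 nrow(clean), min_clean))
    return(obj)
  }
  fit1 <- fit_capped_spline(clean$amplitude, clean$peak_velocity, max_df)
  fit2 <- fit_capped_spline(clean$duration_ms, clean$peak_velocity, max_df)
  if (is.null(fit1) || is.null(fit2)) return(obj)
  r1 <- clean$peak_velocity - predict(fit1, clean$amplitude)$y
  r2 <- clean$peak_velocity - predict(fit2, clean$duration_ms)$y
  obj$fit_amp <- fit1; obj$fit_dur <- fit2
  obj$sigma_amp <- sd_or_zero(r1); obj$sigma_dur <- sd_or_zero(r2)
  obj$df_amp <- fit1$df; obj$df_dur <- fit2$df
  obj$ok <- obj$sigma_amp > 0 && obj$sigma_dur > 0
  obj
}

fit_capped_spline <- function(x, y, max_df) {
  nu <- length(unique(x))
  if (nu < 4L) return(NULL)
  df <- min(max_df, nu - 1L)
  tryCatch(smooth.spline(x, y, df = df, cv = FALSE),
           error = function(e) NULL)
}

#' @export
print.oculo_mainseq <- function(x, ...) {
  if (!x$ok) {
    cat("<oculo_mainseq> unusable fit (", x$n_clean, "clean saccades )\n")
  } else {
    cat(sprintf(
      "<oculo_mainseq> %d clean saccades; residual SD %.1f (amplitude fit, df %.1f), %.1f (duration fit, df %.1f)\n",
      x$n_clean, x$sigma_amp, x$df_amp, x$sigma_dur, x$df_dur
    ))
  }
  invisible(x)
}

#' @export
tidy.oculo_mainseq <- function(x, ...) {
  tibble(
    term = c("peak_velocity ~ amplitude", "peak_velocity ~ duration"),
    edf = c(x$df_amp, x$df_dur),
    sigma = c(x$sigma_amp, x$sigma_dur)
  )
}

#' @export
glance.oculo_mainseq <- function(x, ...) {
  tibble(n_clean = x$n_clean, ok = x$ok,
         sigma_amp = x$sigma_amp, sigma_dur = x$sigma_dur)
}

#' Main-sequence residual Z-scores for every saccade
#'
#' Scores each record of the saccade table — including the flagged ones
#' that were excluded from the fit — against the block's main-sequence
#' splines: `masez = residual / SD(residuals of the clean fit set)` for
#' both the amplitude and the duration fit.
#'
#' @param saccades Saccade table.
#' @param fit An `oculo_mainseq` from [fit_main_sequence()]; fitted from
#'   `saccades` when `NULL`.
#' @return `saccades` with `masez_amp` and `masez_dur` filled in (missing
#'   when the block's fit was unusable).
#' @export
main_sequence_zscores <- function(saccades, fit = NULL) {
  if (is.null(fit)) fit <- fit_main_sequence(saccades)
  if (!fit$ok) {
    saccades$masez_amp <- NA_real_
    saccades$masez_dur <- NA_real_
    return(saccades)
  }
  saccades$masez_amp <-
    (saccades$peak_velocity - predict(fit$fit_amp, saccades$amplitude)$y) / fit$sigma_amp
  saccades$masez_dur <-
    (saccades$peak_velocity - predict(fit$fit_dur, saccades$duration_ms)$y) / fit$sigma_dur
  saccades
}

#' Critical Z for main-sequence exclusion
#'
#' Two-sided standard normal critical value at tail probability `p`;
#' at the default `p = 0.001` this is 3.29 (to two decimals), the cut used
#' when averaging saccade metrics.
#'
#' @param p Two-sided tail probability.
#' @return The critical value.
#' @examples
#' masez_cutoff()        # 3.2905
#' round(masez_cutoff(), 2)
#' @export
masez_cutoff <- function(p = 0.001) qnorm(1 - p / 2)

#' Filter a saccade table by main-sequence Z-scores
#'
#' Retains records whose amplitude- and duration-fit Z-scores are both
#' below the critical value in magnitude. Records with missing scores are
#' dropped.
#'
#' @param saccades Scored saccade table.
#' @param zcrit Critical value; default [masez_cutoff()].
#' @return Filtered tibble.
#' @export
filter_by_masez <- function(saccades, zcrit = masez_cutoff()) {
  if (is.infinite(zcrit)) return(saccades)
  saccades %>%
    filter(is.finite(.data$masez_amp), is.finite(.data$masez_dur),
           abs(.data$masez_amp) < zcrit, abs(.data$masez_dur) < zcrit)
}

#' @export
autoplot.oculo_mainseq <- function(object, saccades = NULL, ...) {
  if (!object$ok) abort("cannot plot an unusable main-sequence fit")
  grid <- tibble(amplitude = seq(min(object$fit_amp$x), max(object$fit_amp$x),
                                 length.out = 200))
  grid$peak_velocity <- predict(object$fit_amp, grid$amplitude)$y
  p <- ggplot(grid, aes(x = .data$amplitude, y = .data$peak_velocity))
  if (!is.null(saccades)) {
    p <- p + geom_point(data = saccades, alpha = 0.3)
  }
  p + geom_line(colour = "firebrick", linewidth = 1) +
    labs(x = "amplitude (deg)", y = "peak velocity (deg/s)",
         title = "Main sequence: smoothing-spline fit") +
    theme_minimal()
}
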