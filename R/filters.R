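#' Zero-phase boxcar (moving-average) filter
#'
#' Smooths a numeric vector by running a width-`w` moving average forward and
#' then backward over the data, which cancels the phase delay of the causal
#' filter. The input is padded with an odd (point-symmetric) reflection of
#' length `3 * (w - 1)` at each end before filtering and the padding is
#' trimmed afterwards, so edges are handled without transient artefacts.
#' The filter has unit DC gain: constant signals pass through unchanged, and
#' a linear ramp is unchanged in its interior.
#'
#' This is the single smoothing primitive used throughout the pipeline
#' (eye position, pupil-area velocity, trend models); only the width varies.
#'
#' @param x Numeric vector to smooth.
#' @param w Integer window width in samples (`w >= 1`). `w = 1` is the
#'   identity.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' zero_phase_boxcar(rep(5, 20), w = 5)      # constants preserved
#' zero_phase_boxcar(seq_len(20), w = 3)     # ramp interior unchanged
#' @export
zero_phase_boxcar <- function(x, w) {
  w <- as.integer(w)
  if (length(w) != 1L || is.na(w) || w < 1L) {
    abort("`w` must be a single integer >= 1.")
  }
  if (w == 1L) return(as.numeric(x))
  n <- length(x)
  pad <- 3L * (w - 1L)
  if (n <= pad) {
    abort(sprintf(
      "input too short for zero-phase filtering: length %d, need more than %d samples for w = %d",
      n, pad, w
    ))
  }
  x <- as.numeric(x)
  front <- 2 * x[1] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- c(front, x, back)
  y <- boxcar_causal(y, w)
  y <- rev(boxcar_causal(rev(y), w))
  y[(pad + 1L):(pad + n)]
}

# Causal moving average with zero initial state:
# y[i] = mean(x[max(1, i-w+1) .. i]) scaled as sum/w (matches an FIR filter
# b = ones(w)/w, a = 1 run from rest).
boxcar_causal <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  lagged <- c(rep(0, w), cs[seq_len(n - w)])
  (cs - lagged) / w
}

#' Central-difference velocity
#'
#' Differentiates a uniformly sampled position vector with a zero-phase
#' three-point central difference: interior samples use
#' `(x[i + 1] - x[i - 1]) / (2 * dt)`, and the first and last samples fall
#' back to a two-point forward/backward difference so the output has the
#' same length as the input.
#'
#' @param x Numeric vector of positions (e.g. degrees).
#' @param dt Sampling interval in seconds (e.g. `0.002` at 500 Hz). Use
#'   `dt = 1` to obtain per-sample-step differences.
#' @return Numeric velocity vector, `length(x)` long, in units of `x` per
#'   second (or per step when `dt = 1`).
#' @examples
#' central_velocity(c(0, 2, 4, 6), dt = 0.002)  # constant 1000 deg/s
#' @export
central_velocity <- function(x, dt) {
  n <- length(x)
  if (n < 2L) abort("`x` must have at least 2 samples to differentiate.")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) abort("`dt` must be a single positive number.")
  x <- as.numeric(x)
  v <- numeric(n)
  v[1L] <- x[2L] - x[1L]
  if (n > 2L) v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  v[n] <- x[n] - x[n - 1L]
  v / dt
}

#' Euclidean eye speed from component velocities
#'
#' @param vel_x,vel_y Numeric vectors of horizontal and vertical velocity
#'   (same length, same units).
#' @return Non-negative speed vector, `sqrt(vel_x^2 + vel_y^2)`.
#' @examples
#' euclidean_speed(300, 400)  # 500
#' @export
euclidean_speed <- function(vel_x, vel_y) {
  if (length(vel_x) != length(vel_y)) abort("`vel_x` and `vel_y` must have equal length.")
  sqrt(vel_x^2 + vel_y^2)
}

# Runs of TRUE in a logical vector -> tibble(start, end) of indices.
logical_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}

# Absolute angular difference in degrees, in [0, 180].
angle_diff <- function(a, b) {
  d <- abs(((a - b) %% 360 + 360) %% 360)
  ifelse(d > 180, 360 - d, d)
}
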