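#' Screen geometry for gaze-angle conversion
#'
#' Describes the display used during recording: pixel resolution, physical
#' size, and the eye-to-screen distance. These three quantities define the
#' pixel-to-degree mapping used by [pixels_to_degrees()].
#'
#' The defaults describe a 17-inch 5:4 LCD at 1280 x 1024 viewed from 60 cm,
#' a common laboratory arrangement.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_cm,height_cm Physical screen size in centimetres.
#' @param distance_cm Eye-to-screen distance in centimetres.
#' @return An object of class `screen_geometry` (a named list).
#' @examples
#' geom <- screen_geometry()
#' geom
#' @export
screen_geometry <- function(width_px = 1280L, height_px = 1024L,
                            width_cm = 33.8, height_cm = 27.0,
                            distance_cm = 60) {
  vals <- c(width_px, height_px, width_cm, height_cm, distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all screen geometry fields must be strictly positive and finite")
  }
  ppc_x <- width_px / width_cm
  ppc_y <- height_px / height_cm
  if (abs(ppc_x - ppc_y) / ppc_x > 0.10) {
    warn(sprintf(
      "pixels-per-cm differ by more than 10%% between axes (%.2f vs %.2f); check screen metrics",
      ppc_x, ppc_y
    ))
  }
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      width_cm = as.numeric(width_cm), height_cm = as.numeric(height_cm),
      distance_cm = as.numeric(distance_cm)
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, %.1f x %.1f cm, viewed at %.1f cm\n",
    x$width_px, x$height_px, x$width_cm, x$height_cm, x$distance_cm
  ))
  invisible(x)
}

# Horizontal px -> degrees of visual angle, origin at screen centre,
# rightward positive.
px_to_deg_x <- function(px, geom) {
  cm_per_px <- geom$width_cm / geom$width_px
  atan((px - geom$width_px / 2) * cm_per_px / geom$distance_cm) * 180 / pi
}

# Vertical px -> degrees; screen rows grow downward, so upward is positive.
px_to_deg_y <- function(px, geom) {
  cm_per_px <- geom$height_cm / geom$height_px
  atan((geom$height_px / 2 - px) * cm_per_px / geom$distance_cm) * 180 / pi
}

deg_to_px_x <- function(deg, geom) {
  cm_per_px <- geom$width_cm / geom$width_px
  geom$width_px / 2 + tan(deg * pi / 180) * geom$distance_cm / cm_per_px
}

deg_to_px_y <- function(deg, geom) {
  cm_per_px <- geom$height_cm / geom$height_px
  geom$height_px / 2 - tan(deg * pi / 180) * geom$distance_cm / cm_per_px
}

#' Convert gaze samples between pixels and degrees of visual angle
#'
#' `pixels_to_degrees()` maps the `x`/`y` sample columns of a session from
#' screen pixels to degrees of visual angle with the origin at the screen
#' centre (rightward/upward positive), using the per-axis mapping
#' `deg = atan((px - centre_px) * cm_per_px / distance_cm) * 180 / pi`.
#' `degrees_to_pixels()` is the exact inverse.
#'
#' @param session An [ipast_session] object.
#' @return The session with converted `x`/`y` columns and its `units` field
#'   updated.
#' @export
pixels_to_degrees <- function(session) {
  stopifnot(inherits(session, "ipast_session"))
  if (session$units == "deg") return(session)
  geom <- session$geometry
  if (geom$distance_cm <= 0) abort("viewing distance must be positive")
  session$samples <- session$samples %>%
    mutate(x = px_to_deg_x(.data$x, geom), y = px_to_deg_y(.data$y, geom))
  session$units <- "deg"
  session
}

#' @rdname pixels_to_degrees
#' @export
degrees_to_pixels <- function(session) {
  stopifnot(inherits(session, "ipast_session"))
  if (session$units == "px") return(session)
  geom <- session$geometry
  session$samples <- session$samples %>%
    mutate(x = deg_to_px_x(.data$x, geom), y = deg_to_px_y(.data$y, geom))
  session$units <- "px"
  session
}
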