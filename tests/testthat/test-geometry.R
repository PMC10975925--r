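test_that("pixel-to-degree conversion maps the screen centre to the origin", {
  geom <- screen_geometry()
  s <- make_quiet_trial()
  s$x <- rep(geom$width_px / 2, nrow(s))
  s$y <- rep(geom$height_px / 2, nrow(s))
  sess <- make_session(s, make_trial_row(), units = "px")
  out <- pixels_to_degrees(sess)
  expect_equal(out$samples$x, rep(0, nrow(s)))
  expect_equal(out$samples$y, rep(0, nrow(s)))
  expect_identical(out$units, "deg")
})

test_that("a point 10.58 cm right of centre at 60 cm is 10 degrees", {
  geom <- screen_geometry()
  px_per_cm <- geom$width_px / geom$width_cm
  px <- geom$width_px / 2 + 10.58 * px_per_cm
  s <- make_quiet_trial(); s$x <- rep(px, nrow(s))
  out <- pixels_to_degrees(make_session(s, make_trial_row(), units = "px"))
  expect_equal(out$samples$x[1], atan(10.58 / 60) * 180 / pi, tolerance = 1e-9)
  expect_equal(out$samples$x[1], 10, tolerance = 0.01)
})

test_that("symmetric pixels give equal-magnitude opposite-sign degrees and the mapping inverts", {
  geom <- screen_geometry()
  s <- make_quiet_trial()
  n <- nrow(s)
  set.seed(4)
  off <- runif(n, -300, 300)
  s$x <- geom$width_px / 2 + off
  s$y <- geom$height_px / 2 + off
  sess <- make_session(s, make_trial_row(), units = "px")
  deg <- pixels_to_degrees(sess)
  mirror <- sess
  mirror$samples$x <- geom$width_px / 2 - off
  deg_m <- pixels_to_degrees(mirror)
  expect_equal(deg$samples$x, -deg_m$samples$x, tolerance = 1e-12)
  # y: screen rows grow downward, so +off px is downward = negative degrees
  expect_true(all(sign(deg$samples$y[off != 0]) == -sign(off[off != 0])))
  back <- degrees_to_pixels(deg)
  expect_equal(back$samples$x, sess$samples$x, tolerance = 1e-9)
  expect_equal(back$samples$y, sess$samples$y, tolerance = 1e-9)
})

test_that("screen geometry validates its fields", {
  expect_error(screen_geometry(distance_cm = 0), "positive")
  expect_error(screen_geometry(width_px = -1), "positive")
  expect_warning(screen_geometry(width_cm = 60), "10%")
})
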