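test_that("zero-phase boxcar has unit DC gain and a symmetric impulse response", {
  for (w in c(2, 3, 5, 50)) {
    x <- rep(7.5, 200)
    expect_equal(zero_phase_boxcar(x, w), x, tolerance = 1e-12)
  }
  imp <- c(rep(0, 30), 1, rep(0, 30))
  for (w in c(3, 5)) {
    y <- zero_phase_boxcar(imp, w)
    expect_equal(sum(y), 1, tolerance = 1e-12)        # gain preserved
    expect_equal(y, rev(y), tolerance = 1e-12)        # zero phase
    expect_equal(which.max(y), 31L)                   # no shift
  }
})

test_that("zero-phase boxcar leaves a linear ramp unchanged and rejects short input", {
  ramp <- seq(0, 10, length.out = 50)
  expect_equal(zero_phase_boxcar(ramp, 3), ramp, tolerance = 1e-9)
  expect_error(zero_phase_boxcar(1:5, 3), "too short")
  expect_error(zero_phase_boxcar(numeric(0), 2), "too short")
  expect_identical(zero_phase_boxcar(c(1, 5, 2), 1), c(1, 5, 2))
})

test_that("zero-phase boxcar matches an independent forward-backward filter in the interior", {
  skip_if_not_installed("signal")
  set.seed(1)
  x <- cumsum(rnorm(300))
  for (w in c(3, 5, 10)) {
    ours <- zero_phase_boxcar(x, w)
    ref <- signal::filtfilt(rep(1, w) / w, 1, x)
    i <- 40:260  # away from the differing edge treatments
    expect_equal(ours[i], ref[i], tolerance = 1e-10)
  }
})

test_that("smoothing introduces no lag on band-limited signals", {
  s <- sin(2 * pi * (1:400) / 50)
  sm <- zero_phase_boxcar(s, 5)
  lags <- -5:5
  cc <- vapply(lags, function(L) cor(s[(6 + L):(395 + L)], sm[6:395]), 0)
  expect_identical(lags[which.max(cc)], 0L)
})

test_that("central-difference velocity follows the endpoint and interior rules", {
  expect_equal(central_velocity(c(0, 2, 4, 6), 0.002), rep(1000, 4))
  expect_equal(central_velocity(rep(3, 10), 0.002), rep(0, 10))
  expect_equal(central_velocity(c(0, 1), 0.002), c(500, 500))
  expect_error(central_velocity(1, 0.002), "at least 2")
  expect_error(central_velocity(1:5, 0), "positive")
})

test_that("differentiating the integral of a velocity profile recovers it to O(dt^2)", {
  dt <- 0.002
  t <- seq(0, 1, by = dt)
  pos <- -cos(2 * pi * t) / (2 * pi)   # integral of sin(2*pi*t)
  v_true <- sin(2 * pi * t)
  v <- central_velocity(pos, dt)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(v[interior] - v_true[interior])), (2 * pi * dt)^2)
})

test_that("euclidean speed combines components pointwise", {
  expect_equal(euclidean_speed(300, 400), 500)
  expect_equal(euclidean_speed(c(-7, 0), c(0, 0)), c(7, 0))
  expect_error(euclidean_speed(1:3, 1:2), "equal length")
})
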