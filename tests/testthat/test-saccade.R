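test_that("the dynamic threshold is mean + 2.5 SD of fixation noise, floored at 20", {
  set.seed(1)
  # noise with known mean/SD: use a fabricated two-point distribution
  noise1 <- rep(c(1, 9), 200)     # mean 5, sd ~4.0
  thr1 <- dynamic_threshold(noise1, rep(TRUE, 400))
  expect_equal(thr1$value, 20)    # 5 + 2.5*4 = 15 -> floored
  noise2 <- rep(c(2, 18), 200)    # mean 10, sd ~8.0
  thr2 <- dynamic_threshold(noise2, rep(TRUE, 400))
  expect_equal(thr2$value, 10 + 2.5 * sd(noise2), tolerance = 1e-9)
  expect_gt(thr2$value, 29.9)
  expect_warning(thr3 <- dynamic_threshold(numeric(0), logical(0)), "floor")
  expect_equal(thr3$value, 20)
  # samples at or above the 50 deg/s ceiling are excluded from the noise
  thr4 <- dynamic_threshold(c(noise1, rep(400, 50)), rep(TRUE, 450))
  expect_equal(thr4$value, 20)
})

test_that("candidate detection applies the 10 ms minimum duration", {
  speed <- rep(5, 200)
  speed[50:69] <- 100              # 40 ms lobe
  cand <- detect_candidates(speed, 20, 500)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$onset, 50)
  expect_equal(cand$offset, 70)    # first sub-threshold sample after the run
  spike <- rep(5, 200); spike[50:53] <- 100   # 8 ms = 4 samples
  expect_equal(nrow(detect_candidates(spike, 20, 500)), 0)
  two <- rep(5, 200); two[50:60] <- 100; two[100:110] <- 100
  expect_equal(nrow(detect_candidates(two, 20, 500)), 2)
})

test_that("on noise-free traces detection matches a brute-force threshold scan exactly", {
  # independent oracle: literal walk over samples
  brute <- function(speed, thr, min_run) {
    out <- NULL; i <- 1; n <- length(speed)
    while (i <= n) {
      if (speed[i] > thr) {
        j <- i
        while (j < n && speed[j + 1] > thr) j <- j + 1
        if (j - i + 1 >= min_run) out <- rbind(out, c(i, min(j + 1, n)))
        i <- j + 1
      }
      i <- i + 1
    }
    out
  }
  tau <- seq(0, 400, by = 2)
  for (amp in c(2, 5, 12)) {
    vp <- 500 * (1 - exp(-amp / 12))
    d <- 2 * amp / vp * 1000
    v <- ifelse(tau < 50 | tau > 50 + d, 0,
                vp * sin(pi * (tau - 50) / d)^2)
    cand <- detect_candidates(v, 20, 500)
    ref <- brute(v, 20, 5)
    expect_equal(as.integer(cand$onset), ref[, 1])
    expect_equal(as.integer(cand$offset), ref[, 2])
  }
})

test_that("PSO absorption follows the gap/amplitude rules and updates the endpoint", {
  fx <- fx_detection()
  sac <- fx$res$saccades
  merged <- sac[sac$pso_merged, ]
  expect_gt(nrow(merged), 50)
  # merged amplitude is the start -> PSO-end displacement by definition
  expect_equal(merged$amplitude,
               sqrt((merged$end_x - merged$start_x)^2 +
                      (merged$end_y - merged$start_y)^2),
               tolerance = 1e-9)
  expect_equal(merged$pso_end_ms, merged$offset_ms)
  expect_true(all(merged$core_offset_ms < merged$offset_ms))
})

test_that("a follower outside the merge window or amplitude band is not absorbed", {
  step <- 2; t_ms <- seq(0, 998, by = step)
  ts <- tibble::tibble(
    t_ms = t_ms, x_s = 0, y_s = 0,
    speed = rep(0, length(t_ms))
  )
  mk <- function(onset, offset, amp) {
    tibble::tibble(onset_ms = onset, offset_ms = offset,
                   duration_ms = offset - onset, start_x = 0, start_y = 0,
                   end_x = amp, end_y = 0, amplitude = amp, angle = 0,
                   peak_velocity = 300, peak_acceleration = 1e4,
                   onset_idx = onset / step + 1, offset_idx = offset / step + 1)
  }
  # gap 50 ms: not merged
  ev <- dplyr::bind_rows(mk(100, 160, 10), mk(210, 230, 1))
  out <- merge_pso(ev, ts, 0.002)
  expect_equal(nrow(out), 2)
  expect_false(any(out$pso_merged))
  # follower of 6 degrees: not merged
  ev2 <- dplyr::bind_rows(mk(100, 160, 10), mk(180, 220, 6))
  expect_equal(nrow(merge_pso(ev2, ts, 0.002)), 2)
  # qualifying follower: merged, offset extended
  ts$x_s <- approx(c(0, 100, 160, 180, 200, 998), c(0, 0, 10, 10, 9.2, 9.2),
                   xout = t_ms)$y
  ev3 <- dplyr::bind_rows(mk(100, 160, 10), mk(180, 200, 0.8))
  out3 <- merge_pso(ev3, ts, 0.002)
  expect_equal(nrow(out3), 1)
  expect_true(out3$pso_merged)
  expect_equal(out3$offset_ms, 200)
  expect_equal(out3$end_x, 9.2, tolerance = 1e-6)
  expect_equal(out3$core_offset_ms, 160)
})

test_that("opposed fused movements split at the speed nadir; ordinary saccades never do", {
  fx <- fx_boomerang()
  expect_gte(fx$score$boomerang$split_rate, 0.95)
  expect_equal(fx$score$boomerang$false_splits, 0)
  halves <- fx$res$saccades[fx$res$saccades$boomerang_half != "none", ]
  expect_gt(nrow(halves), 0)
  # halves of one trial move in opposite horizontal directions
  for (id in unique(halves$trial_id)) {
    h <- halves[halves$trial_id == id, ]
    if (nrow(h) == 2) {
      expect_lt(prod(h$end_x - h$start_x), 0)
    }
  }
  ord <- fx_ordinary()
  expect_gte(nrow(ord$res$saccades), 500)
  expect_equal(sum(ord$res$saccades$boomerang_half != "none"), 0)
  expect_gte(ord$score$saccades$recall, 0.98)
})

test_that("up-loss-down artefacts resolve to blinks (< 2 deg) or single blincades (>= 2 deg)", {
  n_blink_ok <- 0L
  n_blincade_ok <- 0L
  for (k in 1:10) {
    dx_small <- runif(1, 0, 1.5)
    s <- add_kinematics(make_artifact_session(dx_small, loss_ms = runif(1, 60, 140), seed = k))
    bl <- detect_blinks(s)
    sa <- suppressWarnings(detect_saccades(s, bl))
    n_blink_ok <- n_blink_ok +
      (nrow(sa) == 0 && nrow(attr(sa, "reclassified_blinks")) == 1)
    dx_big <- runif(1, 2.5, 9)
    s2 <- add_kinematics(make_artifact_session(dx_big, loss_ms = runif(1, 60, 140), seed = k + 100))
    bl2 <- detect_blinks(s2)
    sa2 <- suppressWarnings(detect_saccades(s2, bl2))
    n_blincade_ok <- n_blincade_ok +
      (nrow(sa2) == 1 && sa2$blincade[1] && abs(sa2$amplitude[1] - dx_big) < 1)
  }
  expect_equal(n_blink_ok, 10L)
  expect_equal(n_blincade_ok, 10L)
})

test_that("saccades with no loss overlap are never tagged blincade", {
  fx <- fx_detection()
  sac <- fx$res$saccades
  expect_false(any(sac$blincade))   # default blinks sit in the ITI
})
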