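test_that("a constant pupil trace yields a flat response with no onset", {
  s <- make_quiet_trial()
  s$a <- rep(500, nrow(s))
  sess <- add_kinematics(make_session(s, make_trial_row()))
  el <- trial_eligibility(sess, fx_empty_saccades(), empty_blinks())
  expect_true(el$eligible)
  pm <- pupil_metrics(sess, el)
  expect_equal(pm$baseline, 500)
  expect_equal(pm$constriction_amount, 0)
  expect_true(is.na(pm$onset_latency))
})

test_that("eligibility reports reasons for movement, off-centre gaze and loss", {
  s <- make_quiet_trial()
  sess <- add_kinematics(make_session(s, make_trial_row()))
  sac <- make_saccade_row(onset_ms = -600, amplitude = 5)
  el <- trial_eligibility(sess, sac, empty_blinks())
  expect_false(el$eligible)
  expect_match(el$reason, "saccade>2deg")

  s2 <- make_quiet_trial()
  s2$x <- s2$x + 4
  el2 <- trial_eligibility(add_kinematics(make_session(s2, make_trial_row())),
                           fx_empty_saccades(), empty_blinks())
  expect_match(el2$reason, "off_center")

  s3 <- make_quiet_trial()
  s3$a[s3$t_ms >= -800 & s3$t_ms < -550] <- 0   # 250 ms loss in FIX
  el3 <- trial_eligibility(add_kinematics(make_session(s3, make_trial_row())),
                           fx_empty_saccades(), empty_blinks())
  expect_match(el3$reason, "loss>=200ms")
})

test_that("metric identities hold exactly and metrics are homogeneous in raw area", {
  fx <- fx_pupil()
  pm <- fx$res$pupil[fx$res$pupil$eligible, ]
  expect_gt(nrow(pm), 100)
  expect_equal(pm$dilation_amount + pm$min_size, pm$final_size, tolerance = 1e-9)
  expect_equal(pm$baseline - pm$constriction_amount, pm$min_size, tolerance = 1e-9)
  expect_true(all(pm$onset_latency < pm$max_constriction_time, na.rm = TRUE))

  sess <- fx$res$session
  scaled <- sess
  scaled$samples$a <- scaled$samples$a * 3
  el <- trial_eligibility(scaled, fx$res$saccades, fx$res$blinks)
  pm3 <- pupil_metrics(scaled, el)
  m <- dplyr::inner_join(pm, pm3, by = "trial_id", suffix = c("_1", "_3"))
  expect_equal(m$baseline_3, 3 * m$baseline_1, tolerance = 1e-9)
  expect_equal(m$constriction_amount_3, 3 * m$constriction_amount_1, tolerance = 1e-9)
  expect_equal(m$max_constriction_time_3, m$max_constriction_time_1)
})

test_that("commanded pupil parameters are recovered from eligible trials", {
  fx <- fx_pupil()
  pm <- fx$res$pupil[fx$res$pupil$eligible, ]
  expect_gte(nrow(pm), 200)
  expect_lt(abs(mean(pm$constriction_amount) - 80), 2)
  expect_lt(abs(mean(pm$dilation_amount) - 40), 2)
  expect_lt(abs(mean(pm$max_constriction_time) - 600), 10)
  expect_lt(abs(mean(pm$onset_latency, na.rm = TRUE) - 250), 20)
  expect_true(all(pm$max_constriction_velocity < 0, na.rm = TRUE))
  expect_true(all(pm$max_dilation_velocity > 0, na.rm = TRUE))
})
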