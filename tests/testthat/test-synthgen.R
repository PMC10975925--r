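test_that("identical seed and config give bit-identical sessions", {
  cfg <- generator_config(n_trials = 10, seed = 31)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$session$samples, b$session$samples)
  expect_identical(a$truth$saccades, b$truth$saccades)
  expect_identical(a$truth$trials, b$truth$trials)
  c <- simulate_session(generator_config(n_trials = 10, seed = 32))
  expect_false(identical(a$session$samples$x, c$session$samples$x))
})

test_that("with slosh disabled, merged and threshold-only endpoints agree within noise", {
  sim <- simulate_session(generator_config(n_trials = 40, seed = 14, slosh_gain = 0))
  res <- suppressWarnings(run_ipast_pipeline(sim$session))
  sc <- score_detection(res$saccades, res$blinks, sim$truth)
  expect_lt(abs(sc$saccades$end_err_merged - sc$saccades$end_err_core), 0.05)
})

test_that("boomerang probability one labels an opposed pair on every responding ANTI trial", {
  sim <- simulate_session(generator_config(
    n_trials = 30, seed = 15, boomerang_prob = 1,
    behavior_probs = c(correct = 0.9, direction_error = 0.1, anticipatory = 0,
                       fixation_break = 0, no_saccade = 0, random = 0,
                       never_fixated = 0, eye_loss = 0)
  ))
  anti <- sim$truth$trials$trial_id[sim$truth$trials$condition == "ANTI"]
  pairs <- sim$truth$saccades[!is.na(sim$truth$saccades$pair_id), ]
  expect_setequal(unique(pairs$trial_id), anti)
  for (id in anti) {
    p <- pairs[pairs$trial_id == id, ]
    expect_equal(nrow(p), 2)
    expect_equal(abs(p$dir_deg[1] - p$dir_deg[2]), 180)
  }
})

test_that("every labelled event lies within its trial's time span", {
  fx <- fx_detection()
  tl <- ipast_timeline()
  ts <- fx$sim$truth$saccades
  expect_true(all(ts$onset_ms > tl$iti_start_ms & ts$offset_ms < tl$trial_end_ms))
  tb <- fx$sim$truth$blinks
  expect_true(all(tb$blink_start_ms > tl$iti_start_ms &
                    tb$blink_end_ms < tl$trial_end_ms))
})

test_that("scoring counts matches, misses and spurious detections correctly", {
  truth <- list(
    saccades = tibble::tibble(
      trial_id = c(1L, 1L, 2L), onset_ms = c(100, 300, 200),
      amp = c(10, 5, 8), end_x = c(10, 5, 8), end_y = 0, pair_id = NA_integer_,
      signal_offset_ms = c(160, 360, 260)
    ),
    blinks = tibble::tibble(trial_id = integer(), loss_start_ms = numeric(),
                            loss_end_ms = numeric())
  )
  det_row <- function(id, onset, amp) {
    tibble::tibble(trial_id = id, onset_ms = onset, amplitude = amp,
                   end_x = amp, end_y = 0, core_end_x = amp, core_end_y = 0,
                   start_x = 0, start_y = 0, blincade = FALSE,
                   boomerang_half = "none")
  }
  perfect <- dplyr::bind_rows(det_row(1L, 101, 10), det_row(1L, 299, 5),
                              det_row(2L, 200, 8))
  no_blinks <- empty_blinks()
  sc <- score_detection(perfect, no_blinks, truth)
  expect_equal(sc$saccades$recall, 1)
  expect_equal(sc$saccades$precision, 1)

  sc0 <- score_detection(perfect[0, ], no_blinks, truth)
  expect_equal(sc0$saccades$recall, 0)

  spurious <- dplyr::bind_rows(perfect, det_row(2L, 700, 6))
  sc1 <- score_detection(spurious, no_blinks, truth)
  expect_equal(sc1$saccades$recall, 1)
  expect_equal(sc1$saccades$precision, 3 / 4)
})

test_that("generator configs are validated", {
  expect_error(generator_config(behavior_probs = c(correct = 0.5)), "sum to 1")
  expect_error(generator_config(boomerang_prob = 2))
  expect_error(simulate_session(generator_config(amplitude_range = c(2, 60))),
               "implausibly large")
})
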