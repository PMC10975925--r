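test_that("SRT timing windows honour their boundaries exactly", {
  expect_identical(classify_srt(c(-111, -110, 89, 90, 139, 140, 800, 801, 1000, 1001)),
                   c("fixation_break", "anticipatory", "anticipatory", "express",
                     "express", "regular", "regular", "late", "late", NA))
})

test_that("the first viable saccade obeys the amplitude, launch and window rules", {
  tab <- dplyr::bind_rows(
    make_saccade_row(onset_ms = 120, amplitude = 10),
    make_saccade_row(onset_ms = 300, amplitude = 10)
  )
  expect_equal(first_viable_saccade(tab)$onset_ms, 120)
  small <- make_saccade_row(onset_ms = 150, amplitude = 1)
  expect_null(first_viable_saccade(small))
  far <- make_saccade_row(onset_ms = 150, amplitude = 10, start_x = 6)
  expect_null(first_viable_saccade(far))
  early <- make_saccade_row(onset_ms = -400, amplitude = 10)
  expect_null(first_viable_saccade(early))
  blinc <- make_saccade_row(onset_ms = 200, amplitude = 5, blincade = TRUE)
  expect_equal(first_viable_saccade(blinc)$onset_ms, 200)   # blincades count
})

test_that("trials are classified by condition, direction and timing window", {
  ts <- make_quiet_trial()
  cases <- list(
    list(cond = "PRO", side = "right", srt = 120, angle = 0,
         want = "Correct Pro-Saccade"),
    list(cond = "ANTI", side = "right", srt = 150, angle = 0,
         want = "Anti-Saccade Direction Error"),
    list(cond = "ANTI", side = "right", srt = -50, angle = 180,
         want = "Anticipatory Correct Anti-Saccade"),
    list(cond = "ANTI", side = "left", srt = 89, angle = 0,
         want = "Anticipatory Correct Anti-Saccade"),
    list(cond = "ANTI", side = "left", srt = 90, angle = 0,
         want = "Correct Anti-Saccade"),
    list(cond = "PRO", side = "left", srt = 300, angle = 180,
         want = "Correct Pro-Saccade"),
    list(cond = "PRO", side = "left", srt = 300, angle = 0,
         want = "Pro-Saccade Direction Error"),
    list(cond = "PRO", side = "right", srt = 250, angle = 90,
         want = "Random Saccade"),
    list(cond = "PRO", side = "right", srt = 1000, angle = 0,
         want = "Correct Pro-Saccade"),
    list(cond = "PRO", side = "right", srt = 1001, angle = 0,
         want = "No Saccade")
  )
  for (cs in cases) {
    tr <- make_trial_row(condition = cs$cond, stim_side = cs$side)
    sac <- make_saccade_row(onset_ms = cs$srt, angle = cs$angle)
    got <- classify_trial(tr, ts, sac, empty_blinks())
    expect_identical(got$category, cs$want)
  }
  # no saccade at all, fixation held
  got <- classify_trial(make_trial_row(), ts, fx_empty_saccades(), empty_blinks())
  expect_identical(got$category, "No Saccade")
})

test_that("loss and fixation failures take precedence, in order", {
  tr <- make_trial_row()
  lost <- make_quiet_trial()
  lost$a[lost$t_ms >= -1200] <- 0
  got <- classify_trial(tr, lost, fx_empty_saccades(), empty_blinks())
  expect_identical(got$category, "Eye Loss")

  away <- make_quiet_trial()
  away$x <- away$x + 6
  got2 <- classify_trial(tr, away, fx_empty_saccades(), empty_blinks())
  expect_identical(got2$category, "Never Fixated")

  broke <- make_quiet_trial()
  broke$x[broke$t_ms >= -600] <- 6    # leaves FIX window, never returns
  got3 <- classify_trial(tr, broke, fx_empty_saccades(), empty_blinks())
  expect_identical(got3$category, "Fixation Break")

  lapse <- make_quiet_trial()
  lapse$x[lapse$t_ms >= -700 & lapse$t_ms < -500] <- 6   # out and back
  sac <- make_saccade_row(onset_ms = 150)
  got4 <- classify_trial(make_trial_row(condition = "PRO", stim_side = "right"),
                         lapse, sac, empty_blinks())
  expect_identical(got4$category, "Correct Pro-Saccade")
  expect_true(got4$lapse_flag)
})

test_that("session statistics reproduce the rate and ratio definitions", {
  cls <- tibble::tibble(
    trial_id = 1:60,
    category = c(rep("Correct Anti-Saccade", 40),
                 rep("Anti-Saccade Direction Error", 10),
                 rep("Fixation Break", 10)),
    first_viable_srt = 200, lapse_flag = FALSE
  )
  trials <- tibble::tibble(trial_id = 1:60, condition = "ANTI")
  st <- session_stats(cls, trials)
  expect_equal(st$rates$error_ratio, 0.200)
  expect_equal(st$rates$error_rate, 10 / 60, tolerance = 1e-9)
  expect_equal(st$rates$error_rate, 0.1667, tolerance = 5e-4)
  expect_equal(st$rates$non_compliance_rate, 0)
  expect_equal(st$rates$fixation_break_rate, 10 / 60)
  expect_equal(sum(st$counts$n), 60)
})

test_that("zero denominators give missing rates and zero errors give zero", {
  cls <- tibble::tibble(trial_id = 1:5, category = rep("Correct Pro-Saccade", 5),
                        first_viable_srt = 200, lapse_flag = FALSE)
  trials <- tibble::tibble(trial_id = 1:5, condition = "PRO")
  st <- session_stats(cls, trials)
  expect_true(is.na(st$rates$error_rate))      # no ANTI trials at all
  expect_equal(st$rates$non_compliance_rate, 0)

  cls2 <- tibble::tibble(trial_id = 1:4, category = rep("Correct Anti-Saccade", 4),
                         first_viable_srt = 200, lapse_flag = FALSE)
  st2 <- session_stats(cls2, tibble::tibble(trial_id = 1:4, condition = "ANTI"))
  expect_equal(st2$rates$error_rate, 0)
  expect_equal(st2$rates$error_ratio, 0)
})

test_that("every trial gets exactly one category and the ratio dominates the rate", {
  fx <- fx_classify()
  cls <- fx$res$classifications
  expect_equal(nrow(cls), 1000)
  expect_equal(length(unique(cls$trial_id)), 1000)
  expect_true(all(cls$category %in% ipast_categories()))
  st <- fx$res$stats
  expect_equal(sum(st$counts$n), 1000)
  expect_gte(st$rates$error_ratio, st$rates$error_rate)
})
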