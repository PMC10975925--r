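test_that("pupil-area normalization fixes the informative mean at 300", {
  expect_equal(normalize_area(c(600, 600, 0, 600)), c(300, 300, 0, 300))
  expect_equal(normalize_area(rep(300, 5)), rep(300, 5))
  # values at or below 10 are excluded from the mean but still rescaled
  expect_equal(normalize_area(c(5, 600, 600)), c(2.5, 300, 300))
  expect_warning(out <- normalize_area(c(0, 3, 9)), "fully lost")
  expect_equal(out, c(0, 0, 0))
  expect_error(normalize_area(c(-1, 500)), ">= 0")
})

test_that("the informative mean of normalized area is exactly 300 on every simulated trial", {
  fx <- fx_detection()
  sess <- fx$sim$session
  for (id in sess$trials$trial_id[1:25]) {
    a <- sess$samples$a[sess$samples$trial_id == id]
    good <- a > 10
    a300 <- suppressWarnings(normalize_area(a))
    if (any(good)) {
      expect_equal(mean(a300[good]), 300, tolerance = 1e-6)
    }
  }
})

test_that("flattening removes slow drift and is stable on already-flat input", {
  flat <- flatten_area(rep(300, 400))
  expect_equal(flat$a_flat, rep(300, 400), tolerance = 1e-9)
  t <- seq_len(1600)
  drifting <- 300 + 40 * sin(2 * pi * t / 1600)
  f1 <- flatten_area(drifting)
  expect_true(all(abs(f1$a_flat - 300) < 5))
  f2 <- flatten_area(f1$a_flat)
  expect_equal(f2$a_flat, f1$a_flat, tolerance = 1.5)
})

test_that("a dip to zero inside drift is the only excursion past the loss threshold", {
  t <- seq_len(1600)
  a <- 300 + 40 * sin(2 * pi * t / 1600)
  dip <- t >= 800 & t < 850   # 100 ms at 500 Hz
  a[dip] <- 0
  f <- flatten_area(a)
  below <- which(f$a_flat < 250)
  expect_true(length(below) > 0)
  expect_true(all(below >= 790 & below <= 865))
})

test_that("loss detection reports maximal runs and merges near-adjacent ones", {
  expect_equal(nrow(detect_loss(rep(300, 100))), 0)
  a <- rep(300, 500); a[100:129] <- 100   # 60 ms dip
  runs <- detect_loss(a)
  expect_equal(nrow(runs), 1)
  expect_lte(abs((runs$end - runs$start + 1) - 30), 1)
  expect_identical(runs$tail, "low")
  b <- rep(300, 500); b[100:120] <- 100; b[125:145] <- 400  # 8 ms apart
  m <- detect_loss(b)
  expect_equal(nrow(m), 1)
  expect_identical(m$tail, "both")
})

test_that("extent refinement absorbs area ramps but not instantaneous edges", {
  sq <- rep(300, 600); sq[200:260] <- 0
  runs <- detect_loss(sq)
  ref <- refine_blink_extent(sq, runs)
  # the smoothed-derivative support spreads an instantaneous edge over
  # +/- 3 samples; the cap rule prevents any further expansion
  expect_lte(abs(ref$blink_start - runs$start), 3)
  expect_lte(abs(ref$blink_end - runs$end), 3)
})

test_that("loss categories follow the duration bounds", {
  expect_identical(categorize_loss(c(20, 150, 2000)),
                   c("dropout", "blink", "other_loss"))
  expect_identical(categorize_loss(c(50, 500)), c("blink", "blink"))
  expect_identical(categorize_loss(49.9), "dropout")
})

test_that("generator blinks are detected with full extents containing the loss", {
  fx <- fx_detection()
  sc <- fx$score$blinks
  expect_gte(sc$recall, 0.98)
  expect_gte(sc$precision, 0.98)
  expect_equal(sc$containment, 1)
  # full duration ~ loss + 2 x 30 ms ramps
  one_per_trial <- function(d) {
    d <- dplyr::add_count(d, trial_id)
    d[d$n == 1, setdiff(names(d), "n")]
  }
  tb <- one_per_trial(fx$sim$truth$blinks)
  db <- one_per_trial(fx$res$blinks[fx$res$blinks$category == "blink", ])
  m <- dplyr::inner_join(tb, db, by = "trial_id", suffix = c("_t", "_d"))
  expect_gt(nrow(m), 10)
  dur_t <- m$loss_end_ms_t - m$loss_start_ms_t + 60
  dur_d <- m$blink_end_ms_d - m$blink_start_ms_d
  expect_lt(median(abs(dur_d - dur_t)), 6)
})
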