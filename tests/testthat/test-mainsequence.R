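make_mainseq_table <- function(n = 200, seed = 1, sigma = 10) {
  set.seed(seed)
  amp <- runif(n, 2, 15)
  dur <- 2.2 * amp + 21 + rnorm(n, 0, 1)
  pv <- 500 * (1 - exp(-amp / 12)) + rnorm(n, 0, sigma)
  tibble::tibble(
    trial_id = seq_len(n), amplitude = amp, duration_ms = dur,
    peak_velocity = pv, blincade = FALSE, boomerang_half = "none"
  )
}

test_that("the exclusion cut-off is the two-sided normal critical value at p = 0.001", {
  expect_equal(round(masez_cutoff(), 2), 3.29)
  expect_equal(masez_cutoff(), qnorm(0.9995))
  expect_equal(masez_cutoff(0.05), qnorm(0.975))
})

test_that("a record on the fitted curve scores zero; a planted outlier scores its SD distance", {
  tab <- make_mainseq_table(300, seed = 2)
  fit <- fit_main_sequence(tab)
  expect_true(fit$ok)
  expect_lte(fit$df_amp, 8.05)
  on_curve <- tibble::tibble(
    trial_id = 0L, amplitude = 8,
    duration_ms = 2.2 * 8 + 21,
    peak_velocity = predict(fit$fit_amp, 8)$y,
    blincade = FALSE, boomerang_half = "none"
  )
  scored <- main_sequence_zscores(dplyr::bind_rows(tab, on_curve), fit)
  expect_equal(scored$masez_amp[nrow(scored)], 0, tolerance = 1e-9)

  outlier <- on_curve
  outlier$peak_velocity <- outlier$peak_velocity + 5 * fit$sigma_amp
  scored2 <- main_sequence_zscores(dplyr::bind_rows(tab, outlier), fit)
  expect_equal(scored2$masez_amp[nrow(scored2)], 5, tolerance = 0.2)
})

test_that("flagged records are excluded from the fit but still receive Z-scores", {
  tab <- make_mainseq_table(120, seed = 3)
  # a blincade far off the curve must not drag the fit
  bad <- tibble::tibble(trial_id = 0L, amplitude = 8, duration_ms = 38.6,
                        peak_velocity = 2000, blincade = TRUE,
                        boomerang_half = "none")
  both <- dplyr::bind_rows(tab, bad)
  fit_with <- fit_main_sequence(both)
  fit_without <- fit_main_sequence(tab)
  expect_equal(predict(fit_with$fit_amp, 8)$y, predict(fit_without$fit_amp, 8)$y,
               tolerance = 1e-6)
  scored <- main_sequence_zscores(both, fit_with)
  expect_true(is.finite(scored$masez_amp[nrow(scored)]))
  expect_gt(scored$masez_amp[nrow(scored)], 10)
})

test_that("too few clean saccades yields missing scores and a flagged fit", {
  tab <- make_mainseq_table(20, seed = 4)
  expect_warning(fit <- fit_main_sequence(tab), "skipped")
  expect_false(fit$ok)
  scored <- main_sequence_zscores(tab, fit)
  expect_true(all(is.na(scored$masez_amp)))
})

test_that("the Z filter keeps records only when both scores are inside the cut", {
  tab <- tibble::tibble(masez_amp = c(0.5, 4.0, -1, 2), masez_dur = c(1.0, 0.1, 3.4, NA))
  kept <- filter_by_masez(tab, 3.29)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$masez_amp, 0.5)
  expect_equal(nrow(filter_by_masez(tab, Inf)), 4)   # identity filter
})

test_that("tidy and glance summarise the fit", {
  fit <- fit_main_sequence(make_mainseq_table(100, seed = 5))
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(td$edf <= 8.05))
  gl <- generics::glance(fit)
  expect_true(gl$ok)
  expect_equal(gl$n_clean, 100)
})
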