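flat_trace <- function(fs = 2000, dur = 0.2) {
  tibble::tibble(time_s = seq(0, dur, by = 1 / fs), emg_mv = 0)
}

test_that("peak-to-peak scoring is exact and baseline-invariant", {
  tr <- flat_trace()
  expect_equal(peak_to_peak(tr, 0.05), 0)
  # inserted biphasic pulse of +/- 0.5 mV scores 1.0 mV
  tr2 <- tr
  tr2$emg_mv[tr2$time_s >= 0.08 & tr2$time_s < 0.0805] <- 0.5
  tr2$emg_mv[tr2$time_s >= 0.0805 & tr2$time_s < 0.081] <- -0.5
  expect_equal(peak_to_peak(tr2, 0.05), 1.0)
  # a baseline shift leaves the amplitude unchanged
  tr3 <- tr2; tr3$emg_mv <- tr3$emg_mv + 0.7
  expect_equal(peak_to_peak(tr3, 0.05), peak_to_peak(tr2, 0.05))
  expect_error(peak_to_peak(tr, 0.19), "window")
})

test_that("binning assigns trials by cycle position and flags sparse bins", {
  trials <- tibble::tibble(cycle_pct = rep(3, 12), amplitude_mv = 1:12)
  b <- bin_and_average(trials, min_trials = 10)
  expect_equal(nrow(b), 16)
  expect_equal(b$n[1], 12L)
  expect_false(b$flagged[1])
  expect_true(all(b$flagged[-1]))
  expect_equal(b$mean_amplitude_mv[1], mean(1:12))
  # constructed per-bin means recover exactly
  centers <- 100 / 16 * (0:15) + 100 / 32
  tr2 <- tibble::tibble(cycle_pct = rep(centers, each = 3),
                        amplitude_mv = rep(seq(1, 4, length.out = 16),
                                           each = 3))
  b2 <- bin_and_average(tr2, min_trials = 3)
  expect_equal(b2$mean_amplitude_mv, seq(1, 4, length.out = 16))
  expect_false(any(b2$flagged))
  # empty input: 16 flagged empty bins
  b0 <- bin_and_average(tibble::tibble(cycle_pct = numeric(0),
                                       amplitude_mv = numeric(0)))
  expect_equal(b0$n, rep(0L, 16))
  expect_true(all(b0$flagged))
})

test_that("normalization maps the largest bin to one and handles ties", {
  centers <- 100 / 16 * (0:15) + 100 / 32
  b <- bin_and_average(tibble::tibble(cycle_pct = centers,
                                      amplitude_mv = rep(2, 16)),
                       min_trials = 1)
  mc <- normalize_and_interpolate(b)
  expect_equal(predict(mc, seq(0, 100, by = 5)), rep(1, 21))
  # a ramp passes through its normalized bin values at the centers
  b2 <- bin_and_average(tibble::tibble(cycle_pct = centers,
                                       amplitude_mv = seq(0.5, 2, length.out = 16)),
                        min_trials = 1)
  mc2 <- normalize_and_interpolate(b2)
  expect_equal(predict(mc2, centers),
               seq(0.5, 2, length.out = 16) / 2, tolerance = 1e-9)
})

test_that("the modulation curve is scale-invariant in the amplitudes", {
  curve <- generate_modulation_presets()$soleus$reference
  trials <- generate_reflex_trials(curve, n_per_bin = 3, seed = 5)
  c1 <- reflex_modulation_curve(trials, min_trials = 3)
  trials2 <- trials
  trials2$trace <- lapply(trials$trace, function(tr) {
    tr$emg_mv <- tr$emg_mv * 7.3; tr
  })
  c2 <- reflex_modulation_curve(trials2, min_trials = 3)
  expect_equal(c1$bin_values, c2$bin_values, tolerance = 1e-12)
})

test_that("noiseless trials round-trip the generating curve at bin centers", {
  for (g in c("soleus", "vasti")) {
    curve <- generate_modulation_presets()[[g]]$reference
    trials <- generate_reflex_trials(curve, n_per_bin = 10, noise_sd = 0)
    rec <- reflex_modulation_curve(trials)
    expect_lt(max(abs(rec$bin_values - predict(curve, rec$bin_centers))),
              1e-9)
  }
})

test_that("noisy trials recover the bin means within sampling error", {
  curve <- generate_modulation_presets()$soleus$stroke
  n <- 100; sd <- 0.05
  trials <- generate_reflex_trials(curve, n_per_bin = n, noise_sd = sd,
                                   seed = 3)
  b <- reflex_amplitudes(trials) |> bin_and_average(min_trials = n)
  truth <- predict(curve, b$bin_center_pct)
  # amplitudes are clipped at zero, so compare where clipping is negligible
  ok <- truth > 3 * sd
  expect_true(all(abs(b$mean_amplitude_mv[ok] - truth[ok]) <=
                    3 * sd / sqrt(n)))
})

test_that("preset curves have the stroke-type loss of swing suppression", {
  presets <- generate_modulation_presets()
  swing <- seq(70, 95, by = 0.5)
  for (g in c("soleus", "gastrocnemius")) {
    ref <- predict(presets[[g]]$reference, swing)
    str <- predict(presets[[g]]$stroke, swing)
    expect_lt(mean(ref), 0.2)
    expect_gte(mean(str), 0.5)
    expect_true(all(str >= ref))
  }
  # curves are continuous across the 0/100% seam
  for (g in names(presets)) {
    for (cnd in c("reference", "stroke")) {
      mc <- presets[[g]][[cnd]]
      expect_equal(predict(mc, 1e-9), predict(mc, 100 - 1e-9),
                   tolerance = 1e-6)
      dense <- predict(mc, seq(0, 100, by = 0.05))
      expect_true(all(dense >= 0 & dense <= 1))
    }
  }
})
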