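test_that("R peaks are found within 1 ms of truth on clean traces", {
  sim <- simulate_ecg(
    heart_rate = 450, noise_sd = 0, baseline_wander_amp = 0,
    qt_window_drift_cv = 0, per_beat_qt_jitter_sd_ms = 0, duration_s = 15, seed = 1
  )
  r <- detect_r_peaks(sim$trace)
  expect_equal(length(r), length(sim$r_times_s))
  expect_lt(max(abs(r - sim$r_times_s)) * 1000, 1)
  expect_true(all(diff(r) > 0))
})

test_that("flatline and noise-only traces raise detection errors", {
  flat <- tibble::tibble(time_s = seq(0, 5, by = 1e-3), voltage_mV = 0)
  expect_error(detect_r_peaks(flat), class = "cardiophen_detection_error")
  expect_error(
    detect_r_peaks(flat[1:500, ]), # < 2 s
    class = "cardiophen_detection_error"
  )
})

test_that("beats are all detected with no false positives under 5% noise", {
  stats <- vapply(1:10, function(s) {
    sim <- simulate_ecg(heart_rate = 450, noise_sd = 0.05, duration_s = 30, seed = s)
    r <- suppressWarnings(detect_r_peaks(sim$trace))
    hit <- vapply(sim$r_times_s, function(t) min(abs(r - t)) < 0.005, logical(1))
    fp <- vapply(r, function(t) min(abs(sim$r_times_s - t)) < 0.005, logical(1))
    c(mean(hit), mean(fp))
  }, numeric(2))
  expect_gte(min(stats[1, ]), 0.99)
  expect_equal(min(stats[2, ]), 1) # every detection matches a true beat
})

test_that("averaging identical beats reproduces a single beat and scales linearly", {
  # HR 400 puts every R peak exactly on the 1 kHz grid, so all beats are
  # sample-identical and the average must equal any single beat
  sim <- simulate_ecg(
    heart_rate = 400, noise_sd = 0, baseline_wander_amp = 0,
    qt_window_drift_cv = 0, per_beat_qt_jitter_sd_ms = 0, duration_s = 5, seed = 1
  )
  r <- detect_r_peaks(sim$trace)
  cyc <- average_cycle(sim$trace, r)
  n_pre <- sum(cyc$waveform$time_ms < 0)
  i_r <- round(r[5] * 1000) + 1
  single <- sim$trace$voltage_mV[(i_r - n_pre):(i_r + (nrow(cyc$waveform) - n_pre - 1))]
  expect_equal(cyc$waveform$voltage, single, tolerance = 1e-9)

  # linearity: doubling the trace doubles the averaged waveform
  tr2 <- sim$trace
  tr2$voltage_mV <- 2 * tr2$voltage_mV
  cyc2 <- average_cycle(tr2, r)
  expect_equal(cyc2$waveform$voltage, 2 * cyc$waveform$voltage, tolerance = 1e-12)
  expect_error(
    average_cycle(sim$trace, r[1:2], window = c(0, 0.3)),
    class = "cardiophen_insufficient_data"
  )
})

test_that("averaging N beats shrinks white noise like 1/sqrt(N)", {
  ratio <- vapply(1:10, function(s) {
    sigma <- 0.05
    sim <- simulate_ecg(
      noise_sd = sigma, baseline_wander_amp = 0, qt_window_drift_cv = 0,
      per_beat_qt_jitter_sd_ms = 0, duration_s = 30, seed = s
    )
    clean <- simulate_ecg(
      noise_sd = 0, baseline_wander_amp = 0, qt_window_drift_cv = 0,
      per_beat_qt_jitter_sd_ms = 0, duration_s = 30, seed = s
    )
    r <- detect_r_peaks(clean$trace)
    cyc <- average_cycle(sim$trace, r)
    cyc0 <- average_cycle(clean$trace, r)
    resid_sd <- sd(cyc$waveform$voltage - cyc0$waveform$voltage)
    resid_sd / (sigma / sqrt(cyc$n_beats_averaged))
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.20)
})

test_that("noiseless QT is recovered within 2 ms across rates and polarities", {
  for (mode in c("positive", "negative_undershoot")) {
    for (hr in c(350, 500)) {
      for (qt in c(24, 32)) {
        res <- analyze_ecg_animal(
          heart_rate = hr, qt_true_ms = qt, qt_window_drift_cv = 0,
          per_beat_qt_jitter_sd_ms = 0, noise_sd = 0, baseline_wander_amp = 0,
          t_wave_mode = mode, duration_s = 15, seed = 1
        )
        expect_lt(abs(res$qt_mean_ms - qt), 2)
      }
    }
  }
})

test_that("T-end detection is polarity invariant", {
  qts <- vapply(c("positive", "negative_undershoot"), function(mode) {
    analyze_ecg_animal(
      qt_true_ms = 28, qt_window_drift_cv = 0, per_beat_qt_jitter_sd_ms = 0,
      noise_sd = 0, baseline_wander_amp = 0, t_wave_mode = mode,
      duration_s = 15, seed = 1
    )$qt_mean_ms
  }, numeric(1))
  expect_lt(abs(diff(qts)), 2)
})

test_that("landmarks are invariant under positive voltage scaling", {
  sim <- simulate_ecg(
    noise_sd = 0, baseline_wander_amp = 0, qt_window_drift_cv = 0,
    per_beat_qt_jitter_sd_ms = 0, duration_s = 5, seed = 2
  )
  r <- detect_r_peaks(sim$trace)
  cyc <- locate_landmarks(average_cycle(sim$trace, r))
  tr_k <- sim$trace
  tr_k$voltage_mV <- 3.7 * tr_k$voltage_mV
  cyc_k <- locate_landmarks(average_cycle(tr_k, r))
  expect_equal(cyc_k$landmarks_ms, cyc$landmarks_ms, tolerance = 1e-9)
})

test_that("QT-length variation is scale and offset invariant", {
  sim <- simulate_ecg(qt_window_drift_cv = 0.06, seed = 4)
  base <- suppressWarnings(qt_variation(sim$trace))
  tr <- sim$trace
  tr$voltage_mV <- 2.5 * tr$voltage_mV + 0.4
  mod <- suppressWarnings(qt_variation(tr))
  expect_equal(mod$qt_cv, base$qt_cv, tolerance = 1e-6)
  expect_equal(mod$windows$qt_ms, base$windows$qt_ms, tolerance = 1e-3)
})

test_that("doubling the sampling rate moves QT by at most one original sample", {
  for (fs in c(1000, 2000)) {
    res <- analyze_ecg_animal(
      sampling_rate = fs, qt_true_ms = 28, qt_window_drift_cv = 0,
      per_beat_qt_jitter_sd_ms = 0, noise_sd = 0, baseline_wander_amp = 0,
      duration_s = 15, seed = 1
    )
    assign(paste0("qt_", fs), res$qt_mean_ms)
  }
  expect_lt(abs(qt_1000 - qt_2000), 1)
})

test_that("hand-computed window QTs give the documented mean and CV", {
  qts <- c(27, 28, 27, 29, 28, 27)
  expect_equal(mean(qts), 27.667, tolerance = 1e-3)
  expect_equal(coefficient_of_variation(qts), 0.0295, tolerance = 1e-3)
})

test_that("expected QT CV never decreases as generator drift grows", {
  grid <- c(0.02, 0.05, 0.083, 0.12)
  mean_cv <- vapply(grid, function(cv) {
    mean(vapply(1:20, function(s) {
      analyze_ecg_animal(qt_window_drift_cv = cv, seed = s)$qt_cv
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cv) > -1e-6))
})

test_that("a short window drops out and too few windows abort the analysis", {
  sim <- simulate_ecg(duration_s = 5, seed = 1)
  # 5 s trace has one window: below the 3-window minimum
  expect_error(
    suppressWarnings(qt_variation(sim$trace)),
    class = "cardiophen_analysis_error"
  )
})
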