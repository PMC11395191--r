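test_that("background subtraction recovers the true ratio exactly when noiseless", {
  sim <- simulate_fura(n_transients = 20, noise_sd = 0, seed = 1)
  rt <- subtract_background(sim$trace, sim$stimulus_times_s)
  expect_equal(rt$background_340, 50, tolerance = 1e-9)
  expect_equal(rt$background_380, 80, tolerance = 1e-9)
  # ratio at a stimulus onset equals the baseline exactly
  i_on <- which.min(abs(rt$data$time_s - sim$stimulus_times_s[3]))
  expect_equal(rt$data$ratio[i_on], 0.246, tolerance = 1e-12)
})

test_that("shifting both backgrounds leaves the ratio unchanged", {
  a <- simulate_fura(n_transients = 15, noise_sd = 0, seed = 1)
  b <- simulate_fura(
    n_transients = 15, noise_sd = 0,
    background_340 = 100, background_380 = 160, seed = 1
  )
  ra <- subtract_background(a$trace, a$stimulus_times_s)
  rb <- subtract_background(b$trace, b$stimulus_times_s)
  expect_equal(ra$data$ratio, rb$data$ratio, tolerance = 1e-9)
})

test_that("a background window over the stimulated segment is rejected", {
  sim <- simulate_fura(n_transients = 15, seed = 1)
  expect_error(
    subtract_background(sim$trace, sim$stimulus_times_s, background_window = c(0.5, 1.5)),
    "overlaps"
  )
})

test_that("F380 at or below background is a signal-to-background error", {
  sim <- simulate_fura(n_transients = 15, noise_sd = 0, seed = 1)
  tr <- sim$trace
  tr$f380[100:120] <- 70 # paced samples dropping below the 80-count background
  expect_error(
    subtract_background(tr, sim$stimulus_times_s),
    class = "cardiophen_background_error"
  )
})

test_that("the ensemble average of identical transients equals one transient", {
  sim <- simulate_fura(n_transients = 30, noise_sd = 0, seed = 1)
  rt <- subtract_background(sim$trace, sim$stimulus_times_s)
  avg <- ensemble_average(rt)
  i0 <- which.min(abs(rt$data$time_s - sim$stimulus_times_s[4]))
  one <- rt$data$ratio[i0:(i0 + nrow(avg$data) - 1)]
  expect_equal(avg$data$ratio, one, tolerance = 1e-10)
  expect_equal(avg$n_transients_averaged, 30L)
  expect_equal(avg$period_ms, 200)
})

test_that("averaging ~100 transients shrinks noise by ~10x", {
  ratio <- vapply(1:10, function(s) {
    sigma <- 3
    noisy <- simulate_fura(n_transients = 100, noise_sd = sigma, seed = s)
    clean <- simulate_fura(n_transients = 100, noise_sd = 0, seed = s)
    avg_n <- ensemble_average(subtract_background(noisy$trace, noisy$stimulus_times_s))
    avg_c <- ensemble_average(subtract_background(clean$trace, clean$stimulus_times_s))
    resid <- avg_n$data$ratio - avg_c$data$ratio
    # per-sample ratio noise: two channels of sd sigma on F340 and F380
    sd_ratio_single <- sigma / 800 * sqrt(1 + 0.246^2)
    sd(resid) / (sd_ratio_single / sqrt(100))
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.20)
})

test_that("one doubled transient among 100 barely moves the average", {
  sim <- simulate_fura(n_transients = 100, noise_sd = 0, seed = 1)
  rt <- subtract_background(sim$trace, sim$stimulus_times_s)
  base <- ensemble_average(rt)
  rt2 <- rt
  i0 <- which.min(abs(rt$data$time_s - sim$stimulus_times_s[1]))
  idx <- i0:(i0 + 49)
  rt2$data$ratio[idx] <- 0.246 + 2 * (rt2$data$ratio[idx] - 0.246)
  mod <- ensemble_average(rt2)
  amp_base <- max(base$data$ratio) - 0.246
  amp_mod <- max(mod$data$ratio) - 0.246
  expect_lte(amp_mod / amp_base, 1.01 + 1e-9)
})

test_that("irregular stimulus spacing is a pacing error", {
  sim <- simulate_fura(n_transients = 20, seed = 1)
  rt <- subtract_background(sim$trace, sim$stimulus_times_s)
  rt$stimulus_times_s[10] <- rt$stimulus_times_s[10] + 0.03 # 15% of the period
  expect_error(ensemble_average(rt), class = "cardiophen_pacing_error")
  rt$stimulus_times_s <- rt$stimulus_times_s[1:5]
  expect_error(ensemble_average(rt), class = "cardiophen_insufficient_data")
})

test_that("noiseless metrics equal the generator's realized labels", {
  sim <- simulate_fura(n_transients = 100, noise_sd = 0, seed = 1)
  m <- analyze_fura(sim)
  real <- sim$truth$realized
  expect_equal(m$baseline, real$baseline, tolerance = 1e-6)
  expect_equal(m$peak_amplitude, real$peak_amplitude, tolerance = 1e-6)
  expect_equal(m$time_to_peak_ms, real$time_to_peak_ms, tolerance = 1e-9)
  expect_equal(m$time_to_90pct_baseline_ms, real$time_to_90pct_baseline_ms,
    tolerance = 1e-6
  )
  expect_equal(m$tau_ms, sim$truth$tau_ms, tolerance = 0.02 * sim$truth$tau_ms)
  # consistency identity holds exactly
  expect_equal(
    m$peak_amplitude_pct_baseline, 100 * m$peak_amplitude / m$baseline,
    tolerance = 1e-12
  )
})

test_that("ratio metrics are invariant to a common channel rescaling", {
  sim <- simulate_fura(n_transients = 40, noise_sd = 1, seed = 2)
  m1 <- analyze_fura(sim)
  k <- 1.8
  sim$trace$f340 <- k * sim$trace$f340
  sim$trace$f380 <- k * sim$trace$f380
  m2 <- analyze_fura(sim)
  expect_equal(m2$peak_amplitude, m1$peak_amplitude, tolerance = 1e-9)
  expect_equal(m2$tau_ms, m1$tau_ms, tolerance = 1e-6)
})

test_that("a flat trace yields zero amplitude and missing-metric flags", {
  avg <- make_averaged_transient(rep(0.25, 50))
  m <- transient_metrics(avg)
  expect_equal(m$peak_amplitude, 0)
  expect_true("no_transient" %in% m$flags)
  expect_true(is.na(m$tau_ms))
})

test_that("a pure exponential satisfies t90 - t_peak = tau * ln(10)", {
  fs <- 250
  for (tau in c(30, 40)) {
    t_ms <- (0:119) / fs * 1000
    avg <- make_averaged_transient(0.246 + 0.107 * exp(-t_ms / tau), sampling_rate = fs)
    m <- transient_metrics(avg)
    expect_lt(
      abs((m$time_to_90pct_baseline_ms - m$time_to_peak_ms) - tau * log(10)),
      1000 / fs
    )
    expect_equal(m$tau_ms, tau, tolerance = 0.01 * tau)
  }
})

test_that("tau recovery stays within 5% across the identifiable range", {
  for (tau in c(20, 40, 80)) {
    est <- vapply(1:20, function(s) {
      sim <- suppressWarnings(simulate_fura(
        tau_ms = tau, noise_sd = 0.01 * 0.246 * 800,
        background_duration_s = 5, seed = s
      ))
      analyze_fura(sim)$tau_ms
    }, numeric(1))
    expect_lt(abs(mean(est) - tau) / tau, 0.05)
  }
})

test_that("a transient that never recovers is flagged, not an error", {
  t_ms <- (0:49) * 4
  slow <- 0.24 + 0.1 * (t_ms / max(t_ms))^2 # still rising at the period end
  m <- transient_metrics(make_averaged_transient(slow))
  expect_true(is.na(m$time_to_90pct_baseline_ms))
  expect_true("t90_not_reached" %in% m$flags)
  expect_true(is.na(m$tau_ms))
})
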