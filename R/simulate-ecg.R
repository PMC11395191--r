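#' Simulate a mouse Lead-I ECG trace with analytic QT ground truth
#'
#' Builds a 30 s (by default) single-lead ECG from a per-beat template of
#' compact-support raised-cosine components (P, Q, R, S, a J-wave bump, and a
#' T-wave in either polarity). Every landmark of the template (Q onset, R
#' peak, J wave, T end) is an analytic function of the parameters, so the QT
#' interval of each beat is known exactly: `qt = t_end - q_onset`.
#'
#' QT variability is controlled on two levels, mirroring how windowed
#' QT-variation statistics are computed downstream: each 5 s window draws a
#' window-mean QT as `qt_true * (1 + e)`, `e ~ N(0, qt_window_drift_cv)`, so
#' the coefficient of variation of window means equals `qt_window_drift_cv`
#' in expectation; individual beats then jitter around their window mean with
#' SD `per_beat_qt_jitter_sd`. Jitter moves the whole T complex, leaving the
#' QRS (and hence Q onset at -6 ms relative to R) untouched.
#'
#' The `negative_undershoot` T-wave appends a trailing negative lobe whose
#' minimum falls exactly at the T end, so both polarities share the same
#' ground-truth QT and exercise the derivative-zero T-end rule.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param duration_s Trace duration in seconds; must be a multiple of 5.
#' @param heart_rate Heart rate in BPM (mouse range, nominally 350-500).
#' @param qt_true_ms Noiseless template QT (Q onset to T end) in ms.
#' @param qt_window_drift_cv CV of the window-mean QT across 5 s windows.
#' @param per_beat_qt_jitter_sd_ms Per-beat QT jitter SD in ms.
#' @param t_wave_mode `"positive"` or `"negative_undershoot"`.
#' @param noise_sd Additive white-noise SD in mV (R amplitude is 1 mV).
#' @param baseline_wander_amp Amplitude in mV of a 0.5 Hz baseline wander.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return A list with:
#' \describe{
#'   \item{trace}{tibble with columns `time_s`, `voltage_mV`.}
#'   \item{r_times_s}{true R-peak times (s).}
#'   \item{windows}{tibble of per-window ground truth: drawn window-mean QT
#'     and the realized mean over the beats in the window (ms).}
#'   \item{beats}{tibble of per-beat true QT (ms) and window membership.}
#'   \item{landmarks_ms}{template landmarks relative to R: `q_onset`,
#'     `j_wave`, and the noiseless `t_end` (= `q_onset + qt_true_ms`).}
#'   \item{spec}{the parameter list used.}
#' }
#' @examples
#' sim <- simulate_ecg(duration_s = 5, seed = 1)
#' head(sim$trace)
#' @export
simulate_ecg <- function(sampling_rate = 1000,
                         duration_s = 30,
                         heart_rate = 450,
                         qt_true_ms = 28,
                         qt_window_drift_cv = 0.05,
                         per_beat_qt_jitter_sd_ms = 0.5,
                         t_wave_mode = c("positive", "negative_undershoot"),
                         noise_sd = 0.02,
                         baseline_wander_amp = 0.05,
                         seed = NULL) {
  t_wave_mode <- match.arg(t_wave_mode)
  check_positive(sampling_rate, "sampling_rate")
  check_positive(duration_s, "duration_s")
  if (abs(duration_s / 5 - round(duration_s / 5)) > 1e-9) {
    abort_param("duration_s", "must be a multiple of 5 s")
  }
  check_positive(heart_rate, "heart_rate")
  check_nonneg(qt_window_drift_cv, "qt_window_drift_cv")
  check_nonneg(per_beat_qt_jitter_sd_ms, "per_beat_qt_jitter_sd_ms")
  check_nonneg(noise_sd, "noise_sd")
  check_nonneg(baseline_wander_amp, "baseline_wander_amp")
  rr_ms <- 60000 / heart_rate
  if (qt_true_ms < 0 || qt_true_ms >= rr_ms) {
    abort_param("qt_true_ms", "must satisfy 0 <= qt_true < one RR interval (60000/heart_rate ms)")
  }

  with_seed(seed, {
    rr_s <- 60 / heart_rate
    offset_s <- 0.05
    r_times <- seq(offset_s, duration_s - 0.08, by = rr_s)
    n_windows <- as.integer(round(duration_s / 5))
    window_id <- pmin(floor(r_times / 5) + 1L, n_windows)

    qt_window <- qt_true_ms * (1 + stats::rnorm(n_windows, 0, qt_window_drift_cv))
    qt_beat <- qt_window[window_id] +
      stats::rnorm(length(r_times), 0, per_beat_qt_jitter_sd_ms)
    # QT can never collapse into the QRS or spill past the beat window
    qt_beat <- pmin(pmax(qt_beat, 14), 0.55 * rr_ms)

    n <- as.integer(round(duration_s * sampling_rate))
    time_s <- (seq_len(n) - 1) / sampling_rate
    v <- numeric(n)

    for (b in seq_along(r_times)) {
      t_end_b <- qt_beat[b] - 6 # T end relative to R (q_onset = -6 ms)
      lo <- max(1L, as.integer(floor((r_times[b] - 0.045) * sampling_rate)) + 1L)
      hi <- min(n, as.integer(ceiling((r_times[b] + (t_end_b + 8) / 1000) * sampling_rate)) + 1L)
      idx <- lo:hi
      tt <- (time_s[idx] - r_times[b]) * 1000 # ms relative to R
      beat <- rc_bump(tt, -30, 8, 0.10) + # P
        rc_bump(tt, -4, 2, -0.20) +       # Q (onset -6 ms)
        rc_bump(tt, 0, 3, 1.00) +         # R (overlaps Q: no isoelectric notch)
        rc_bump(tt, 3, 2, -0.30) +        # S
        rc_bump(tt, 7, 3, 0.12)           # J-wave bump
      if (t_wave_mode == "positive") {
        beat <- beat + rc_bump(tt, t_end_b - 6, 6, 0.35)
      } else {
        # positive lobe ends 2 ms past the trailing lobe's onset so the
        # summed derivative first returns to zero exactly at the trough
        beat <- beat + rc_bump(tt, t_end_b - 7, 5, 0.35) +
          rc_bump(tt, t_end_b, 4, -0.12)
      }
      v[idx] <- v[idx] + beat
    }

    if (baseline_wander_amp > 0) {
      v <- v + baseline_wander_amp * sin(2 * pi * 0.5 * time_s)
    }
    if (noise_sd > 0) {
      v <- v + stats::rnorm(n, 0, noise_sd)
    }

    windows <- tibble::tibble(
      window = seq_len(n_windows),
      t_start_s = (seq_len(n_windows) - 1) * 5,
      t_end_s = seq_len(n_windows) * 5,
      qt_drawn_ms = qt_window,
      qt_realized_ms = vapply(
        seq_len(n_windows),
        function(w) mean(qt_beat[window_id == w]),
        numeric(1)
      )
    )

    list(
      trace = tibble::tibble(time_s = time_s, voltage_mV = v),
      r_times_s = r_times,
      windows = windows,
      beats = tibble::tibble(
        r_time_s = r_times, window = window_id, qt_true_ms = qt_beat
      ),
      landmarks_ms = c(q_onset = -6, j_wave = 7, t_end = qt_true_ms - 6),
      spec = list(
        sampling_rate = sampling_rate, duration_s = duration_s,
        heart_rate = heart_rate, qt_true_ms = qt_true_ms,
        qt_window_drift_cv = qt_window_drift_cv,
        per_beat_qt_jitter_sd_ms = per_beat_qt_jitter_sd_ms,
        t_wave_mode = t_wave_mode, noise_sd = noise_sd,
        baseline_wander_amp = baseline_wander_amp, seed = seed
      )
    )
  })
}
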