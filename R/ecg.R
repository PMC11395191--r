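#' Detect R peaks in a single-lead ECG trace
#'
#' Band-passes the signal (5-90 Hz Butterworth, zero-phase), squares its
#' derivative to form an energy envelope, and thresholds the envelope at 40%
#' of its rolling 2 s maximum with a 40 ms refractory period. Peak times are
#' refined to the maximum of the band-passed trace near each envelope peak.
#'
#' @param trace Data frame with a `time_s` column and one voltage channel
#'   (first non-time column is used).
#' @param hr_band Allowed heart-rate range in BPM used to sanity-check
#'   inter-peak intervals; a median rate outside the band raises an error,
#'   individual out-of-band intervals a warning.
#' @return Numeric vector of strictly increasing R-peak times in seconds.
#' @examples
#' sim <- simulate_ecg(duration_s = 5, noise_sd = 0, seed = 1)
#' r <- detect_r_peaks(sim$trace)
#' @export
detect_r_peaks <- function(trace, hr_band = c(300, 900)) {
  tr <- as_trace_frame(trace, n_channels = 1L)
  v <- tr$values[[1]]
  fs <- tr$sampling_rate
  if (tail(tr$time, 1) - tr$time[1] < 2) {
    abort("trace must be at least 2 s long", class = "cardiophen_detection_error")
  }
  if (stats::sd(v) < 1e-12) {
    abort("flatline trace: no R peaks detectable", class = "cardiophen_detection_error")
  }

  hi <- min(90, 0.45 * fs)
  bp <- signal::butter(2, c(5, hi) / (fs / 2), type = "pass")
  vf <- as.numeric(signal::filtfilt(bp, v))
  env <- central_diff(vf, 1 / fs)^2
  env <- moving_average(env, round(0.010 * fs))

  # threshold: 40% of the rolling 2 s maximum (block-wise)
  block <- max(1L, as.integer(round(2 * fs)))
  nb <- ceiling(length(env) / block)
  bmax <- vapply(seq_len(nb), function(i) {
    max(env[((i - 1L) * block + 1L):min(i * block, length(env))])
  }, numeric(1))
  bmax <- pmax(bmax, c(bmax[-1], bmax[nb]), c(bmax[1], bmax[-nb]))
  thr <- rep(0.4 * bmax, each = block, length.out = length(env))

  above <- env > thr
  if (!any(above)) {
    abort("no R peaks found above threshold", class = "cardiophen_detection_error")
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  refine <- as.integer(round(0.010 * fs))
  cand <- vapply(which(runs$values), function(k) {
    i <- starts[k]:ends[k]
    i[which.max(env[i])]
  }, integer(1))
  # refine each candidate to the band-passed voltage maximum nearby
  peaks <- vapply(cand, function(i) {
    w <- max(1L, i - refine):min(length(vf), i + refine)
    w[which.max(vf[w])]
  }, integer(1))
  peaks <- sort(unique(peaks))

  # refractory: drop the weaker of any pair closer than 40 ms
  refractory <- as.integer(round(0.040 * fs))
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- peaks[i]
    } else if (vf[peaks[i]] > vf[peaks[which(keep)[sum(keep)]]]) {
      keep[which(keep)[sum(keep)]] <- FALSE
      keep[i] <- TRUE
      last <- peaks[i]
    }
  }
  peaks <- peaks[keep]
  if (length(peaks) < 2) {
    abort("fewer than 2 R peaks found", class = "cardiophen_detection_error")
  }

  times <- tr$time[peaks]
  rr <- diff(times)
  hr <- 60 / rr
  if (stats::median(hr) < hr_band[1] || stats::median(hr) > hr_band[2]) {
    abort(
      sprintf(
        "median heart rate %.0f BPM outside physiologic band [%g, %g]",
        stats::median(hr), hr_band[1], hr_band[2]
      ),
      class = "cardiophen_detection_error"
    )
  }
  if (any(hr < hr_band[1] | hr > hr_band[2])) {
    warn(sprintf(
      "%d inter-beat interval(s) outside %g-%g BPM",
      sum(hr < hr_band[1] | hr > hr_band[2]), hr_band[1], hr_band[2]
    ))
  }
  times
}

#' Average beat-aligned ECG cycles within a time window
#'
#' Segments the trace around each R peak (one median RR interval, one third
#' before the peak and two thirds after) and averages the aligned segments.
#'
#' @inheritParams detect_r_peaks
#' @param r_peaks R-peak times in seconds (e.g. from [detect_r_peaks()]).
#' @param window Length-2 numeric `(start_s, end_s)`; only beats whose R peak
#'   falls inside the window are averaged. Defaults to the whole trace.
#' @return An object of class `averaged_cycle`: list with `waveform`
#'   (tibble `time_ms`, `voltage`; time relative to the R peak),
#'   `sampling_rate`, `n_beats_averaged`, and (once located) `landmarks_ms`.
#' @export
average_cycle <- function(trace, r_peaks, window = NULL) {
  tr <- as_trace_frame(trace, n_channels = 1L)
  if (is.null(window)) window <- c(tr$time[1], tail(tr$time, 1))
  fs <- tr$sampling_rate
  inside <- r_peaks >= window[1] & r_peaks < window[2]
  pk <- r_peaks[inside]
  if (length(pk) < 3) {
    abort("fewer than 3 beats in window: cannot average", class = "cardiophen_insufficient_data")
  }
  rr <- stats::median(diff(pk))
  n_pre <- as.integer(round(rr / 3 * fs))
  n_post <- as.integer(round(2 * rr / 3 * fs))
  v <- tr$values[[1]]
  idx_r <- as.integer(round((pk - tr$time[1]) * fs)) + 1L
  ok <- idx_r - n_pre >= 1L & idx_r + n_post <= length(v)
  idx_r <- idx_r[ok]
  if (length(idx_r) < 3) {
    abort("fewer than 3 complete beats in window", class = "cardiophen_insufficient_data")
  }
  seg <- vapply(
    idx_r,
    function(i) v[(i - n_pre):(i + n_post)],
    numeric(n_pre + n_post + 1L)
  )
  structure(
    list(
      waveform = tibble::tibble(
        time_ms = ((-n_pre):n_post) / fs * 1000,
        voltage = rowMeans(seg)
      ),
      sampling_rate = fs,
      n_beats_averaged = length(idx_r),
      landmarks_ms = NULL
    ),
    class = "averaged_cycle"
  )
}

#' Locate Q onset, J wave, and T end on an averaged ECG cycle
#'
#' Implements the J-wave anchored, derivative-zero T-end rule: after
#' Savitzky-Golay smoothing, the T end is the first point after the steepest
#' post-J repolarization slope (the most negative smoothed derivative) where
#' the derivative returns to zero, resolved by linear interpolation between
#' samples. The rule identifies the end of entirely positive T waves (which
#' need not return to the isoelectric baseline) as well as the trough of T
#' waves with a negative undershoot.
#'
#' Q onset is the last point before the R peak where the smoothed trace stays
#' within an isoelectric band (3 x the noise SD of the TP segment, floored at
#' 1.5% of the R amplitude; the isoelectric level is the median of the TP
#' segment). The J wave is the first local maximum 2-20 ms after the S-wave
#' minimum.
#'
#' @param cycle An `averaged_cycle` from [average_cycle()].
#' @param smoothing_ms Savitzky-Golay window (order 3) in ms.
#' @return The cycle with `landmarks_ms` set: named vector `q_onset`,
#'   `r_peak` (0), `j_wave`, `t_end`, and `qt_ms = t_end - q_onset`.
#' @export
locate_landmarks <- function(cycle, smoothing_ms = 5) {
  stopifnot(inherits(cycle, "averaged_cycle"))
  wf <- cycle$waveform
  fs <- cycle$sampling_rate
  dt_ms <- 1000 / fs
  sm <- sgolay_smooth(wf$voltage, fs, width_ms = smoothing_ms)
  t_ms <- wf$time_ms
  i0 <- which.min(abs(t_ms)) # R peak

  # TP segment: last quarter of the post-R extent (after T, before next P)
  tp <- which(t_ms > 0.75 * max(t_ms))
  iso <- stats::median(sm[tp])
  noise_sd <- stats::sd(wf$voltage[tp] - sm[tp] + (sm[tp] - iso))
  amp_r <- sm[i0] - iso
  if (!is.finite(amp_r) || amp_r <= 0) {
    abort("R peak not positive relative to isoelectric level", class = "cardiophen_landmark_error")
  }
  band <- max(3 * noise_sd, 0.015 * amp_r)

  # Q onset: walk back from R until the trace re-enters the isoelectric band
  q_idx <- NA_integer_
  for (i in seq(i0 - 1L, 2L)) {
    if (abs(sm[i] - iso) < band) {
      q_idx <- i
      break
    }
  }
  if (is.na(q_idx)) {
    abort("Q onset not found before R peak", class = "cardiophen_landmark_error")
  }

  # S minimum within 8 ms after R, then J = first local max 2-20 ms later
  s_win <- which(t_ms > 0 & t_ms <= 8)
  s_idx <- s_win[which.min(sm[s_win])]
  j_win <- which(t_ms > t_ms[s_idx] + 2 & t_ms <= t_ms[s_idx] + 20)
  j_idx <- NA_integer_
  for (i in j_win) {
    if (i > 1 && i < length(sm) && sm[i] >= sm[i - 1] && sm[i] > sm[i + 1]) {
      j_idx <- i
      break
    }
  }
  if (is.na(j_idx)) j_idx <- j_win[which.max(sm[j_win])]

  # T end: first zero of the smoothed derivative after the steepest
  # repolarization down-slope following the J wave
  d <- central_diff(sm, dt_ms)
  search <- which(seq_along(sm) > j_idx & t_ms <= 0.75 * max(t_ms))
  if (length(search) < 3) {
    abort("no samples after J wave to search for T end", class = "cardiophen_tend_error")
  }
  anchor <- search[which.min(d[search])]
  # "derivative equals zero" resolved against a small threshold (2% of the
  # anchor slope): smoothing makes a tangential return to baseline approach
  # zero asymptotically, which would otherwise bias the T end late
  eps <- 0.02 * abs(d[anchor])
  t_end_ms <- NA_real_
  for (i in anchor:(max(search) - 1L)) {
    if (d[i] < -eps && d[i + 1] >= -eps) {
      frac <- if (d[i + 1] > d[i]) (d[i] + eps) / (d[i] - d[i + 1]) else 0
      t_end_ms <- t_ms[i] + frac * dt_ms
      break
    }
  }
  if (is.na(t_end_ms)) {
    abort("no derivative zero-crossing after J wave: T end not found",
      class = "cardiophen_tend_error"
    )
  }

  lm <- c(
    q_onset = t_ms[q_idx], r_peak = 0,
    j_wave = t_ms[j_idx], t_end = t_end_ms
  )
  if (!(lm[["q_onset"]] < 0 && lm[["j_wave"]] > 0 && lm[["t_end"]] > lm[["j_wave"]])) {
    abort("landmark ordering q_onset < 0 < j_wave < t_end violated",
      class = "cardiophen_landmark_error"
    )
  }
  cycle$landmarks_ms <- lm
  cycle$qt_ms <- unname(lm[["t_end"]] - lm[["q_onset"]])
  cycle
}

#' Windowed QT intervals and QT-length variation from a 30 s ECG
#'
#' Splits the trace into consecutive 5 s windows, computes one averaged cycle
#' and one QT interval per window via [average_cycle()] and
#' [locate_landmarks()], and summarizes QT-length variation as the
#' coefficient of variation (sample SD / mean) of the window QTs. Windows
#' whose T end cannot be located are dropped with a warning; at least three
#' surviving windows are required.
#'
#' @inheritParams detect_r_peaks
#' @param window_s Window length in seconds; the trace duration must be an
#'   integer multiple of it.
#' @param smoothing_ms Passed to [locate_landmarks()].
#' @param hr_warn_band Heart-rate range (BPM) outside which a warning is
#'   issued (the anesthesia titration band).
#' @return An object of class `qt_result`: list with `windows` (per-window
#'   tibble: QT, landmarks, beats averaged, status), `qt_mean_ms`, `qt_cv`,
#'   `heart_rate_bpm`, `n_windows_used`.
#' @examples
#' sim <- simulate_ecg(seed = 42)
#' res <- qt_variation(sim$trace)
#' glance(res)
#' @export
qt_variation <- function(trace, window_s = 5, smoothing_ms = 5,
                         hr_warn_band = c(300, 500)) {
  tr <- as_trace_frame(trace, n_channels = 1L)
  duration <- tail(tr$time, 1) - tr$time[1] + 1 / tr$sampling_rate
  n_win <- round(duration / window_s)
  if (abs(duration - n_win * window_s) > 0.01 * duration || n_win < 1) {
    abort_param("window_s", "trace duration must be a multiple of the window length")
  }

  r_peaks <- detect_r_peaks(trace)
  heart_rate <- 60 * (length(r_peaks) - 1) / (tail(r_peaks, 1) - r_peaks[1])
  if (heart_rate < hr_warn_band[1] || heart_rate > hr_warn_band[2]) {
    warn(sprintf(
      "heart rate %.0f BPM outside the titration band %g-%g BPM",
      heart_rate, hr_warn_band[1], hr_warn_band[2]
    ))
  }

  t0 <- tr$time[1]
  rows <- purrr::map(seq_len(n_win), function(w) {
    win <- t0 + c((w - 1) * window_s, w * window_s)
    out <- tibble::tibble(
      window = w, n_beats = NA_integer_, q_onset_ms = NA_real_,
      j_wave_ms = NA_real_, t_end_ms = NA_real_, qt_ms = NA_real_,
      status = "ok"
    )
    res <- tryCatch(
      {
        cyc <- average_cycle(trace, r_peaks, window = win)
        cyc <- locate_landmarks(cyc, smoothing_ms = smoothing_ms)
        out$n_beats <- cyc$n_beats_averaged
        out$q_onset_ms <- cyc$landmarks_ms[["q_onset"]]
        out$j_wave_ms <- cyc$landmarks_ms[["j_wave"]]
        out$t_end_ms <- cyc$landmarks_ms[["t_end"]]
        out$qt_ms <- cyc$qt_ms
        out
      },
      cardiophen_tend_error = function(e) {
        out$status <- "t_end_not_found"
        out
      },
      cardiophen_insufficient_data = function(e) {
        out$status <- "too_few_beats"
        out
      },
      cardiophen_landmark_error = function(e) {
        out$status <- "landmark_error"
        out
      }
    )
    res
  })
  windows <- dplyr::bind_rows(rows)
  dropped <- windows$status != "ok"
  if (any(dropped)) {
    warn(sprintf("%d window(s) dropped: %s", sum(dropped),
      paste(unique(windows$status[dropped]), collapse = ", ")
    ))
  }
  used <- windows$qt_ms[!dropped]
  if (length(used) < 3) {
    abort("fewer than 3 windows with a measurable QT", class = "cardiophen_analysis_error")
  }
  structure(
    list(
      windows = windows,
      qt_mean_ms = mean(used),
      qt_cv = sample_cv(used),
      heart_rate_bpm = heart_rate,
      n_windows_used = length(used)
    ),
    class = "qt_result"
  )
}

#' @export
print.qt_result <- function(x, ...) {
  cat(sprintf(
    "QT analysis: mean QT %.2f ms, QT-length variation (CV) %.4f, HR %.0f BPM (%d/%d windows)\n",
    x$qt_mean_ms, x$qt_cv, x$heart_rate_bpm, x$n_windows_used, nrow(x$windows)
  ))
  invisible(x)
}

#' @export
tidy.qt_result <- function(x, ...) x$windows

#' @export
glance.qt_result <- function(x, ...) {
  tibble::tibble(
    qt_mean_ms = x$qt_mean_ms, qt_cv = x$qt_cv,
    heart_rate_bpm = x$heart_rate_bpm,
    n_windows_used = x$n_windows_used, n_windows = nrow(x$windows)
  )
}

#' @export
autoplot.qt_result <- function(object, ...) {
  df <- object$windows[object$windows$status == "ok", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$qt_ms)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$qt_mean_ms, linetype = "dashed") +
    ggplot2::labs(
      x = "5 s window", y = "QT (ms)",
      title = sprintf("QT variation: CV = %.3f", object$qt_cv)
    )
}

#' @export
autoplot.averaged_cycle <- function(object, ...) {
  p <- ggplot2::ggplot(object$waveform, ggplot2::aes(x = .data$time_ms, y = .data$voltage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time relative to R (ms)", y = "voltage (mV)")
  if (!is.null(object$landmarks_ms)) {
    p <- p + ggplot2::geom_vline(
      xintercept = unname(object$landmarks_ms[c("q_onset", "j_wave", "t_end")]),
      linetype = "dotted"
    )
  }
  p
}
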