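#' Background-subtract two-channel photometry into an F340/F380 ratio
#'
#' Estimates one scalar background per channel as the mean over a
#' stimulus-free window (by default the empty-field segment after the last
#' stimulus) and forms `ratio = (F340 - b340) / (F380 - b380)` over the
#' paced portion of the recording.
#'
#' @param trace Data frame with `time_s`, `f340`, `f380` columns (matched by
#'   name prefix, otherwise taken in that order).
#' @param stimulus_times_s Stimulus onset times in seconds.
#' @param background_window Length-2 numeric `(start_s, end_s)` over which
#'   the per-channel backgrounds are averaged. Must lie in a stimulus-free
#'   part of the recording: a window overlapping the paced segment is a
#'   parameter error (the resulting backgrounds would be biased by signal).
#' @return An object of class `ratio_trace`: list with `data` (tibble
#'   `time_s`, `ratio` over the paced segment), `stimulus_times_s`,
#'   `background_340`, `background_380`, `sampling_rate`.
#' @export
subtract_background <- function(trace, stimulus_times_s, background_window = NULL) {
  tr <- as_trace_frame(trace, n_channels = 2L)
  i340 <- grep("340", tr$channels)[1]
  i380 <- grep("380", tr$channels)[1]
  if (is.na(i340)) i340 <- 1L
  if (is.na(i380)) i380 <- setdiff(1:2, i340)[1]
  f340 <- tr$values[[i340]]
  f380 <- tr$values[[i380]]
  if (length(stimulus_times_s) < 1) {
    abort_param("stimulus_times_s", "at least one stimulus is required")
  }
  period <- if (length(stimulus_times_s) > 1) {
    stats::median(diff(stimulus_times_s))
  } else {
    0.2
  }
  paced_end <- tail(stimulus_times_s, 1) + period

  if (is.null(background_window)) {
    background_window <- c(paced_end + period, tail(tr$time, 1))
  }
  if (background_window[1] < paced_end &&
    background_window[2] > stimulus_times_s[1]) {
    abort_param(
      "background_window",
      "overlaps the stimulated segment; backgrounds would be biased by signal"
    )
  }
  bg_idx <- tr$time >= background_window[1] & tr$time <= background_window[2]
  if (sum(bg_idx) < 2) {
    abort_param("background_window", "contains fewer than 2 samples")
  }
  b340 <- mean(f340[bg_idx])
  b380 <- mean(f380[bg_idx])

  paced_idx <- tr$time < paced_end
  denom <- f380[paced_idx] - b380
  if (any(denom <= 0)) {
    abort("F380 does not exceed its background everywhere: signal-to-background failure",
      class = "cardiophen_background_error"
    )
  }
  structure(
    list(
      data = tibble::tibble(
        time_s = tr$time[paced_idx],
        ratio = (f340[paced_idx] - b340) / denom
      ),
      stimulus_times_s = stimulus_times_s,
      background_340 = b340,
      background_380 = b380,
      sampling_rate = tr$sampling_rate
    ),
    class = "ratio_trace"
  )
}

#' Ensemble-average paced transients into a single-period transient
#'
#' Aligns the ratio trace at each stimulus onset and averages the aligned
#' one-period segments (e.g. 50 samples at 5 Hz pacing, 250 Hz sampling).
#'
#' @param ratio A `ratio_trace` from [subtract_background()].
#' @return An object of class `averaged_transient`: list with `data`
#'   (tibble `time_ms` since stimulus onset, `ratio`), `sampling_rate`,
#'   `period_ms`, `n_transients_averaged`.
#' @export
ensemble_average <- function(ratio) {
  stopifnot(inherits(ratio, "ratio_trace"))
  stim <- ratio$stimulus_times_s
  if (length(stim) < 10) {
    abort("at least 10 stimuli are required for ensemble averaging",
      class = "cardiophen_insufficient_data"
    )
  }
  dstim <- diff(stim)
  period <- stats::median(dstim)
  if (max(abs(dstim - period)) > 0.05 * period) {
    abort("irregular stimulus spacing (> 5% jitter): cannot infer pacing period",
      class = "cardiophen_pacing_error"
    )
  }
  fs <- ratio$sampling_rate
  n_per <- as.integer(round(period * fs))
  t0 <- ratio$data$time_s[1]
  onsets <- as.integer(round((stim - t0) * fs)) + 1L
  ok <- onsets >= 1L & (onsets + n_per - 1L) <= nrow(ratio$data)
  onsets <- onsets[ok]
  seg <- vapply(
    onsets,
    function(i) ratio$data$ratio[i:(i + n_per - 1L)],
    numeric(n_per)
  )
  structure(
    list(
      data = tibble::tibble(
        time_ms = (seq_len(n_per) - 1) / fs * 1000,
        ratio = rowMeans(seg)
      ),
      sampling_rate = fs,
      period_ms = period * 1000,
      n_transients_averaged = length(onsets)
    ),
    class = "averaged_transient"
  )
}

#' Kinetic metrics of an averaged calcium transient
#'
#' Computes the six metrics of an averaged Fura-2 transient: `baseline`
#' (mean of the pre-stimulus samples, i.e. the last 10% of the period before
#' the next onset), `peak_amplitude` (max - baseline),
#' `peak_amplitude_pct_baseline`, `time_to_peak` (stimulus onset to maximum,
#' ms), `time_to_90pct_baseline` (onset to the first post-peak crossing of
#' `baseline + 0.1 * amplitude`, linearly interpolated; optionally measured
#' from the peak), and `tau` from a nonlinear least-squares fit of
#' `A * exp(-(t - t_peak)/tau) + c` over the decay segment, initialized from
#' a log-linear fit against the measured baseline. The offset `c` is a free
#' parameter: with paced transients the decay is truncated by the pacing
#' period and the pre-stimulus level overestimates the true asymptote, which
#' would bias a fixed-baseline fit.
#'
#' A transient that never recovers to the 90% level within the period, or a
#' flat trace, yields `NA` metrics with the corresponding flag set rather
#' than an error.
#'
#' @param avg An `averaged_transient` from [ensemble_average()].
#' @param t90_reference Reference point for `time_to_90pct_baseline`:
#'   `"stimulus"` (default) or `"peak"`.
#' @return An object of class `transient_metrics`; `tidy()` returns the
#'   metrics as a one-row tibble.
#' @export
transient_metrics <- function(avg, t90_reference = c("stimulus", "peak")) {
  stopifnot(inherits(avg, "averaged_transient"))
  t90_reference <- match.arg(t90_reference)
  y <- avg$data$ratio
  t_ms <- avg$data$time_ms
  n <- length(y)
  if (n < 40) {
    abort("averaged transient must have at least 40 samples",
      class = "cardiophen_insufficient_data"
    )
  }
  dt_ms <- 1000 / avg$sampling_rate
  pre_idx <- (n - max(1L, round(0.1 * n)) + 1L):n
  baseline <- mean(y[pre_idx])
  i_pk <- which.max(y)
  amp <- y[i_pk] - baseline
  flags <- character(0)

  out <- list(
    baseline = baseline, peak_amplitude = amp,
    peak_amplitude_pct_baseline = 100 * amp / baseline,
    time_to_peak_ms = NA_real_, time_to_90pct_baseline_ms = NA_real_,
    tau_ms = NA_real_, fit_rmse = NA_real_,
    n_transients_averaged = avg$n_transients_averaged,
    t90_reference = t90_reference, flags = character(0)
  )
  if (amp <= 1e-9 * max(abs(y), 1)) {
    out$peak_amplitude <- max(amp, 0)
    out$flags <- c("no_transient", "time_to_peak_missing", "t90_missing", "tau_missing")
    return(structure(out, class = "transient_metrics"))
  }

  out$time_to_peak_ms <- t_ms[i_pk]

  thr <- baseline + 0.1 * amp
  t90 <- NA_real_
  if (i_pk < n) {
    for (i in i_pk:(n - 1L)) {
      if (y[i] > thr && y[i + 1L] <= thr) {
        t90 <- t_ms[i] + (y[i] - thr) / (y[i] - y[i + 1L]) * dt_ms
        break
      }
    }
  }
  if (is.na(t90)) {
    flags <- c(flags, "t90_not_reached")
  } else if (t90_reference == "peak") {
    t90 <- t90 - t_ms[i_pk]
  }
  out$time_to_90pct_baseline_ms <- t90

  if (n - i_pk < 5L) {
    out$flags <- c(flags, "tau_fit_failed")
    return(structure(out, class = "transient_metrics"))
  }
  # decay fit over (peak, end of period]; the sampled peak itself can sit on
  # the rising limb, so the fit starts one sample later
  dec <- (i_pk + 1L):n
  td <- t_ms[dec] - t_ms[i_pk]
  yd <- y[dec]
  pos <- yd - baseline > 0.02 * amp
  tau0 <- if (sum(pos) >= 3) {
    sl <- unname(coef(stats::lm(log(yd[pos] - baseline) ~ td[pos]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else avg$period_ms / 4
  } else {
    avg$period_ms / 4
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yd ~ A * exp(-td / tau) + c0,
      start = list(A = amp, tau = tau0, c0 = baseline),
      lower = c(A = 0, tau = dt_ms / 10, c0 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    flags <- c(flags, "tau_fit_failed")
  } else {
    out$tau_ms <- unname(coef(fit)[["tau"]])
    out$fit_rmse <- sqrt(mean(stats::residuals(fit)^2))
  }
  out$flags <- flags
  structure(out, class = "transient_metrics")
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Ca2+ transient (n = %d averaged): baseline %.3f, amplitude %.4f (%.1f%% of baseline),\n",
      "  time to peak %.1f ms, time to 90%% baseline %.1f ms, tau %.1f ms\n"
    ),
    x$n_transients_averaged, x$baseline, x$peak_amplitude,
    x$peak_amplitude_pct_baseline, x$time_to_peak_ms,
    x$time_to_90pct_baseline_ms, x$tau_ms
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.transient_metrics <- function(x, ...) {
  tibble::tibble(
    baseline = x$baseline,
    peak_amplitude = x$peak_amplitude,
    peak_amplitude_pct_baseline = x$peak_amplitude_pct_baseline,
    time_to_peak_ms = x$time_to_peak_ms,
    time_to_90pct_baseline_ms = x$time_to_90pct_baseline_ms,
    tau_ms = x$tau_ms,
    fit_rmse = x$fit_rmse,
    n_transients_averaged = x$n_transients_averaged,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @export
autoplot.averaged_transient <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_ms, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time since stimulus (ms)", y = "F340/F380",
      title = sprintf("Averaged transient (n = %d)", object$n_transients_averaged)
    )
}
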