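#' Segment a pressure-volume trace into cardiac cycles
#'
#' Cycle boundaries are placed at end-diastole, i.e. at local maxima of the
#' (smoothed) volume channel. The trace start and end act as outer
#' boundaries when the adjacent partial segments are close to a full cycle.
#'
#' @param trace Data frame with `time_s` plus pressure and volume channels
#'   (matched by name prefix `pressure` / `volume`; otherwise taken in that
#'   order).
#' @return Tibble with one row per cycle: `cycle`, `start_s`, `end_s`,
#'   `start_idx`, `end_idx`.
#' @export
segment_pv_cycles <- function(trace) {
  tr <- pv_trace(trace)
  v <- tr$volume
  fs <- tr$sampling_rate
  if (stats::sd(v) < 1e-9 * (abs(mean(v)) + 1)) {
    abort("volume channel is flat: cannot segment cycles", class = "cardiophen_segmentation_error")
  }
  vs <- moving_average(v, round(0.015 * fs))
  k <- max(2L, as.integer(round(0.040 * fs)))
  n <- length(vs)
  is_max <- vapply(seq(k + 1L, n - k), function(i) {
    vs[i] >= max(vs[(i - k):(i + k)]) && vs[i] > min(vs[(i - k):(i + k)])
  }, logical(1))
  peaks <- which(is_max) + k
  # collapse plateaus / near-duplicates closer than 40 ms
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) > k)
    peaks <- peaks[keep]
  }
  if (length(peaks) < 2) {
    abort("volume channel is not periodic: fewer than 2 end-diastolic maxima",
      class = "cardiophen_segmentation_error"
    )
  }
  med_len <- stats::median(diff(peaks))
  bounds <- peaks
  if (peaks[1] - 1L >= 0.8 * med_len) bounds <- c(1L, bounds)
  if (n - tail(peaks, 1) >= 0.8 * med_len) bounds <- c(bounds, n)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  full <- (ends - starts) >= 0.7 * med_len
  starts <- starts[full]
  ends <- ends[full]
  if (length(starts) < 3) {
    abort("fewer than 3 full cardiac cycles found", class = "cardiophen_segmentation_error")
  }
  tibble::tibble(
    cycle = seq_along(starts),
    start_s = tr$time[starts], end_s = tr$time[ends],
    start_idx = starts, end_idx = ends
  )
}

#' Per-cycle pressure-volume indices
#'
#' For each segmented cycle computes dP/dt extrema (centered finite
#' differences on lightly smoothed pressure), the end-systolic point as the
#' point of maximal elastance `P / (V - v0)`, and the end-diastolic point as
#' the point of maximal volume.
#'
#' @inheritParams segment_pv_cycles
#' @param cycles Cycle boundaries from [segment_pv_cycles()]; computed if
#'   omitted.
#' @param v0 Volume-axis offset used in the maximal-elastance definition of
#'   end-systole (uL). Every volume sample must exceed it.
#' @param smooth_ms Moving-average width (ms) applied to both channels for
#'   differentiation and point *selection*; the reported point values are
#'   read from the raw channels at the selected samples, so smoothing does
#'   not bias the extracted pressures.
#' @return Tibble with one row per cycle: dP/dt extrema and the end-systolic
#'   and end-diastolic (volume, pressure) points.
#' @export
pv_cycle_metrics <- function(trace, cycles = NULL, v0 = 0, smooth_ms = 5) {
  tr <- pv_trace(trace)
  if (is.null(cycles)) cycles <- segment_pv_cycles(trace)
  fs <- tr$sampling_rate
  ps <- moving_average(tr$pressure, round(smooth_ms / 1000 * fs))
  vs <- moving_average(tr$volume, round(smooth_ms / 1000 * fs))
  if (any(vs <= v0)) {
    abort(sprintf("volume <= v0 (%g uL) encountered; choose a smaller v0", v0),
      class = "cardiophen_config_error"
    )
  }
  dpdt <- central_diff(ps, 1 / fs)
  p_raw <- tr$pressure
  v_raw <- tr$volume
  purrr::map_dfr(seq_len(nrow(cycles)), function(c) {
    idx <- cycles$start_idx[c]:cycles$end_idx[c]
    elast <- ps[idx] / (vs[idx] - v0)
    i_es <- idx[which.max(elast)]
    i_ed <- idx[which.max(vs[idx])]
    tibble::tibble(
      cycle = cycles$cycle[c],
      start_s = cycles$start_s[c], end_s = cycles$end_s[c],
      dpdt_max = max(dpdt[idx]), dpdt_min = min(dpdt[idx]),
      es_volume = v_raw[i_es], es_pressure = p_raw[i_es],
      ed_volume = v_raw[i_ed], ed_pressure = p_raw[i_ed]
    )
  })
}

#' Fit the end-systolic (or end-diastolic) pressure-volume relationship
#'
#' Ordinary least squares `P = slope * V + intercept` on the end-systolic
#' points of the occlusion-ordered cycles, with the perfusion-compromise
#' exclusion rule: the first five cycles are always retained; each further
#' cycle is admitted only if the incremental slope between its point and the
#' previous retained point is non-negative, otherwise it is excluded with
#' reason `"negative-slope"` (volume/pressure reduction impairing cardiac
#' perfusion).
#'
#' @param cycle_metrics Tibble from [pv_cycle_metrics()], ordered by
#'   occlusion time.
#' @param points Which points to fit: `"es"` (ESPVR) or `"ed"` (EDPVR).
#' @return An object of class `pv_fit`: `slope` (mmHg/uL), `intercept`
#'   (mmHg), `r_squared`, `included_cycles`, `excluded` (tibble with
#'   reasons), `points` and the fitted point table.
#' @export
fit_espvr <- function(cycle_metrics, points = c("es", "ed")) {
  points <- match.arg(points)
  cm <- cycle_metrics
  if (!is.data.frame(cm) || nrow(cm) < 5) {
    abort("at least 5 cycles are required to fit a PV relationship",
      class = "cardiophen_insufficient_data"
    )
  }
  if (nrow(cm) > 16) {
    warn("more than 16 cycles supplied; all are considered")
  }
  vol <- cm[[paste0(points, "_volume")]]
  pre <- cm[[paste0(points, "_pressure")]]

  included <- seq_len(min(5L, nrow(cm)))
  excluded <- integer(0)
  reasons <- character(0)
  if (nrow(cm) > 5) {
    for (i in 6:nrow(cm)) {
      prev <- tail(included, 1)
      dv <- vol[i] - vol[prev]
      dp <- pre[i] - pre[prev]
      if (dv == 0 || dp / dv < 0) {
        excluded <- c(excluded, i)
        reasons <- c(reasons, "negative-slope")
      } else {
        included <- c(included, i)
      }
    }
  }
  if (stats::sd(vol[included]) < 1e-12) {
    abort("degenerate regressor: all included volumes identical",
      class = "cardiophen_fit_error"
    )
  }
  fit <- stats::lm(pre[included] ~ vol[included])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pre[included] - mean(pre[included]))^2)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      included_cycles = cm$cycle[included],
      excluded = tibble::tibble(cycle = cm$cycle[excluded], reason = reasons),
      points = points,
      data = tibble::tibble(
        cycle = cm$cycle, volume = vol, pressure = pre,
        included = seq_len(nrow(cm)) %in% included
      )
    ),
    class = "pv_fit"
  )
}

#' @rdname fit_espvr
#' @export
fit_edpvr <- function(cycle_metrics) fit_espvr(cycle_metrics, points = "ed")

#' @export
print.pv_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit: slope %.3f mmHg/uL, intercept %.2f mmHg, r^2 %.4f (%d included, %d excluded)\n",
    if (x$points == "es") "ESPVR" else "EDPVR",
    x$slope, x$intercept, x$r_squared,
    length(x$included_cycles), nrow(x$excluded)
  ))
  invisible(x)
}

#' @export
tidy.pv_fit <- function(x, ...) x$data

#' @export
glance.pv_fit <- function(x, ...) {
  tibble::tibble(
    relationship = if (x$points == "es") "ESPVR" else "EDPVR",
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    n_included = length(x$included_cycles), n_excluded = nrow(x$excluded)
  )
}

#' @export
autoplot.pv_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(
    x = .data$volume, y = .data$pressure, shape = .data$included
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "volume (uL)", y = "pressure (mmHg)",
      title = sprintf(
        "%s: slope %.2f mmHg/uL",
        if (object$points == "es") "ESPVR" else "EDPVR", object$slope
      )
    )
}

# Internal: pull pressure/volume channels out of a trace data frame.
pv_trace <- function(trace) {
  tr <- as_trace_frame(trace, n_channels = 2L)
  ip <- grep("^pressure", tr$channels)[1]
  iv <- grep("^volume", tr$channels)[1]
  if (is.na(ip)) ip <- 1L
  if (is.na(iv)) iv <- setdiff(1:2, ip)[1]
  list(
    time = tr$time, sampling_rate = tr$sampling_rate,
    pressure = tr$values[[ip]], volume = tr$values[[iv]]
  )
}
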