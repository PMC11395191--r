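# Trace reading/writing and the internal uniform-trace representation.

# Validate a trace data frame (time + channel columns) and return a light
# internal representation: time vector, sampling rate, channel list.
as_trace_frame <- function(trace, n_channels = NULL) {
  if (!is.data.frame(trace) || ncol(trace) < 2) {
    abort("trace must be a data frame with a time column and >= 1 channel",
      class = "cardiophen_format_error"
    )
  }
  time_col <- grep("^time", names(trace))[1]
  if (is.na(time_col)) time_col <- 1L
  time <- trace[[time_col]]
  if (any(diff(time) <= 0)) {
    abort(
      sprintf("time column `%s` is not strictly increasing", names(trace)[time_col]),
      class = "cardiophen_format_error"
    )
  }
  dt <- stats::median(diff(time))
  channels <- setdiff(seq_along(trace), time_col)
  if (!is.null(n_channels) && length(channels) < n_channels) {
    abort(
      sprintf("trace has %d channel(s); %d required", length(channels), n_channels),
      class = "cardiophen_format_error"
    )
  }
  if (!is.null(n_channels)) channels <- channels[seq_len(n_channels)]
  list(
    time = time,
    sampling_rate = 1 / dt,
    channels = names(trace)[channels],
    values = lapply(channels, function(j) trace[[j]])
  )
}

#' Read a time-series trace from CSV
#'
#' Expects a `time_s` column followed by channel columns whose names carry
#' unit suffixes (e.g. `voltage_mV`, `pressure_mmHg`, `volume_uL`). The time
#' axis must be strictly increasing; sampling is checked for uniformity
#' (inter-sample deviation below 1% of the median interval). Mild timing
#' jitter is accepted with the sampling interval taken as the median; larger
#' jitter triggers linear resampling onto a uniform grid with a warning.
#'
#' @param path Path to a CSV file.
#' @param expected_channels Optional character vector of required channel
#'   names (matched as prefixes, so `"pressure"` matches `pressure_mmHg`).
#' @return A tibble with the time column first.
#' @export
read_trace <- function(path, expected_channels = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  time_col <- grep("^time", names(df))[1]
  if (is.na(time_col)) {
    abort("no `time` column found in trace file", class = "cardiophen_format_error")
  }
  for (ch in expected_channels) {
    if (!any(startsWith(names(df), ch))) {
      abort(sprintf("missing channel `%s` in %s", ch, path),
        class = "cardiophen_format_error"
      )
    }
  }
  time <- df[[time_col]]
  if (any(diff(time) <= 0)) {
    abort(
      sprintf("time column `%s` is not strictly increasing in %s", names(df)[time_col], path),
      class = "cardiophen_format_error"
    )
  }
  dt <- stats::median(diff(time))
  dev <- max(abs(diff(time) - dt))
  if (dev >= 0.05 * dt) {
    warn(sprintf(
      "timing jitter %.1f%% of dt: resampling onto a uniform grid", 100 * dev / dt
    ))
    grid <- seq(time[1], tail(time, 1), by = dt)
    df <- dplyr::bind_cols(
      tibble::tibble(!!names(df)[time_col] := grid),
      purrr::map_dfc(df[-time_col], function(y) stats::approx(time, y, xout = grid)$y)
    )
  } else if (dev >= 0.01 * dt) {
    warn(sprintf("timing jitter %.2f%% of dt accepted; dt = median interval", 100 * dev / dt))
  }
  df
}

#' Write a trace to CSV
#'
#' @param trace Data frame with the time column first.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation (trace + ground-truth sidecar) to disk
#'
#' Writes the simulated trace as `<name>.csv`, any stimulus times as
#' `<name>.stim.csv`, and all remaining ground-truth fields as a JSON sidecar
#' `<name>.truth.json`.
#'
#' @param sim A simulation result from one of the `simulate_*()` generators.
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(trace = file.path(dir, paste0(name, ".csv")))
  write_trace(sim$trace, files[["trace"]])
  if (!is.null(sim$stimulus_times_s)) {
    files[["stimuli"]] <- file.path(dir, paste0(name, ".stim.csv"))
    utils::write.csv(
      data.frame(stimulus_time_s = sim$stimulus_times_s),
      files[["stimuli"]], row.names = FALSE, quote = FALSE
    )
  }
  truth <- sim[setdiff(names(sim), c("trace", "stimulus_times_s"))]
  files[["truth"]] <- file.path(dir, paste0(name, ".truth.json"))
  jsonlite::write_json(truth, files[["truth"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(files)
}
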