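# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# Averaged transient object from an explicit ratio waveform.
make_averaged_transient <- function(ratio, sampling_rate = 250,
                                    period_ms = length(ratio) / sampling_rate * 1000,
                                    n_averaged = 1L) {
  structure(
    list(
      data = tibble::tibble(
        time_ms = (seq_along(ratio) - 1) / sampling_rate * 1000,
        ratio = ratio
      ),
      sampling_rate = sampling_rate,
      period_ms = period_ms,
      n_transients_averaged = n_averaged
    ),
    class = "averaged_transient"
  )
}

# Full ECG analysis of one simulated animal; returns the qt_result.
analyze_ecg_animal <- function(...) {
  sim <- simulate_ecg(...)
  suppressWarnings(qt_variation(sim$trace))
}

# Full calcium chain on one simulated cell.
analyze_fura <- function(sim) {
  sim$trace |>
    subtract_background(sim$stimulus_times_s) |>
    ensemble_average() |>
    transient_metrics()
}

# Permutation p-value of the pooled t statistic (oracle for the Student
# test; with equal-variance normal data the two agree closely).
permutation_p <- function(x, y, n_perm = 2000, seed = 1) {
  pool <- c(x, y)
  nx <- length(x)
  ny <- length(y)
  t_of <- function(a, b) {
    sp <- ((nx - 1) * stats::var(a) + (ny - 1) * stats::var(b)) / (nx + ny - 2)
    (mean(a) - mean(b)) / sqrt(sp * (1 / nx + 1 / ny))
  }
  obs <- abs(t_of(x, y))
  set.seed(seed)
  more <- replicate(n_perm, {
    idx <- sample.int(length(pool), nx)
    abs(t_of(pool[idx], pool[-idx])) >= obs - 1e-12
  })
  mean(more)
}
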