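#' Simulate left-ventricular pressure-volume loops under preload reduction
#'
#' Time-varying elastance model in which the true end-systolic and
#' end-diastolic pressure-volume relationships are exactly linear by
#' construction. During systole the activation rises as
#' `E(t) = Ees * (1 - cos(2 * pi * t / T_sys)) / 2`, and pressure blends the
#' systolic and diastolic relationships,
#' `P = [E + (1 - E/Ees) * S_ed] * (V - V0)`, so that at peak activation the
#' working point lies exactly on `P = Ees * (V - V0)` and at end-diastole on
#' `P = S_ed * (V - V0)`. Successive cycles reduce end-diastolic volume by a
#' fixed decrement, emulating an inferior vena cava occlusion ramp.
#'
#' The last `n_corrupt_tail_cycles` cycles carry a perfusion-compromise
#' artifact: activation is depressed and ejection collapses, so their
#' end-systolic volume rises while pressure falls. Including such a cycle
#' makes the incremental end-systolic slope against the previous retained
#' cycle negative, which is exactly the failure mode the fitting-stage
#' exclusion rule targets.
#'
#' @param sampling_rate Hz.
#' @param heart_rate BPM.
#' @param ees_true True end-systolic elastance (ESPVR slope), mmHg/uL.
#' @param v0 Volume-axis intercept, uL.
#' @param edpvr_slope_true True EDPVR slope, mmHg/uL.
#' @param edv_start End-diastolic volume of the first cycle, uL.
#' @param occlusion_cycles Number of cycles (5-16).
#' @param edv_decrement_per_cycle EDV reduction per cycle, uL.
#' @param ejection_fraction_of_reserve Fraction of (EDV - V0) ejected each
#'   cycle in uncorrupted cycles.
#' @param noise_sd_pressure,noise_sd_volume Additive white-noise SDs.
#' @param n_corrupt_tail_cycles Number of trailing perfusion-compromised
#'   cycles.
#' @param seed Integer seed.
#'
#' @return List with `trace` (tibble `time_s`, `pressure_mmHg`, `volume_uL`),
#'   `cycles` (per-cycle ground truth: true EDV/ESV and end-systolic point,
#'   corrupt flag), `ees_true`, `edpvr_slope_true`, `v0`,
#'   `corrupt_cycles` (indices), and `spec`.
#' @examples
#' sim <- simulate_pv(seed = 1)
#' fit_espvr(pv_cycle_metrics(sim$trace))
#' @export
simulate_pv <- function(sampling_rate = 1000,
                        heart_rate = 400,
                        ees_true = 6.0,
                        v0 = 5,
                        edpvr_slope_true = 0.18,
                        edv_start = 40,
                        occlusion_cycles = 10,
                        edv_decrement_per_cycle = 2,
                        ejection_fraction_of_reserve = 0.6,
                        noise_sd_pressure = 0,
                        noise_sd_volume = 0,
                        n_corrupt_tail_cycles = 0,
                        seed = NULL) {
  check_positive(sampling_rate, "sampling_rate")
  check_positive(heart_rate, "heart_rate")
  check_positive(ees_true, "ees_true")
  check_nonneg(edpvr_slope_true, "edpvr_slope_true")
  if (edpvr_slope_true >= ees_true) {
    abort_param("edpvr_slope_true", "must be below ees_true")
  }
  n_cyc <- check_count(occlusion_cycles, "occlusion_cycles", min = 1L)
  if (n_cyc < 5 || n_cyc > 16) {
    abort_param("occlusion_cycles", "must be within 5-16 cycles")
  }
  check_nonneg(edv_decrement_per_cycle, "edv_decrement_per_cycle")
  n_corrupt <- check_count(n_corrupt_tail_cycles, "n_corrupt_tail_cycles")
  if (n_corrupt >= n_cyc - 4L) {
    abort_param("n_corrupt_tail_cycles", "must leave at least 5 clean cycles")
  }
  if (edv_start <= v0) abort_param("edv_start", "must exceed v0")
  edv <- edv_start - (seq_len(n_cyc) - 1) * edv_decrement_per_cycle
  if (any(edv <= v0 + 1)) {
    abort_param("edv_decrement_per_cycle", "EDV would fall to v0 during the occlusion ramp")
  }

  with_seed(seed, {
    t_rr <- 60 / heart_rate
    frac <- ejection_fraction_of_reserve
    # snap the systolic interval so peak elastance falls exactly on a sample
    n_per <- as.integer(round(t_rr * sampling_rate))
    t_rr <- n_per / sampling_rate
    k_peak <- max(2L, as.integer(round(0.225 * n_per)))
    t_sys <- 2 * k_peak / sampling_rate

    corrupt <- if (n_corrupt > 0) (n_cyc - n_corrupt + 1L):n_cyc else integer(0)
    gamma_e <- rep(1, n_cyc) # elastance depression factor
    phi_e <- rep(1, n_cyc) # ejection collapse factor
    if (n_corrupt > 0) {
      # growing depression of activation with collapsing ejection: the
      # end-systolic volume rises while pressure falls, so the incremental
      # slope against the last healthy cycle is negative
      j <- seq_len(n_corrupt)
      gamma_e[corrupt] <- 0.45^j
      phi_e[corrupt] <- pmax(0.5^j, 0.3) # keep a visible volume dip per cycle
    }
    sv <- frac * phi_e * (edv - v0)
    esv <- edv - sv
    edv_next <- c(edv[-1], edv[n_cyc] - edv_decrement_per_cycle)

    n <- n_per * n_cyc + 1L
    time_s <- (seq_len(n) - 1) / sampling_rate
    p <- numeric(n)
    v <- numeric(n)
    for (c in seq_len(n_cyc)) {
      idx <- ((c - 1L) * n_per + 1L):(c * n_per + 1L)
      tt <- time_s[idx] - (c - 1) * t_rr
      act <- ifelse(tt <= t_sys, (1 - cos(2 * pi * tt / t_sys)) / 2, 0)
      ej_phase <- tt <= t_sys / 2
      vol <- ifelse(
        ej_phase,
        edv[c] - sv[c] * (1 - cos(2 * pi * tt / t_sys)) / 2,
        esv[c] + (edv_next[c] - esv[c]) *
          (1 - cos(pi * (tt - t_sys / 2) / (t_rr - t_sys / 2))) / 2
      )
      e_t <- gamma_e[c] * ees_true * act
      blend <- e_t + (1 - e_t / ees_true) * edpvr_slope_true
      p[idx] <- blend * (vol - v0)
      v[idx] <- vol
    }
    if (noise_sd_pressure > 0) p <- p + stats::rnorm(n, 0, noise_sd_pressure)
    if (noise_sd_volume > 0) v <- v + stats::rnorm(n, 0, noise_sd_volume)

    cycles <- tibble::tibble(
      cycle = seq_len(n_cyc),
      edv_true = edv,
      esv_true = esv,
      es_volume_true = esv,
      es_pressure_true = (gamma_e * ees_true +
        (1 - gamma_e) * edpvr_slope_true) * (esv - v0),
      ed_pressure_true = edpvr_slope_true * (edv - v0),
      corrupt = seq_len(n_cyc) %in% corrupt
    )

    list(
      trace = tibble::tibble(time_s = time_s, pressure_mmHg = p, volume_uL = v),
      cycles = cycles,
      ees_true = ees_true,
      edpvr_slope_true = edpvr_slope_true,
      v0 = v0,
      corrupt_cycles = corrupt,
      spec = list(
        sampling_rate = sampling_rate, heart_rate = heart_rate,
        ees_true = ees_true, v0 = v0, edpvr_slope_true = edpvr_slope_true,
        edv_start = edv_start, occlusion_cycles = n_cyc,
        edv_decrement_per_cycle = edv_decrement_per_cycle,
        ejection_fraction_of_reserve = frac,
        noise_sd_pressure = noise_sd_pressure,
        noise_sd_volume = noise_sd_volume,
        n_corrupt_tail_cycles = n_corrupt, seed = seed
      )
    )
  })
}
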