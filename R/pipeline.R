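#' Build a configuration for the end-to-end phenotyping pipeline
#'
#' The defaults describe a two-genotype mouse study: wild-type-like and
#' knockout-like group parameters for echo geometry, windowed QT variation,
#' end-systolic elastance, and calcium-transient kinetics, with
#' between-animal variability chosen so group SEMs land in the range typical
#' of cohorts of 10-14 animals. All randomness derives from the single
#' `seed`.
#'
#' @param seed Integer master seed.
#' @param n_animals Named vector of animals per genotype.
#' @param modalities Subset of `c("echo", "ecg", "pv", "ca")`.
#' @param params Optional list overriding per-modality group parameters; see
#'   the function body for the structure.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            n_animals = c(WT = 6, KO = 6),
                            modalities = c("echo", "ecg", "pv", "ca"),
                            params = list()) {
  defaults <- list(
    echo = list(
      lvid_d = c(WT = 3.0, KO = 3.7), lvid_d_sd = 0.3,
      lvid_s = c(WT = 1.9, KO = 2.8), lvid_s_sd = 0.35
    ),
    ecg = list(
      qt_cv = c(WT = 0.050, KO = 0.083),
      heart_rate = c(WT = 430, KO = 410), heart_rate_sd = 25,
      qt_true_ms = 28, duration_s = 30
    ),
    pv = list(
      ees = c(WT = 6.0, KO = 3.9), ees_sd = 0.8,
      edpvr = c(WT = 0.18, KO = 0.25),
      occlusion_cycles = 12, noise_sd_pressure = 0.5, noise_sd_volume = 0.2
    ),
    ca = list(
      amplitude = c(WT = 0.107, KO = 0.083), amplitude_sd = 0.015,
      baseline = c(WT = 0.246, KO = 0.225),
      tau_ms = c(WT = 40, KO = 43), n_transients = 60, noise_sd = 2
    )
  )
  structure(
    list(
      seed = as.integer(seed),
      n_animals = n_animals,
      modalities = modalities,
      params = modifyList(defaults, params)
    ),
    class = "pipeline_config"
  )
}

#' Run the full synthetic two-genotype phenotyping pipeline
#'
#' For every animal, simulates the requested modalities (seeded
#' deterministically from the master seed), analyzes each trace with the
#' package's estimators, assembles the per-animal parameter table, applies
#' the a-priori outlier rule, and tests every parameter between genotypes.
#' A failing stage is recorded as failed while the remaining stages
#' complete.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, `report.json` and
#'   `report.md` are written there (byte-identical on re-run with the same
#'   config).
#' @return A `phenotype_report`: list with `config`, `config_hash`,
#'   `stages`, `animals` (per-animal parameter tibble), `tests`,
#'   `exit_status` (0 iff all requested stages succeeded).
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 7, n_animals = c(WT = 4, KO = 4),
#'   modalities = "echo"
#' ))
#' rep$tests
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  genotypes <- names(config$n_animals)
  seeds <- child_seeds(config$seed, sum(config$n_animals) * 8L)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seeds[seed_i]
  }

  animal_ids <- unlist(lapply(genotypes, function(g) {
    sprintf("%s_%02d", g, seq_len(config$n_animals[[g]]))
  }))
  animal_geno <- rep(genotypes, times = unlist(config$n_animals))

  stage_rows <- list()
  animal_rows <- list()
  known <- c("echo", "ecg", "pv", "ca")

  for (mod in config$modalities) {
    res <- tryCatch(
      {
        if (!mod %in% known) {
          abort(sprintf("unknown modality `%s`", mod), class = "cardiophen_config_error")
        }
        fn <- switch(mod,
          echo = pipeline_stage_echo, ecg = pipeline_stage_ecg,
          pv = pipeline_stage_pv, ca = pipeline_stage_ca
        )
        rows <- purrr::map2_dfr(animal_ids, animal_geno, function(id, g) {
          fn(config$params[[mod]], g, next_seed()) |>
            dplyr::mutate(genotype = g, animal_id = id, .before = 1)
        })
        list(status = "ok", message = "", rows = rows)
      },
      error = function(e) list(status = "failed", message = conditionMessage(e), rows = NULL)
    )
    stage_rows[[mod]] <- tibble::tibble(
      stage = mod, status = res$status, message = res$message
    )
    if (!is.null(res$rows)) animal_rows[[mod]] <- res$rows
  }

  animals <- if (length(animal_rows)) {
    dplyr::bind_rows(animal_rows) |>
      tidyr::pivot_longer(
        -c("genotype", "animal_id"),
        names_to = "parameter", values_to = "value"
      ) |>
      dplyr::filter(is.finite(.data$value))
  } else {
    tibble::tibble(
      genotype = character(), animal_id = character(),
      parameter = character(), value = numeric()
    )
  }

  tests <- if (nrow(animals)) {
    purrr::map_dfr(unique(animals$parameter), function(p) {
      sub <- animals[animals$parameter == p, ]
      res <- suppressWarnings(compare_groups(sub, outlier_rule = TRUE))
      gs <- res$group_stats
      tibble::tibble(
        parameter = p,
        group_1 = gs$group[1], mean_1 = gs$mean[1], sem_1 = gs$sem[1],
        n_1 = gs$n[1] - gs$excluded_n[1],
        group_2 = gs$group[2], mean_2 = gs$mean[2], sem_2 = gs$sem[2],
        n_2 = gs$n[2] - gs$excluded_n[2],
        excluded = sum(gs$excluded_n),
        t_statistic = res$t_statistic,
        degrees_of_freedom = res$degrees_of_freedom,
        p_value = res$p_value, method = res$method
      )
    })
  } else {
    tibble::tibble()
  }

  stages <- dplyr::bind_rows(stage_rows)
  report <- structure(
    list(
      config = unclass(config),
      config_hash = rlang::hash(unclass(config)),
      stages = stages,
      animals = animals,
      tests = tests,
      exit_status = if (all(stages$status == "ok")) 0L else 1L
    ),
    class = "phenotype_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

pipeline_stage_echo <- function(p, g, seed) {
  with_seed(seed, {
    lvid_d <- stats::rnorm(1, p$lvid_d[[g]], p$lvid_d_sd)
    lvid_s <- stats::rnorm(1, p$lvid_s[[g]], p$lvid_s_sd)
    lvid_d <- max(lvid_d, 1)
    lvid_s <- min(max(lvid_s, 0.5), lvid_d - 0.05)
    d <- suppressWarnings(echo_derive(tibble::tibble(lvid_d = lvid_d, lvid_s = lvid_s)))
    tibble::tibble(
      lvid_d_mm = lvid_d, lvid_s_mm = lvid_s, fs_pct = d$fs_pct,
      edv_uL = d$edv_uL, esv_uL = d$esv_uL, sv_uL = d$sv_uL, ef_pct = d$ef_pct
    )
  })
}

pipeline_stage_ecg <- function(p, g, seed) {
  hr <- with_seed(seed, stats::rnorm(1, p$heart_rate[[g]], p$heart_rate_sd))
  hr <- min(max(hr, 320), 520)
  sim <- simulate_ecg(
    duration_s = p$duration_s, heart_rate = hr, qt_true_ms = p$qt_true_ms,
    qt_window_drift_cv = p$qt_cv[[g]], seed = seed + 1L
  )
  res <- suppressWarnings(qt_variation(sim$trace))
  tibble::tibble(
    qt_mean_ms = res$qt_mean_ms, qt_cv = res$qt_cv,
    heart_rate_bpm = res$heart_rate_bpm
  )
}

pipeline_stage_pv <- function(p, g, seed) {
  ees <- with_seed(seed, max(stats::rnorm(1, p$ees[[g]], p$ees_sd), 0.8))
  sim <- simulate_pv(
    ees_true = ees, edpvr_slope_true = p$edpvr[[g]],
    occlusion_cycles = p$occlusion_cycles,
    noise_sd_pressure = p$noise_sd_pressure,
    noise_sd_volume = p$noise_sd_volume, seed = seed + 1L
  )
  cm <- pv_cycle_metrics(sim$trace, v0 = sim$v0)
  es <- fit_espvr(cm)
  ed <- fit_edpvr(cm)
  tibble::tibble(
    espvr_slope = es$slope, edpvr_slope = ed$slope,
    dpdt_max = max(cm$dpdt_max), dpdt_min = min(cm$dpdt_min),
    es_pressure = cm$es_pressure[1], ed_pressure = cm$ed_pressure[1]
  )
}

pipeline_stage_ca <- function(p, g, seed) {
  amp <- with_seed(seed, max(stats::rnorm(1, p$amplitude[[g]], p$amplitude_sd), 0.02))
  sim <- suppressWarnings(simulate_fura(
    amplitude_true = amp, baseline_ratio = p$baseline[[g]],
    tau_ms = p$tau_ms[[g]], n_transients = p$n_transients,
    noise_sd = p$noise_sd, background_duration_s = 5, seed = seed + 1L
  ))
  m <- sim$trace |>
    subtract_background(sim$stimulus_times_s) |>
    ensemble_average() |>
    transient_metrics()
  tibble::tibble(
    ca_baseline = m$baseline, ca_amplitude = m$peak_amplitude,
    ca_amplitude_pct = m$peak_amplitude_pct_baseline,
    ca_time_to_peak_ms = m$time_to_peak_ms,
    ca_t90_ms = m$time_to_90pct_baseline_ms, ca_tau_ms = m$tau_ms
  )
}

#' Write a phenotype report to disk
#'
#' Writes `report.json` (full report) and `report.md` (human-readable
#' summary). Output is deterministic: no timestamps, fixed number
#' formatting, so re-running the same seeded config reproduces the files
#' byte-identically.
#'
#' @param report A `phenotype_report`.
#' @param dir Output directory (created if needed).
#' @return Named vector of paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    report[c("config", "config_hash", "stages", "animals", "tests", "exit_status")],
    json_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  md_path <- file.path(dir, "report.md")
  lines <- c(
    "# Phenotype report",
    "",
    sprintf("- master seed: %d", report$config$seed),
    sprintf("- config hash: %s", report$config_hash),
    sprintf(
      "- animals: %s",
      paste(sprintf("%s = %d", names(report$config$n_animals), report$config$n_animals),
        collapse = ", "
      )
    ),
    "",
    "## Stages",
    "",
    sprintf(
      "- %s: %s%s", report$stages$stage, report$stages$status,
      ifelse(report$stages$message == "", "", paste0(" (", report$stages$message, ")"))
    ),
    "",
    "## Group comparisons",
    ""
  )
  if (nrow(report$tests)) {
    lines <- c(lines, sprintf(
      "- %s: %s %.4g +/- %.3g (n=%d) vs %s %.4g +/- %.3g (n=%d), t = %.3f, df = %g, p = %.4g [%s]",
      report$tests$parameter,
      report$tests$group_1, report$tests$mean_1, report$tests$sem_1, report$tests$n_1,
      report$tests$group_2, report$tests$mean_2, report$tests$sem_2, report$tests$n_2,
      report$tests$t_statistic, report$tests$degrees_of_freedom,
      report$tests$p_value, report$tests$method
    ))
  }
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(sprintf(
    "Phenotype report (seed %d, hash %s): %d/%d stages ok, %d animals, %d parameters tested\n",
    x$config$seed, x$config_hash,
    sum(x$stages$status == "ok"), nrow(x$stages),
    length(unique(x$animals$animal_id)), nrow(x$tests)
  ))
  invisible(x)
}

#' @export
tidy.phenotype_report <- function(x, ...) x$tests

#' @export
glance.phenotype_report <- function(x, ...) {
  tibble::tibble(
    seed = x$config$seed, config_hash = x$config_hash,
    stages_ok = sum(x$stages$status == "ok"), stages = nrow(x$stages),
    n_animals = length(unique(x$animals$animal_id)),
    n_tests = nrow(x$tests), exit_status = x$exit_status
  )
}
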