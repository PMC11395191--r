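#' Simulate a hierarchical two-genotype cohort table
#'
#' Draws animal-level effects `~ Normal(group_mean, animal_sd)` and, when
#' `cells_per_animal > 1`, cell-level values `~ Normal(animal_effect,
#' cell_sd)`; with one cell per animal the table is a flat two-group design.
#' Optionally plants outliers (values displaced by 3 total SDs, alternating
#' sign) that are flagged in the ground truth, exercising the a-priori 2-SD
#' exclusion rule downstream.
#'
#' @param n_animals_per_group Integer, or named length-2 vector giving the
#'   group sizes in the order of `group_means`.
#' @param cells_per_animal Cells measured per animal (1 = animal-level).
#' @param group_means Named numeric vector of true per-genotype means, e.g.
#'   `c(WT = 6.0, KO = 3.9)`.
#' @param animal_sd,cell_sd Between-animal and within-animal SDs.
#' @param parameter Name recorded in the `parameter` column.
#' @param outlier_inject Number of points to displace by 3 total SDs.
#' @param seed Integer seed.
#' @return Tibble with columns `genotype`, `animal_id`, `cell_id`,
#'   `parameter`, `value`, `outlier_true`; ground truth (per-animal effects)
#'   in attribute `"truth"`.
#' @examples
#' simulate_cohort(c(WT = 5, KO = 5), group_means = c(WT = 1, KO = 0), seed = 1)
#' @export
simulate_cohort <- function(n_animals_per_group,
                            cells_per_animal = 1,
                            group_means,
                            animal_sd = 0,
                            cell_sd = 0,
                            parameter = "value",
                            outlier_inject = 0,
                            seed = NULL) {
  if (is.null(names(group_means)) || length(group_means) != 2) {
    abort_param("group_means", "must be a named length-2 vector (e.g. c(WT = ..., KO = ...))")
  }
  if (length(n_animals_per_group) == 1) {
    n_animals_per_group <- setNames(
      rep(n_animals_per_group, 2), names(group_means)
    )
  }
  n_animals_per_group <- vapply(
    n_animals_per_group, check_count,
    integer(1), field = "n_animals_per_group", min = 2L
  )
  cells <- check_count(cells_per_animal, "cells_per_animal", min = 1L)
  check_nonneg(animal_sd, "animal_sd")
  check_nonneg(cell_sd, "cell_sd")
  n_out <- check_count(outlier_inject, "outlier_inject")

  with_seed(seed, {
    tab <- purrr::map2_dfr(
      names(group_means), n_animals_per_group[names(group_means)],
      function(g, n_a) {
        animal_eff <- stats::rnorm(n_a, group_means[[g]], animal_sd)
        purrr::map_dfr(seq_len(n_a), function(a) {
          tibble::tibble(
            genotype = g,
            animal_id = sprintf("%s_%02d", g, a),
            cell_id = if (cells > 1) sprintf("c%02d", seq_len(cells)) else NA_character_,
            parameter = parameter,
            value = if (cells > 1) {
              stats::rnorm(cells, animal_eff[a], cell_sd)
            } else {
              animal_eff[a]
            },
            animal_effect_true = animal_eff[a]
          )
        })
      }
    )
    tab$outlier_true <- FALSE
    if (n_out > 0) {
      total_sd <- sqrt(animal_sd^2 + cell_sd^2)
      if (total_sd == 0) total_sd <- 0.5 * max(abs(unlist(group_means)), 1)
      rows <- sample.int(nrow(tab), min(n_out, nrow(tab)))
      sign <- rep(c(1, -1), length.out = length(rows))
      tab$value[rows] <- group_means[tab$genotype[rows]] + sign * 3 * total_sd
      tab$outlier_true[rows] <- TRUE
    }
    truth <- list(
      group_means = as.list(group_means),
      animal_sd = animal_sd, cell_sd = cell_sd,
      outlier_rows = which(tab$outlier_true)
    )
    out <- tab[c("genotype", "animal_id", "cell_id", "parameter", "value", "outlier_true")]
    attr(out, "truth") <- truth
    out
  })
}
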