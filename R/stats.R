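#' A-priori two-standard-deviation outlier exclusion
#'
#' Single-pass rule applied independently per group: compute the mean and
#' sample SD of all values in the group, flag points with `|z| > 2`, and
#' exclude at most two per group (if more qualify, the two with the largest
#' `|z|` are excluded with a warning). Means and SDs are not recomputed
#' after removal. Groups with fewer than 3 values are skipped with a
#' warning.
#'
#' @param data Data frame of per-animal (or per-point) values.
#' @param value_col,group_col Column names of the value and grouping
#'   variable.
#' @return The input tibble with a logical `outlier` column appended
#'   (`TRUE` = excluded).
#' @examples
#' df <- tibble::tibble(g = "a", v = c(rep(0, 10), 10))
#' exclude_outliers(df, "v", "g")
#' @export
exclude_outliers <- function(data, value_col = "value", group_col = "genotype") {
  df <- tibble::as_tibble(data)
  stopifnot(value_col %in% names(df), group_col %in% names(df))
  df$outlier <- FALSE
  for (g in unique(df[[group_col]])) {
    idx <- which(df[[group_col]] == g)
    x <- df[[value_col]][idx]
    if (length(x) < 3) {
      warn(sprintf("group `%s` has < 3 values: outlier rule skipped", g))
      next
    }
    s <- stats::sd(x)
    if (s == 0) next
    z <- abs(x - mean(x)) / s
    flag <- which(z > 2)
    if (length(flag) > 2) {
      warn(sprintf(
        "group `%s`: %d points exceed 2 SD; only the 2 most extreme excluded",
        g, length(flag)
      ))
      flag <- flag[order(z[flag], decreasing = TRUE)][1:2]
    }
    df$outlier[idx[flag]] <- TRUE
  }
  df
}

#' Unpaired two-tailed Student's t test
#'
#' Pooled-variance two-sample t test (`df = nA + nB - 2`) by default;
#' `var_equal = FALSE` gives the Welch variant. Zero-variance degeneracies
#' are handled explicitly: identical group means give `t = 0, p = 1`;
#' differing means with zero pooled variance give `p = 0` flagged
#' degenerate.
#'
#' @param x,y Numeric samples for the two groups.
#' @param var_equal Pool the variances (classical Student's test)?
#' @return A `group_test` object: list with `group_stats` (mean, SEM, n per
#'   group), `t_statistic`, `degrees_of_freedom`, `p_value`, `method`,
#'   `degenerate`.
#' @examples
#' student_t(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 values", class = "cardiophen_insufficient_data")
  }
  nx <- length(x)
  ny <- length(y)
  pooled_var <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  degenerate <- FALSE
  if (pooled_var == 0) {
    if (mean(x) == mean(y)) {
      t_stat <- 0
      p <- 1
      dof <- nx + ny - 2
    } else {
      t_stat <- sign(mean(x) - mean(y)) * Inf
      p <- 0
      dof <- nx + ny - 2
      degenerate <- TRUE
      warn("zero within-group variance with unequal means: p -> 0 (degenerate)")
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = var_equal)
    t_stat <- unname(ht$statistic)
    dof <- unname(ht$parameter)
    p <- ht$p.value
  }
  new_group_test(
    group_stats = tibble::tibble(
      group = c("x", "y"),
      n = c(nx, ny),
      mean = c(mean(x), mean(y)),
      sem = c(stats::sd(x) / sqrt(nx), stats::sd(y) / sqrt(ny))
    ),
    t_statistic = t_stat, degrees_of_freedom = dof, p_value = p,
    method = if (var_equal) "student_t" else "welch_t",
    degenerate = degenerate
  )
}

#' Hierarchical (nested) two-group t test for cell-level data
#'
#' One-way nested ANOVA with animals nested in genotype: the genotype effect
#' is tested against the between-animal (within-genotype) mean square, which
#' guards against pseudoreplication when several cells are measured per
#' animal. Reported as `t = sign(difference) * sqrt(F)` with denominator
#' degrees of freedom `n_animals - 2`. With one cell per animal this reduces
#' exactly to the pooled Student's t test; `method = "animal_means"` instead
#' runs the Student's t test on per-animal means.
#'
#' @param data Data frame with one row per cell.
#' @param value_col,group_col,animal_col Column names.
#' @param method `"nested_anova"` (default) or `"animal_means"`.
#' @return A `group_test` object; group means and SEMs are computed over
#'   per-animal means (n = animals).
#' @export
nested_t <- function(data, value_col = "value", group_col = "genotype",
                     animal_col = "animal_id",
                     method = c("nested_anova", "animal_means")) {
  method <- match.arg(method)
  df <- tibble::as_tibble(data)
  stopifnot(all(c(value_col, group_col, animal_col) %in% names(df)))
  groups <- unique(df[[group_col]])
  if (length(groups) != 2) {
    abort("exactly two groups are required", class = "cardiophen_data_error")
  }
  an_means <- df |>
    dplyr::group_by(.data[[group_col]], .data[[animal_col]]) |>
    dplyr::summarise(m = mean(.data[[value_col]]), n_cells = dplyr::n(), .groups = "drop")
  n_animals <- table(an_means[[group_col]])[as.character(groups)]
  if (any(n_animals < 2)) {
    abort("fewer than 2 animals in a group: no denominator degrees of freedom",
      class = "cardiophen_insufficient_data"
    )
  }

  g_stats <- an_means |>
    dplyr::group_by(.data[[group_col]]) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$m),
      sem = stats::sd(.data$m) / sqrt(dplyr::n()), .groups = "drop"
    ) |>
    dplyr::rename(group = 1)
  diff_sign <- sign(
    g_stats$mean[g_stats$group == groups[1]] - g_stats$mean[g_stats$group == groups[2]]
  )

  if (method == "animal_means") {
    m1 <- an_means$m[an_means[[group_col]] == groups[1]]
    m2 <- an_means$m[an_means[[group_col]] == groups[2]]
    res <- student_t(m1, m2)
    res$method <- "nested_t (animal means)"
    res$group_stats$group <- as.character(groups)
    return(res)
  }

  # nested ANOVA sums of squares at the cell level
  y <- df[[value_col]]
  grand <- mean(y)
  by_group <- split(y, df[[group_col]])
  ss_group <- sum(vapply(by_group, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  key <- interaction(df[[group_col]], df[[animal_col]], drop = TRUE)
  by_animal <- split(seq_along(y), key)
  ss_animal <- sum(vapply(by_animal, function(i) {
    g <- df[[group_col]][i[1]]
    length(i) * (mean(y[i]) - mean(by_group[[as.character(g)]]))^2
  }, numeric(1)))
  df_group <- 1L
  df_animal <- sum(n_animals) - 2L
  f_stat <- (ss_group / df_group) / (ss_animal / df_animal)
  p <- stats::pf(f_stat, df_group, df_animal, lower.tail = FALSE)

  new_group_test(
    group_stats = g_stats,
    t_statistic = diff_sign * sqrt(f_stat),
    degrees_of_freedom = df_animal, p_value = p,
    method = "nested_t", degenerate = FALSE
  )
}

#' Coefficient of variation (sample SD / mean)
#'
#' @param x Numeric vector (n >= 2, nonzero mean).
#' @return SD/mean, dimensionless.
#' @examples
#' coefficient_of_variation(c(27, 28, 27, 29, 28, 27)) # 0.0295
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2) {
    abort("at least 2 values required", class = "cardiophen_insufficient_data")
  }
  if (mean(x) == 0) {
    abort("coefficient of variation undefined for zero mean", class = "cardiophen_data_error")
  }
  sample_cv(x)
}

#' Relative expression by the Livak method with dual reference genes
#'
#' Per sample (or per group when no sample column is given), the reference
#' Ct is the arithmetic mean of the two reference genes' Ct values
#' (equivalently, the geometric mean of their abundances);
#' `dCt = Ct_target - Ct_ref`, `ddCt = mean dCt(treatment) - mean
#' dCt(control)`, and the fold change is `2^-ddCt`.
#'
#' @param ct_table Data frame with group, gene, and Ct columns.
#' @param target_gene Gene to quantify.
#' @param reference_genes Character vector of reference genes (e.g. Gapdh
#'   and Pol2ra).
#' @param control_group Group the fold change is expressed relative to.
#' @param group_col,gene_col,ct_col,sample_col Column names; `sample_col`
#'   may be `NULL` when each group's Ct values are already averaged.
#' @return Tibble with `ddct` and `fold_change`.
#' @examples
#' ct <- tibble::tibble(
#'   group = rep(c("WT", "KO"), each = 3),
#'   gene = rep(c("target", "Gapdh", "Pol2ra"), 2),
#'   ct = c(24, 20, 22, 25, 20, 22)
#' )
#' livak_fold_change(ct, "target", c("Gapdh", "Pol2ra"))
#' @export
livak_fold_change <- function(ct_table, target_gene, reference_genes,
                              control_group = "WT",
                              group_col = "group", gene_col = "gene",
                              ct_col = "ct", sample_col = NULL) {
  df <- tibble::as_tibble(ct_table)
  stopifnot(all(c(group_col, gene_col, ct_col) %in% names(df)))
  groups <- unique(df[[group_col]])
  if (!control_group %in% groups || length(groups) != 2) {
    abort("ct_table must contain the control group and exactly one other group",
      class = "cardiophen_data_error"
    )
  }
  for (g in groups) {
    present <- df[[gene_col]][df[[group_col]] == g]
    missing <- setdiff(c(target_gene, reference_genes), present)
    if (length(missing)) {
      abort(
        sprintf("group `%s` lacks gene(s): %s", g, paste(missing, collapse = ", ")),
        class = "cardiophen_data_error"
      )
    }
  }
  unit_cols <- c(group_col, if (!is.null(sample_col)) sample_col)
  dct <- df |>
    dplyr::filter(.data[[gene_col]] %in% c(target_gene, reference_genes)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(unit_cols))) |>
    dplyr::summarise(
      dct = mean(.data[[ct_col]][.data[[gene_col]] == target_gene]) -
        mean(vapply(
          reference_genes,
          function(rg) mean(.data[[ct_col]][.data[[gene_col]] == rg]),
          numeric(1)
        )),
      .groups = "drop"
    )
  mean_dct <- tapply(dct$dct, dct[[group_col]], mean)
  other <- setdiff(groups, control_group)
  ddct <- unname(mean_dct[other] - mean_dct[control_group])
  tibble::tibble(
    target_gene = target_gene,
    group = other,
    control = control_group,
    ddct = ddct,
    fold_change = 2^-ddct
  )
}

#' Compare two genotype groups with the study's statistical conventions
#'
#' Applies the a-priori 2-SD outlier rule to per-animal means, then runs the
#' appropriate two-group test: pooled Student's t for animal-level data, or
#' the hierarchical nested t when several cells per animal are present
#' (excluded animals are dropped entirely).
#'
#' @param data Cohort tibble with `genotype`, `animal_id`, optional
#'   `cell_id`, and `value` columns (as from [simulate_cohort()]).
#' @param value_col,group_col,animal_col Column names.
#' @param outlier_rule Apply [exclude_outliers()] to per-animal means first?
#' @param method `"auto"` picks nested vs Student by cells per animal;
#'   `"student"`, `"welch"`, and `"nested"` force a choice.
#' @return A `group_test` object with `excluded_n` per group recorded.
#' @export
compare_groups <- function(data, value_col = "value", group_col = "genotype",
                           animal_col = "animal_id", outlier_rule = TRUE,
                           method = c("auto", "student", "welch", "nested")) {
  method <- match.arg(method)
  df <- tibble::as_tibble(data)
  an_means <- df |>
    dplyr::group_by(.data[[group_col]], .data[[animal_col]]) |>
    dplyr::summarise(m = mean(.data[[value_col]]), n_cells = dplyr::n(), .groups = "drop")
  excluded_n <- setNames(
    rep(0L, length(unique(an_means[[group_col]]))), unique(an_means[[group_col]])
  )
  if (outlier_rule) {
    flagged <- exclude_outliers(an_means, value_col = "m", group_col = group_col)
    drop_animals <- flagged[[animal_col]][flagged$outlier]
    tab <- table(flagged[[group_col]][flagged$outlier])
    excluded_n[names(tab)] <- as.integer(tab)
    df <- df[!df[[animal_col]] %in% drop_animals, ]
  }
  multi_cell <- any(an_means$n_cells > 1)
  use_nested <- method == "nested" || (method == "auto" && multi_cell)
  res <- if (use_nested) {
    nested_t(df, value_col, group_col, animal_col)
  } else {
    groups <- unique(df[[group_col]])
    am <- df |>
      dplyr::group_by(.data[[group_col]], .data[[animal_col]]) |>
      dplyr::summarise(m = mean(.data[[value_col]]), .groups = "drop")
    out <- student_t(
      am$m[am[[group_col]] == groups[1]],
      am$m[am[[group_col]] == groups[2]],
      var_equal = method != "welch"
    )
    out$group_stats$group <- as.character(groups)
    out
  }
  res$group_stats$excluded_n <- excluded_n[res$group_stats$group]
  res
}

new_group_test <- function(group_stats, t_statistic, degrees_of_freedom,
                           p_value, method, degenerate) {
  structure(
    list(
      group_stats = group_stats, t_statistic = t_statistic,
      degrees_of_freedom = degrees_of_freedom, p_value = p_value,
      method = method, degenerate = degenerate
    ),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  gs <- x$group_stats
  cat(sprintf(
    "%s: t = %.3f, df = %g, p = %.4g\n", x$method,
    x$t_statistic, x$degrees_of_freedom, x$p_value
  ))
  for (i in seq_len(nrow(gs))) {
    cat(sprintf(
      "  %s: %.4g +/- %.3g (n = %d)\n",
      gs$group[i], gs$mean[i], gs$sem[i], gs$n[i]
    ))
  }
  invisible(x)
}

#' @export
tidy.group_test <- function(x, ...) x$group_stats

#' @export
glance.group_test <- function(x, ...) {
  tibble::tibble(
    t_statistic = x$t_statistic,
    degrees_of_freedom = x$degrees_of_freedom,
    p_value = x$p_value,
    method = x$method,
    degenerate = x$degenerate
  )
}
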