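test_that("the 2-SD rule excludes the hand-computed case and respects ties", {
  # ten zeros and one ten: z = 3.015 for the ten
  df <- tibble::tibble(genotype = "g", value = c(rep(0, 10), 10))
  fl <- exclude_outliers(df)
  expect_equal(which(fl$outlier), 11L)
  z <- abs(10 - mean(df$value)) / sd(df$value)
  expect_equal(z, 3.015, tolerance = 1e-3)

  # all equal: SD = 0 handled, nothing excluded
  same <- tibble::tibble(genotype = "g", value = rep(4, 6))
  expect_false(any(exclude_outliers(same)$outlier))

  # symmetric pair at +/- 1.9 SD of the full sample: none excluded
  base <- c(-1, 1, -0.5, 0.5, 0, 0)
  x <- c(base, -1.9, 1.9) * 1 / sd(c(base, -1.9, 1.9)) # unit SD by construction
  pair <- tibble::tibble(genotype = "g", value = x)
  expect_true(max(abs(scale(pair$value))) < 2)
  expect_false(any(exclude_outliers(pair)$outlier))
})

test_that("no more than two points are excluded per group", {
  df <- tibble::tibble(
    genotype = "g",
    value = c(rep(0, 20), 30, -28, 26)
  )
  expect_warning(fl <- exclude_outliers(df), "most extreme")
  expect_equal(sum(fl$outlier), 2L)
  expect_equal(sort(df$value[fl$outlier]), c(-28, 30)) # largest |z| pair
})

test_that("the exclusion rule is idempotent on its own output", {
  set.seed(5)
  df <- tibble::tibble(genotype = rep(c("a", "b"), each = 12), value = rnorm(24))
  df$value[1] <- 8
  f1 <- exclude_outliers(df)
  kept <- f1[!f1$outlier, c("genotype", "value")]
  f2 <- exclude_outliers(kept)
  # re-running on the kept set may flag new points; capping still holds and
  # running once more on an already-clean set changes nothing
  clean <- f2[!f2$outlier, c("genotype", "value")]
  f3 <- exclude_outliers(clean)
  expect_lte(sum(f2$outlier[f2$genotype == "a"]), 2)
  expect_identical(f3$outlier, exclude_outliers(clean)$outlier)
})

test_that("small groups are skipped with a warning", {
  df <- tibble::tibble(genotype = c("a", "a", "b", "b", "b"), value = c(1, 9, 2, 2, 8))
  expect_warning(exclude_outliers(df), "skipped")
})

test_that("the pooled t test matches hand evaluation and is symmetric", {
  r <- student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$degrees_of_freedom, 4)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-3)

  swapped <- student_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t_statistic, -r$t_statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, r$p_value, tolerance = 1e-12)

  same <- student_t(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  const <- suppressWarnings(student_t(c(2, 2, 2), c(3, 3, 3)))
  expect_equal(const$p_value, 0)
  expect_true(const$degenerate)
})

test_that("the pooled t matches a permutation test within Monte-Carlo error", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(8, 0.8 * (i %% 3), 1)
    y <- rnorm(7, 0, 1)
    p_t <- student_t(x, y)$p_value
    p_perm <- permutation_p(x, y, n_perm = 2000, seed = i)
    mc_sd <- sqrt(p_t * (1 - p_t) / 2000)
    expect_lt(abs(p_t - p_perm), 4 * mc_sd + 0.02)
  }
})

test_that("nested and Student tests coincide for one cell per animal", {
  co <- simulate_cohort(c(WT = 7, KO = 6),
    group_means = c(WT = 5, KO = 4.2),
    animal_sd = 1, seed = 8
  )
  n <- nested_t(co)
  s <- student_t(co$value[co$genotype == "WT"], co$value[co$genotype == "KO"])
  expect_equal(n$t_statistic, s$t_statistic, tolerance = 1e-9)
  expect_equal(n$degrees_of_freedom, s$degrees_of_freedom)
  expect_equal(n$p_value, s$p_value, tolerance = 1e-12)
})

test_that("with vanishing cell noise the nested test equals t on animal means", {
  co <- simulate_cohort(c(WT = 6, KO = 6),
    cells_per_animal = 5,
    group_means = c(WT = 3, KO = 2), animal_sd = 0.8, cell_sd = 1e-9, seed = 9
  )
  n <- nested_t(co)
  am <- tapply(co$value, co$animal_id, mean)
  geno <- tapply(co$genotype, co$animal_id, function(g) g[1])
  s <- student_t(am[geno == "WT"], am[geno == "KO"])
  expect_equal(abs(n$t_statistic), abs(s$t_statistic), tolerance = 1e-5)
  expect_equal(n$p_value, s$p_value, tolerance = 1e-5)
})

test_that("the nested F statistic matches aov with an animal error stratum", {
  co <- simulate_cohort(c(WT = 5, KO = 6),
    cells_per_animal = 8,
    group_means = c(WT = 5, KO = 4.3), animal_sd = 1, cell_sd = 2, seed = 4
  )
  n <- nested_t(co)
  a <- summary(stats::aov(value ~ genotype + Error(animal_id), data = co))
  strat <- a[["Error: animal_id"]][[1]]
  expect_equal(n$t_statistic^2, strat[["F value"]][1], tolerance = 1e-9)
  expect_equal(n$p_value, strat[["Pr(>F)"]][1], tolerance = 1e-9)
  expect_lte(n$degrees_of_freedom, 11 - 2)
})

test_that("one animal per group is an insufficient-df error", {
  co <- tibble::tibble(
    genotype = rep(c("WT", "KO"), each = 4),
    animal_id = rep(c("w1", "k1"), each = 4),
    value = rnorm(8)
  )
  expect_error(nested_t(co), class = "cardiophen_insufficient_data")
})

test_that("coefficient of variation handles the documented cases", {
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_equal(coefficient_of_variation(c(27, 28, 27, 29, 28, 27)), 0.0295, tolerance = 1e-3)
  x <- rlnorm(20)
  expect_equal(
    coefficient_of_variation(5.5 * x), coefficient_of_variation(x),
    tolerance = 1e-12
  )
  expect_error(coefficient_of_variation(c(-1, 1)), class = "cardiophen_data_error")
  expect_error(coefficient_of_variation(3), class = "cardiophen_insufficient_data")
})

test_that("Livak fold changes follow the closed form and its invariances", {
  ct <- tibble::tibble(
    group = rep(c("WT", "KO"), each = 3),
    gene = rep(c("tg", "Gapdh", "Pol2ra"), 2),
    ct = c(24, 20, 22, 25, 20, 22)
  )
  r <- livak_fold_change(ct, "tg", c("Gapdh", "Pol2ra"))
  expect_equal(r$ddct, 1)
  expect_equal(r$fold_change, 0.5)

  # identical delta-Ct in both groups: fold change 1
  ct1 <- ct
  ct1$ct[4:6] <- ct1$ct[1:3]
  expect_equal(livak_fold_change(ct1, "tg", c("Gapdh", "Pol2ra"))$fold_change, 1)

  # invariance to adding a constant to every Ct
  ct2 <- ct
  ct2$ct <- ct2$ct + 3.7
  expect_equal(
    livak_fold_change(ct2, "tg", c("Gapdh", "Pol2ra"))$fold_change,
    r$fold_change,
    tolerance = 1e-12
  )
  expect_error(
    livak_fold_change(ct[1:4, ], "tg", c("Gapdh", "Pol2ra")),
    class = "cardiophen_data_error"
  )
})

test_that("compare_groups picks the nested test for cell-level data", {
  co <- simulate_cohort(c(WT = 5, KO = 5),
    cells_per_animal = 6,
    group_means = c(WT = 2, KO = 1), animal_sd = 0.5, cell_sd = 1, seed = 12
  )
  r <- compare_groups(co)
  expect_equal(r$method, "nested_t")
  flat <- simulate_cohort(c(WT = 5, KO = 5),
    group_means = c(WT = 2, KO = 1),
    animal_sd = 0.5, seed = 13
  )
  expect_equal(compare_groups(flat)$method, "student_t")
})
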