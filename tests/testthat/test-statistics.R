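# Reliability and descriptive statistics against independent oracles.

test_that("Pearson correlation matches the closed-form sum formula", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1, 0.7)
  y <- c(2.0, 3.9, 2.5, 6.8, 3.3, 1.1)
  # direct sigma-formula oracle
  n <- length(x)
  rho_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  got <- pearson_cor(x, y)
  expect_equal(got$rho, rho_oracle, tolerance = 1e-12)
  expect_equal(got$n, 6)

  expect_equal(pearson_cor(x, x)$rho, 1)
  expect_equal(pearson_cor(x, -2 * x + 7)$rho, -1)
  # invariance under positive affine transforms
  expect_equal(pearson_cor(3 * x + 2, 0.5 * y - 4)$rho, got$rho)
  expect_error(pearson_cor(x, rep(1, 6)), class = "ffqscore_stat_error")
  expect_error(pearson_cor(x[1:2], y[1:2]), class = "ffqscore_stat_error")
})

# independent sums-of-squares oracle for the two-way single-measure ICC
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   meas = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + meas, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

test_that("ICC(2,1) equals the explicit ANOVA decomposition", {
  m <- cbind(c(9, 8, 7, 5, 4), c(10, 8, 6, 5, 2))
  fit <- icc2_single_absolute(m)
  expect_equal(fit$icc2, icc_oracle(m), tolerance = 1e-12)
  expect_true(fit$ci_lower <= fit$icc2 && fit$icc2 <= fit$ci_upper)

  # identical columns with subject variance -> perfect agreement
  perfect <- icc2_single_absolute(cbind(1:5, 1:5))
  expect_equal(perfect$icc2, 1)

  # constant column shift is penalised by absolute agreement
  shifted <- icc2_single_absolute(cbind(1:5, 1:5 + 1))
  expect_lt(shifted$icc2, 1)
  expect_lt(shifted$icc2, perfect$icc2)

  # degenerate input
  expect_error(icc2_single_absolute(matrix(3, 5, 2)),
               class = "ffqscore_stat_error")
  expect_warning(icc2_single_absolute(cbind(c(1, 2, 3), c(1.2, 2.1, 3.3))),
                 regexp = "unstable")
})

test_that("ICC never exceeds 1 and matches the oracle on random matrices", {
  set.seed(123)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    m <- matrix(rnorm(n * 2, 10, 3), n, 2)
    fit <- suppressWarnings(icc2_single_absolute(m))
    expect_equal(fit$icc2, icc_oracle(m), tolerance = 1e-10)
    expect_lte(fit$icc2, 1)
  }
})

test_that("Koo-Li bands classify with boundaries to the higher class", {
  expect_equal(classify_icc(0.62), "moderate")
  expect_equal(classify_icc(0.95), "excellent")
  expect_equal(classify_icc(0.11), "poor")
  expect_equal(classify_icc(c(0.5, 0.75, 0.9)),
               c("moderate", "good", "excellent"))
  expect_equal(classify_icc(0.4999), "poor")
  expect_error(classify_icc(1.2), class = "ffqscore_validation_error")
})

test_that("normality check keeps its type-I rate and detects skew", {
  expect_error(normality_check(c(1, 2)), class = "ffqscore_stat_error")
  expect_error(normality_check(rep(1, 10)), class = "ffqscore_stat_error")
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    normality_check(rnorm(100))$is_normal
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  rejects <- vapply(1:20, function(s) {
    set.seed(s)
    !normality_check(rexp(200))$is_normal
  }, logical(1))
  expect_gte(mean(rejects), 0.95)
})

test_that("two-sample t matches the closed-form Welch statistic", {
  x <- c(5.1, 6.3, 4.8, 7.0, 5.9)
  y <- c(4.2, 3.9, 5.0, 4.6, 3.5)
  welch_oracle <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  got <- two_sample_t(x, y)
  expect_equal(got$statistic, welch_oracle, tolerance = 1e-12)
  expect_equal(got$test, "welch_t")

  same <- two_sample_t(x, x, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(99)
  a <- rnorm(200, 0, 1); b <- rnorm(200, 0.5, 1)
  expect_lt(two_sample_t(a, b)$p_value, 0.05)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5)),
               class = "ffqscore_stat_error")
  expect_error(two_sample_t(1:4, 1:5, paired = TRUE),
               class = "ffqscore_validation_error")
})

test_that("chi-squared matches the explicit (O-E)^2/E oracle", {
  # diet-by-DFS-group counts: 32/3 omnivores/vegetarians in the high group,
  # 27/14 in the low group
  tab <- matrix(c(32, 3, 27, 14), 2, byrow = FALSE)
  o <- as.vector(tab)
  e <- as.vector(outer(rowSums(tab), colSums(tab)) / sum(tab))
  stat_oracle <- sum((o - e)^2 / e)
  got <- chisq_independence(tab)
  expect_equal(got$statistic, stat_oracle, tolerance = 1e-12)
  expect_equal(got$df, 1)

  flat <- chisq_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_equal(chisq_independence(10 * tab)$statistic, 10 * got$statistic)
  expect_error(chisq_independence(matrix(c(0, 0, 5, 5), 2)),
               class = "ffqscore_stat_error")
  expect_error(chisq_independence(matrix(1:3, 1)),
               class = "ffqscore_validation_error")
})

test_that("descriptive summary reports group stats and one-decimal percents", {
  one <- descriptive_summary(tibble::tibble(x = 4.2), "x")
  expect_equal(one$mean, 4.2)
  expect_equal(one$median, 4.2)
  expect_equal(one$min, one$max)
  expect_true(is.na(one$sd))

  counts <- descriptive_summary(dfs_diet_cohort(), "diet",
                                group_by = "dfs_group")
  omn_hfs <- counts[counts$dfs_group == "HFS" & counts$level == "OMN", ]
  expect_equal(omn_hfs$n, 32)
  expect_equal(omn_hfs$percent, 91.4)
  veg_lfs <- counts[counts$dfs_group == "LFS" & counts$level == "VEG", ]
  expect_equal(veg_lfs$percent, 34.1)

  # numeric + NA handling
  df <- tibble::tibble(g = c("a", "a", "a", "b", "b"),
                       v = c(1, 2, NA, 10, 14))
  st <- descriptive_summary(df, "v", group_by = "g")
  expect_equal(st$n, c(2, 2))
  expect_equal(st$mean, c(1.5, 12))
})

test_that("sample means of a generated cohort sit within sampling error", {
  sch <- demo_schema()
  ref <- demo_reference()
  cfg <- generator_config(n_subjects = 150, timepoints = "BL1",
                          recall_windows = 7, seed = 31)
  prof <- diet_profile(sex_energy_offset = 0, target_energy_sd = 400)
  sim <- generate_cohort(prof, cfg, sch, ref)
  st <- descriptive_summary(sim$truth, "latent_energy_kcal")
  se <- st$sd / sqrt(st$n)
  expect_lt(abs(st$mean - 2000), 3 * se)
})

test_that("percent of reference reproduces the guideline arithmetic", {
  row <- tibble::tibble(energy_kcal_d = 2000, fiber_g_d = 15,
                        sugar_g_d = 97.8, fat_g_d = 66.7,
                        carbohydrates_g_d = 250, protein_g_d = 60)
  pct <- percent_of_reference(row, body_weight = 75)
  getm <- function(m) pct[pct$metric == m, ]
  expect_equal(getm("fiber")$percent, 50)
  expect_equal(getm("sugar")$percent, 195.6)
  expect_equal(getm("energy")$percent, 100)
  expect_equal(getm("fat_energy_share")$value, 9 * 66.7 / 2000 * 100)
  expect_true(getm("carb_energy_share")$within_range)  # 50% in [45, 60]
  expect_equal(getm("protein")$percent, 60 / (0.8 * 75) * 100)

  pct50 <- percent_of_reference(dplyr::mutate(row, sugar_g_d = 50))
  expect_equal(pct50$percent[pct50$metric == "sugar"], 100)

  expect_error(percent_of_reference(dplyr::mutate(row, energy_kcal_d = 0)),
               class = "ffqscore_stat_error")
})

test_that("within-group standardisation matches a manual group loop", {
  expect_equal(standardize_within_group(c(2, 4), c("g", "g")),
               c(-1, 1) / sqrt(2))
  set.seed(6)
  v <- rnorm(40, 25, 6)
  g <- rep(c("F", "M"), 20)
  z <- standardize_within_group(v, g)
  manual <- v
  for (s in c("F", "M")) {
    manual[g == s] <- (v[g == s] - mean(v[g == s])) / sd(v[g == s])
  }
  expect_equal(z, manual)
  expect_lt(abs(mean(z[g == "F"])), 1e-12)
  expect_lt(abs(mean(z[g == "M"])), 1e-12)
  expect_equal(sd(z[g == "F"]), 1)
  # error names the offending group
  expect_error(standardize_within_group(c(1, 2, 3), c("a", "a", "b")),
               regexp = "'b'", class = "ffqscore_stat_error")
  expect_error(standardize_within_group(c(1, 1, 2, 3), c("a", "a", "b", "b")),
               regexp = "'a'.*constant", class = "ffqscore_stat_error")
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(10)
  df <- tibble::tibble(sex = rep(c("F", "M"), each = 20),
                       x = rnorm(40), z = rnorm(40))
  df$y <- 2 * df$x
  cm <- correlation_matrix(df, c("x", "y", "z"))
  expect_equal(cm$rho[cm$var1 == "x" & cm$var2 == "y"], 1)
  expect_equal(cm$rho[cm$var1 == cm$var2], rep(1, 3))
  m_xy <- cm$rho[cm$var1 == "x" & cm$var2 == "z"]
  m_yx <- cm$rho[cm$var1 == "z" & cm$var2 == "x"]
  expect_equal(m_xy, m_yx)

  strat <- correlation_matrix(df, c("x", "z"), stratify_by = "sex")
  manual <- cor(df$x[df$sex == "F"], df$z[df$sex == "F"])
  expect_equal(strat$rho[strat$stratum == "F" & strat$var1 == "x" &
                           strat$var2 == "z"], manual)
})
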