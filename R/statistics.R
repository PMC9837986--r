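# Descriptive and inferential statistics: Pearson, Shapiro-Wilk, t-tests,
# chi-squared, group descriptives, dietary reference standards,
# within-group standardisation, correlation matrices.

#' Pearson product-moment correlation
#'
#' Pairwise-complete Pearson correlation with its test, reporting the
#' number of pairs actually used.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A tibble with `rho`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_stat("Pearson correlation needs >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_stat("correlation undefined: zero variance in x or y")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Shapiro-Wilk normality check
#'
#' Flags whether a sample is compatible with a normal distribution at the
#' given level. The flag is informational only; downstream statistics are
#' never blocked by non-normality.
#'
#' @param x Numeric vector, 3 to 5000 non-missing values.
#' @param alpha Significance level, default 0.05.
#' @return A tibble with `statistic`, `p_value`, `is_normal`, `n`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop_stat("Shapiro-Wilk requires 3 <= n <= 5000 non-missing values")
  }
  if (sd(x) == 0) stop_stat("normality check undefined for a constant series")
  sw <- shapiro.test(x)
  tibble::tibble(statistic = unname(sw$statistic), p_value = sw$p.value,
                 is_normal = sw$p.value >= alpha, n = length(x))
}

#' Two-sample t-test comparison
#'
#' Welch's t-test by default for independent samples (set
#' `var_equal = TRUE` for the classic Student test), classic paired t-test
#' when `paired = TRUE`. Identical paired samples return statistic 0 and
#' p-value 1 by convention.
#'
#' @param x,y Numeric vectors (equal length when `paired`).
#' @param paired Paired test?
#' @param var_equal Assume equal variances for the unpaired test?
#' @return A tibble of class `ffq_group_comparison` with `test`,
#'   `statistic`, `df`, `p_value` and per-group mean/SD/n summaries.
#' @export
two_sample_t <- function(x, y, paired = FALSE, var_equal = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (paired) {
    if (length(x) != length(y)) {
      stop_validation("paired test requires equal lengths")
    }
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
  }
  if (length(x) < 2 || length(y) < 2) {
    stop_stat("each group needs >= 2 observations")
  }
  test_name <- if (paired) "paired_t" else if (var_equal) "student_t" else "welch_t"
  if (paired && sd(x - y) == 0) {
    if (all(x == y)) {
      res <- list(statistic = 0, parameter = length(x) - 1, p.value = 1)
    } else {
      stop_stat("paired t-test undefined: zero variance of differences")
    }
  } else if (!paired && sd(c(x, y)) == 0) {
    stop_stat("t-test undefined: zero pooled variance")
  } else {
    res <- tryCatch(
      t.test(x, y, paired = paired, var.equal = var_equal),
      error = function(e) stop_stat(conditionMessage(e))
    )
  }
  out <- tibble::tibble(
    test = test_name,
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    mean_x = mean(x), sd_x = sd(x), n_x = length(x),
    mean_y = mean(y), sd_y = sd(y), n_y = length(y)
  )
  class(out) <- c("ffq_group_comparison", class(out))
  out
}

#' Chi-squared test of independence
#'
#' Pearson chi-squared statistic on an r-by-c contingency table with
#' `(r-1)(c-1)` degrees of freedom. Yates continuity correction for 2x2
#' tables is off by default (matching the uncorrected statistic of the
#' closed-form `(O - E)^2 / E` sum).
#'
#' @param counts Matrix (at least 2x2) of non-negative counts.
#' @param correct Apply continuity correction for 2x2 tables?
#' @return A tibble of class `ffq_group_comparison` with `test`,
#'   `statistic`, `df`, `p_value`.
#' @export
chisq_independence <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop_validation("contingency table must be at least 2x2")
  }
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_stat("chi-squared undefined: a zero row or column marginal")
  }
  res <- suppressWarnings(chisq.test(counts, correct = correct))
  out <- tibble::tibble(
    test = "chi_squared",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value
  )
  class(out) <- c("ffq_group_comparison", class(out))
  out
}

#' Grouped descriptive summary
#'
#' Mean, SD, median, min, max and n for numeric variables, and counts with
#' within-group percentages (one decimal) for categorical variables,
#' optionally grouped by demographic fields. Missing values are dropped
#' per variable and the n actually used is reported.
#'
#' @param data A data frame (e.g. an intake table).
#' @param variables Character vector of columns to summarise; defaults to
#'   all columns not used for grouping.
#' @param group_by Character vector of grouping columns (may be empty).
#' @return A tibble with the grouping columns plus `variable`, `level`
#'   (`NA` for numeric variables), `n`, `mean`, `sd`, `median`, `min`,
#'   `max`, `percent`.
#' @examples
#' df <- tibble::tibble(g = rep(c("HFS", "LFS"), c(35, 41)),
#'                      diet = rep(c("OMN", "VEG", "OMN", "VEG"),
#'                                 c(32, 3, 27, 14)))
#' descriptive_summary(df, "diet", group_by = "g")
#' @export
descriptive_summary <- function(data, variables = NULL, group_by = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(variables)) variables <- setdiff(names(data), group_by)
  assert_cols(data, c(variables, group_by), "data")
  grp_key <- if (length(group_by) > 0) {
    interaction(data[group_by], drop = TRUE, lex.order = TRUE)
  } else {
    factor(rep("all", nrow(data)))
  }
  out <- lapply(levels(grp_key), function(g) {
    sub <- data[grp_key == g, , drop = FALSE]
    gcols <- if (length(group_by) > 0) {
      sub[1, group_by, drop = FALSE]
    } else {
      tibble::tibble()
    }
    rows <- lapply(variables, function(v) {
      x <- sub[[v]]
      if (is.numeric(x)) {
        x <- x[!is.na(x)]
        tibble::tibble(
          variable = v, level = NA_character_, n = length(x),
          mean = if (length(x) > 0) mean(x) else NA_real_,
          sd = if (length(x) > 1) sd(x) else NA_real_,
          median = if (length(x) > 0) median(x) else NA_real_,
          min = if (length(x) > 0) min(x) else NA_real_,
          max = if (length(x) > 0) max(x) else NA_real_,
          percent = NA_real_
        )
      } else {
        x <- as.character(x)
        x <- x[!is.na(x)]
        tab <- table(x)
        tibble::tibble(
          variable = v, level = names(tab), n = as.integer(tab),
          mean = NA_real_, sd = NA_real_, median = NA_real_,
          min = NA_real_, max = NA_real_,
          percent = round(100 * as.integer(tab) / length(x), 1)
        )
      }
    })
    dplyr::bind_cols(gcols[rep(1, sum(vapply(rows, nrow, 0L))), , drop = FALSE],
                     dplyr::bind_rows(rows))
  })
  dplyr::bind_rows(out)
}

#' Dietary reference standards
#'
#' The recommended-intake anchors used for percent-of-reference reporting:
#' a fiber minimum of 30 g/d, a free-sugar ceiling of 50 g/d, protein of
#' 0.8 g per kg body weight per day, fat at 30% of energy, carbohydrates at
#' 45-60% of energy, and a 2000 kcal/d reference energy intake.
#'
#' @param fiber_min,sugar_max,protein_per_kg,fat_energy_share,energy_reference
#'   Scalar overrides.
#' @param carb_energy_share_range Length-2 increasing range.
#' @return A list of class `ffq_standards`.
#' @export
reference_standards <- function(fiber_min = 30, sugar_max = 50,
                                protein_per_kg = 0.8,
                                fat_energy_share = 0.30,
                                carb_energy_share_range = c(0.45, 0.60),
                                energy_reference = 2000) {
  vals <- c(fiber_min, sugar_max, protein_per_kg, fat_energy_share,
            carb_energy_share_range, energy_reference)
  if (any(vals <= 0)) stop_validation("reference standards must be positive")
  if (diff(carb_energy_share_range) < 0) {
    stop_validation("carb_energy_share_range must be ordered")
  }
  structure(
    list(fiber_min = fiber_min, sugar_max = sugar_max,
         protein_per_kg = protein_per_kg,
         fat_energy_share = fat_energy_share,
         carb_energy_share_range = carb_energy_share_range,
         energy_reference = energy_reference),
    class = "ffq_standards"
  )
}

#' Intake as percent of dietary reference standards
#'
#' For each intake row: fiber and sugar as percent of the recommended
#' 30 g/d minimum and 50 g/d ceiling; energy as percent of the 2000 kcal/d
#' reference; protein as percent of 0.8 g/kg/d when a body weight is given;
#' the fat share of energy (9 kcal/g) against the 30% recommendation; and
#' the carbohydrate share of energy (4 kcal/g) against the 45-60% band.
#'
#' @param intake An intake tibble (rows are scored records).
#' @param standards An [reference_standards()] object.
#' @param body_weight Optional body weight in kg (scalar or per-row) for
#'   the protein check.
#' @return A long tibble: key columns plus `metric`, `value`, `unit`,
#'   `reference_low`, `reference_high`, `percent`, `within_range`.
#' @export
percent_of_reference <- function(intake, standards = reference_standards(),
                                 body_weight = NULL) {
  intake <- tibble::as_tibble(intake)
  assert_cols(intake, c("energy_kcal_d", "fiber_g_d", "sugar_g_d",
                        "fat_g_d", "carbohydrates_g_d"), "intake")
  if (any(!is.na(intake$energy_kcal_d) & intake$energy_kcal_d == 0)) {
    stop_stat("energy-share checks undefined at zero energy")
  }
  keys <- intersect(.KEY_COLS, names(intake))
  base <- intake[, keys, drop = FALSE]
  mk <- function(metric, value, unit, lo, hi, pct, within = NA) {
    dplyr::bind_cols(base, tibble::tibble(
      metric = metric, value = value, unit = unit,
      reference_low = lo, reference_high = hi,
      percent = pct, within_range = within
    ))
  }
  fat_share <- 9 * intake$fat_g_d / intake$energy_kcal_d * 100
  carb_share <- 4 * intake$carbohydrates_g_d / intake$energy_kcal_d * 100
  carb_lo <- standards$carb_energy_share_range[1] * 100
  carb_hi <- standards$carb_energy_share_range[2] * 100
  out <- list(
    mk("fiber", intake$fiber_g_d, "g/d", standards$fiber_min, NA,
       intake$fiber_g_d / standards$fiber_min * 100),
    mk("sugar", intake$sugar_g_d, "g/d", NA, standards$sugar_max,
       intake$sugar_g_d / standards$sugar_max * 100),
    mk("energy", intake$energy_kcal_d, "kcal/d", NA,
       standards$energy_reference,
       intake$energy_kcal_d / standards$energy_reference * 100),
    mk("fat_energy_share", fat_share, "% of energy", NA,
       standards$fat_energy_share * 100,
       fat_share / (standards$fat_energy_share * 100) * 100),
    mk("carb_energy_share", carb_share, "% of energy", carb_lo, carb_hi,
       NA_real_, carb_share >= carb_lo & carb_share <= carb_hi)
  )
  if (!is.null(body_weight)) {
    assert_cols(intake, "protein_g_d", "intake")
    ref <- standards$protein_per_kg * body_weight
    out <- c(out, list(
      mk("protein", intake$protein_g_d, "g/d", ref, NA,
         intake$protein_g_d / ref * 100)
    ))
  }
  dplyr::bind_rows(out)
}

#' Standardise values within groups
#'
#' Z-scores computed separately within each group (sample SD, n - 1
#' denominator): each group ends up with mean 0 and SD 1. Used e.g. to put
#' male and female body-composition markers on a common scale before
#' correlating.
#'
#' @param values Numeric vector.
#' @param group Grouping vector of the same length.
#' @return Numeric vector of within-group z-scores (`NA` preserved).
#' @export
standardize_within_group <- function(values, group) {
  if (length(values) != length(group)) {
    stop_validation("values and group must have equal length")
  }
  out <- rep(NA_real_, length(values))
  for (g in unique(group[!is.na(group)])) {
    idx <- !is.na(group) & group == g
    x <- values[idx]
    xx <- x[!is.na(x)]
    if (length(xx) < 2) {
      stop_stat(sprintf("group '%s' has fewer than 2 values", g))
    }
    if (sd(xx) == 0) {
      stop_stat(sprintf("group '%s' is constant; z-scores undefined", g))
    }
    out[idx] <- (x - mean(xx)) / sd(xx)
  }
  out
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations over a set of variables, as a
#' tidy long table, optionally within strata (e.g. per sex). Cells with
#' fewer than `min_n` complete pairs are `NA`; the n per cell is reported.
#'
#' @param data A data frame.
#' @param variables Character vector of numeric columns to correlate.
#' @param stratify_by Optional single column name to stratify by.
#' @param min_n Minimum complete pairs per cell, default 3.
#' @return A tibble of class `ffq_corr`: `stratum`, `var1`, `var2`, `rho`,
#'   `n`; symmetric with unit diagonal.
#' @export
correlation_matrix <- function(data, variables, stratify_by = NULL,
                               min_n = 3) {
  data <- tibble::as_tibble(data)
  assert_cols(data, c(variables, stratify_by), "data")
  strata <- if (is.null(stratify_by)) {
    list(all = data)
  } else {
    split(data, data[[stratify_by]])
  }
  out <- lapply(names(strata), function(s) {
    sub <- strata[[s]]
    grid <- tidyr::expand_grid(var1 = variables, var2 = variables)
    grid$rho <- NA_real_
    grid$n <- 0L
    for (i in seq_len(nrow(grid))) {
      x <- sub[[grid$var1[i]]]
      y <- sub[[grid$var2[i]]]
      ok <- !is.na(x) & !is.na(y)
      grid$n[i] <- sum(ok)
      if (grid$var1[i] == grid$var2[i]) {
        grid$rho[i] <- if (sum(ok) > 0) 1 else NA_real_
      } else if (sum(ok) >= min_n && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
        grid$rho[i] <- cor(x[ok], y[ok])
      }
    }
    dplyr::bind_cols(tibble::tibble(stratum = s), grid)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("ffq_corr", class(out))
  out
}
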