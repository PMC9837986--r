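# Pipeline steps 5-6: interquartile-range energy outlier filtering and
# Willett residual energy adjustment.

#' Flag energy outliers by the interquartile-range rule
#'
#' Rows whose daily energy lies strictly above `Q3 + multiplier * IQR` or
#' strictly below `Q1 - multiplier * IQR` are flagged. Quartiles are
#' computed on the full input (per recall-window stratum by default, since
#' energy scales differ between short and long recall windows) with R's
#' linear-interpolation quantile convention (`type = 7`); the convention is
#' configurable because published analyses rarely state one.
#'
#' @param intake An intake tibble with an energy column.
#' @param multiplier IQR multiplier, default 1.5.
#' @param per_window If `TRUE` (default) quartiles and bounds are computed
#'   within each `recall_window_days` stratum; `FALSE` pools all rows.
#' @param quantile_type Quantile algorithm passed to [stats::quantile()];
#'   default 7 (linear interpolation).
#' @param basis Name of the energy column, default `"energy_kcal_d"`.
#' @return An object of class `ffq_filter`: a list with `kept` and
#'   `flagged` (disjoint subsets whose union is the input), `bounds`
#'   (per-stratum `q1`, `q3`, `iqr`, `lower_bound`, `upper_bound`, `n`), and
#'   `table` (the full input with `outlier_flag` set).
#' @examples
#' x <- tibble::tibble(respondent_id = as.character(1:9), timepoint = "BL1",
#'                     recall_window_days = 7,
#'                     energy_kcal_d = c(15:22 * 100, 6000))
#' iqr_energy_filter(x)$flagged$energy_kcal_d
#' @export
iqr_energy_filter <- function(intake, multiplier = 1.5, per_window = TRUE,
                              quantile_type = 7, basis = "energy_kcal_d") {
  intake <- tibble::as_tibble(intake)
  assert_cols(intake, basis, "intake")
  if (multiplier <= 0) stop_validation("multiplier must be > 0")
  strat <- if (per_window && "recall_window_days" %in% names(intake)) {
    intake$recall_window_days
  } else {
    rep("all", nrow(intake))
  }
  energy <- intake[[basis]]
  bounds <- lapply(split(seq_along(energy), strat), function(idx) {
    e <- energy[idx]
    e <- e[!is.na(e)]
    if (length(e) < 4) {
      stop_stat(sprintf(
        "need >= 4 rows with non-missing energy per stratum to estimate quartiles (got %d)",
        length(e)
      ))
    }
    q <- quantile(e, c(0.25, 0.75), type = quantile_type, names = FALSE)
    tibble::tibble(
      stratum = strat[idx[1]], n = length(e),
      q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
      lower_bound = q[1] - multiplier * (q[2] - q[1]),
      upper_bound = q[2] + multiplier * (q[2] - q[1])
    )
  })
  bounds <- dplyr::bind_rows(bounds)
  b <- bounds[match(strat, bounds$stratum), ]
  flag <- !is.na(energy) &
    (energy > b$upper_bound | energy < b$lower_bound)
  intake$outlier_flag <- flag
  structure(
    list(
      kept = intake[!flag, , drop = FALSE],
      flagged = intake[flag, , drop = FALSE],
      bounds = bounds,
      table = intake,
      multiplier = multiplier,
      quantile_type = quantile_type,
      basis = basis
    ),
    class = "ffq_filter"
  )
}

#' @export
print.ffq_filter <- function(x, ...) {
  cat(sprintf("<ffq_filter> %d kept, %d flagged (IQR x %.2f, type %d)\n",
              nrow(x$kept), nrow(x$flagged), x$multiplier, x$quantile_type))
  print(x$bounds)
  invisible(x)
}

#' Energy-adjust a nutrient by the residual method
#'
#' Willett residual adjustment: the nutrient is regressed on total energy
#' across the cohort by ordinary least squares, and the residual — the part
#' of intake not explained by how much the person eats overall — is the
#' energy-independent nutrient measure. With `mode = "residual"` (the
#' default used for statistics) the adjusted value is the raw residual,
#' centred at zero and uncorrelated with energy by construction; with
#' `mode = "residual_plus_mean"` the prediction at the cohort mean energy is
#' added back, giving values in interpretable units whose cohort mean equals
#' the unadjusted mean exactly.
#'
#' @param intake An intake tibble.
#' @param nutrient Plain nutrient name (e.g. `"fiber"`) or an explicit
#'   column name present in `intake`; must not be the energy column.
#' @param mode `"residual"` or `"residual_plus_mean"`.
#' @param energy Energy column name, default `"energy_kcal_d"`.
#' @return An object of class `ffq_energy_adjustment`: a list with the fit
#'   (`slope`, `intercept`, `mean_energy`, `n`, `nutrient`, `mode`) and
#'   `table`, the input with `<nutrient column>_adj` appended (`NA` where
#'   energy or nutrient was missing). [tidy()], [glance()] and [augment()]
#'   methods are provided.
#' @export
energy_adjust <- function(intake, nutrient,
                          mode = c("residual", "residual_plus_mean"),
                          energy = "energy_kcal_d") {
  mode <- match.arg(mode)
  intake <- tibble::as_tibble(intake)
  col <- if (nutrient %in% names(intake)) nutrient else .intake_col(nutrient)
  assert_cols(intake, c(col, energy), "intake")
  if (col == energy) stop_validation("cannot energy-adjust energy on itself")
  y <- intake[[col]]
  e <- intake[[energy]]
  ok <- !is.na(y) & !is.na(e)
  if (sum(ok) < 3) {
    stop_stat(sprintf(
      "energy adjustment of '%s' needs >= 3 complete rows (got %d)",
      col, sum(ok)
    ))
  }
  if (var(e[ok]) == 0) {
    stop_stat("cannot adjust on constant energy (zero energy variance)")
  }
  fit <- lm(y[ok] ~ e[ok])
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  mean_energy <- mean(e[ok])
  res <- rep(NA_real_, length(y))
  res[ok] <- residuals(fit)
  adj <- res
  if (mode == "residual_plus_mean") {
    adj <- res + (intercept + slope * mean_energy)
  }
  intake[[paste0(col, "_adj")]] <- adj
  ss_tot <- sum((y[ok] - mean(y[ok]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  structure(
    list(
      table = intake, nutrient = col, mode = mode,
      slope = slope, intercept = intercept,
      mean_energy = mean_energy, n = sum(ok),
      residuals = res, r_squared = r2
    ),
    class = "ffq_energy_adjustment"
  )
}

#' @export
print.ffq_energy_adjustment <- function(x, ...) {
  cat(sprintf(
    "<ffq_energy_adjustment> %s ~ energy (n = %d): slope %.4g, intercept %.4g, mode '%s'\n",
    x$nutrient, x$n, x$slope, x$intercept, x$mode
  ))
  invisible(x)
}

#' Energy-adjust several nutrients at once
#'
#' Convenience wrapper around [energy_adjust()] that appends one `_adj`
#' column per nutrient and returns the augmented table.
#'
#' @inheritParams energy_adjust
#' @param nutrients Character vector of nutrient names.
#' @return The intake tibble with one adjusted column per nutrient.
#' @export
adjust_nutrients <- function(intake, nutrients,
                             mode = c("residual", "residual_plus_mean"),
                             energy = "energy_kcal_d") {
  mode <- match.arg(mode)
  for (nm in nutrients) {
    intake <- energy_adjust(intake, nm, mode = mode, energy = energy)$table
  }
  intake
}
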