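# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy an ICC(2,1) fit
#'
#' @param x An `ffq_icc` object.
#' @param ... Unused.
#' @return One-row tibble with `icc2`, `ci_lower`, `ci_upper`,
#'   `koo_li_class`, `n`, `k`.
#' @method tidy ffq_icc
#' @export
tidy.ffq_icc <- function(x, ...) {
  tibble::tibble(
    icc2 = x$icc2, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    koo_li_class = x$koo_li_class, n = x$n, k = x$k
  )
}

#' @rdname tidy.ffq_icc
#' @method glance ffq_icc
#' @export
glance.ffq_icc <- function(x, ...) {
  tibble::tibble(msr = x$msr, msc = x$msc, mse = x$mse,
                 n = x$n, k = x$k, conf_level = x$conf_level)
}

#' Tidy an energy-adjustment fit
#'
#' @param x An `ffq_energy_adjustment` object.
#' @param ... Unused.
#' @return `tidy()`: the OLS terms; `glance()`: fit summary; `augment()`:
#'   the input table with the adjusted column appended.
#' @method tidy ffq_energy_adjustment
#' @export
tidy.ffq_energy_adjustment <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "energy"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.ffq_energy_adjustment
#' @method glance ffq_energy_adjustment
#' @export
glance.ffq_energy_adjustment <- function(x, ...) {
  tibble::tibble(nutrient = x$nutrient, mode = x$mode,
                 mean_energy = x$mean_energy, r_squared = x$r_squared,
                 n = x$n)
}

#' @rdname tidy.ffq_energy_adjustment
#' @method augment ffq_energy_adjustment
#' @export
augment.ffq_energy_adjustment <- function(x, ...) {
  x$table
}

#' Tidy an IQR energy filter result
#'
#' @param x An `ffq_filter` object.
#' @param ... Unused.
#' @return `tidy()`: per-stratum bounds; `glance()`: kept/flagged counts;
#'   `augment()`: the full table with `outlier_flag` set.
#' @method tidy ffq_filter
#' @export
tidy.ffq_filter <- function(x, ...) {
  x$bounds
}

#' @rdname tidy.ffq_filter
#' @method glance ffq_filter
#' @export
glance.ffq_filter <- function(x, ...) {
  tibble::tibble(n = nrow(x$table), kept = nrow(x$kept),
                 flagged = nrow(x$flagged), multiplier = x$multiplier,
                 quantile_type = x$quantile_type)
}

#' @rdname tidy.ffq_filter
#' @method augment ffq_filter
#' @export
augment.ffq_filter <- function(x, ...) {
  x$table
}
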