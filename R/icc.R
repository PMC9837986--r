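# Intraclass correlation ICC(2,1): two-way random effects, single
# measures, absolute agreement, with the standard F-based 95% CI.

#' ICC(2,1): two-way random, single measures, absolute agreement
#'
#' Quantifies test-retest reliability of a measurement repeated `k` times on
#' `n` subjects, penalising systematic shifts between measurements
#' (absolute agreement, not mere consistency). From the two-way ANOVA
#' decomposition into between-subject (`MSR`), between-measurement (`MSC`)
#' and error (`MSE`) mean squares,
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1)\,MSE + \frac{k}{n}(MSC - MSE)}}
#' The confidence interval is the standard F-based interval for this
#' estimator (McGraw & Wong's A-1 case, as used by the common ICC
#' implementations).
#'
#' @param m Numeric matrix or data frame, `n` subjects by `k` repeated
#'   measurements. Rows with any missing value are dropped (complete cases).
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `ffq_icc`: list with `icc2`, `ci_lower`,
#'   `ci_upper`, `koo_li_class`, the mean squares `msr`, `msc`, `mse`, and
#'   `n`, `k`.
#' @examples
#' icc2_single_absolute(cbind(c(9, 8, 7, 5, 4), c(10, 8, 6, 5, 2)))
#' @export
icc2_single_absolute <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) stop_stat("ICC needs k >= 2 measurements per subject")
  if (n < 2) stop_stat("ICC needs at least 2 complete subjects")
  if (n < 5) {
    warn(sprintf("ICC on only %d subjects is unstable; n >= 5 recommended", n))
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  sst <- sum((m - grand)^2)
  if (sst == 0) stop_stat("ICC undefined: zero total variance")
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  fj <- if (mse > 0) msc / mse else Inf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  if (is.finite(fj) && icc < 1) {
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_u <- qf(1 - alpha / 2, n - 1, v)
    f_l <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  } else {
    lower <- upper <- icc
  }
  structure(
    list(
      icc2 = icc, ci_lower = min(lower, icc), ci_upper = max(upper, icc),
      conf_level = conf_level,
      koo_li_class = classify_icc(icc),
      msr = msr, msc = msc, mse = mse, n = n, k = k
    ),
    class = "ffq_icc"
  )
}

#' @export
print.ffq_icc <- function(x, ...) {
  cat(sprintf("<ffq_icc> ICC(2,1) = %.3f [%.3f, %.3f], n = %d, k = %d (%s)\n",
              x$icc2, x$ci_lower, x$ci_upper, x$n, x$k, x$koo_li_class))
  invisible(x)
}

#' Interpret an ICC value on the Koo-Li bands
#'
#' Reliability bands: below 0.5 poor, 0.5 to below 0.75 moderate, 0.75 to
#' below 0.9 good, 0.9 and above excellent. Boundary values are assigned to
#' the higher class.
#'
#' @param icc2 Numeric vector of ICC values in \[-1, 1\].
#' @return Character vector of classes.
#' @examples
#' classify_icc(c(0.11, 0.62, 0.8, 0.95))
#' @export
classify_icc <- function(icc2) {
  if (any(!is.na(icc2) & (icc2 < -1 | icc2 > 1))) {
    stop_validation("ICC values must lie in [-1, 1]")
  }
  dplyr::case_when(
    is.na(icc2) ~ NA_character_,
    icc2 < 0.5 ~ "poor",
    icc2 < 0.75 ~ "moderate",
    icc2 < 0.9 ~ "good",
    TRUE ~ "excellent"
  )
}
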