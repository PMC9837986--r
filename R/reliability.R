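# Test-retest reliability tables: Pearson's rho and ICC(2,1) per nutrient
# for a chosen pairing (two timepoints within a window, or two recall
# windows).

#' Test-retest reliability per nutrient
#'
#' Builds, for each requested nutrient, the n-subjects-by-2 matrix implied
#' by the chosen pairing, then reports Pearson's rho and ICC(2,1) (absolute
#' agreement, single measures) with its 95% CI and Koo-Li class — the
#' standard reliability table for repeated FFQ administrations.
#'
#' Two pairings are supported: `"timepoints"` compares the two baseline
#' administrations within each recall window (units: respondents);
#' `"windows"` compares two recall windows, pooling repeated timepoints per
#' respondent as separate units by default (set `pool_timepoints = FALSE`
#' to get one table per timepoint).
#'
#' @param intake An intake tibble (typically energy-adjusted via
#'   [adjust_nutrients()]).
#' @param nutrients Character vector of plain nutrient names
#'   (e.g. `c("protein", "fat", "carbohydrates", "fiber", "sugar")`).
#' @param pairing `"timepoints"` or `"windows"`.
#' @param timepoints The two timepoint labels to pair, default the first
#'   two present.
#' @param windows The two recall windows to pair (for
#'   `pairing = "windows"`), default the two present.
#' @param use_adjusted Use the `_adj` (energy-adjusted) columns, default
#'   `TRUE`; energy itself is always taken unadjusted.
#' @param pool_timepoints For `pairing = "windows"`: treat respondent x
#'   timepoint as the unit (default `TRUE`).
#' @return A tibble of class `ffq_reliability`: `nutrient`, `pairing`,
#'   `recall_window_days` (or `timepoint`), `pearson_rho`, `pearson_p`,
#'   `icc2`, `ci_lower`, `ci_upper`, `koo_li_class`, `n`, `k`.
#' @export
reliability_table <- function(intake, nutrients,
                              pairing = c("timepoints", "windows"),
                              timepoints = NULL, windows = NULL,
                              use_adjusted = TRUE, pool_timepoints = TRUE) {
  pairing <- match.arg(pairing)
  intake <- tibble::as_tibble(intake)
  assert_cols(intake, .KEY_COLS, "intake")

  col_for <- function(nm) {
    base <- if (nm %in% names(intake)) nm else .intake_col(nm)
    if (use_adjusted && nm != "energy" &&
        paste0(base, "_adj") %in% names(intake)) {
      paste0(base, "_adj")
    } else {
      base
    }
  }

  one_cell <- function(sub, unit_cols, split_col, levels2, nutrient, label,
                       extra) {
    col <- col_for(nutrient)
    assert_cols(sub, col, "intake")
    wide <- sub %>%
      dplyr::select(dplyr::all_of(c(unit_cols, split_col, col))) %>%
      tidyr::pivot_wider(names_from = dplyr::all_of(split_col),
                         values_from = dplyr::all_of(col))
    if (!all(as.character(levels2) %in% names(wide))) {
      return(NULL)
    }
    m <- as.matrix(wide[, as.character(levels2)])
    m <- m[complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3) return(NULL)
    pr <- pearson_cor(m[, 1], m[, 2])
    ic <- suppressWarnings(icc2_single_absolute(m))
    dplyr::bind_cols(
      tibble::tibble(nutrient = nutrient, pairing = label),
      extra,
      tibble::tibble(
        pearson_rho = pr$rho, pearson_p = pr$p_value,
        icc2 = ic$icc2, ci_lower = ic$ci_lower, ci_upper = ic$ci_upper,
        koo_li_class = ic$koo_li_class, n = ic$n, k = ic$k
      )
    )
  }

  rows <- list()
  if (pairing == "timepoints") {
    tps <- timepoints %||% utils::head(sort(unique(intake$timepoint)), 2)
    if (length(tps) != 2) stop_validation("need exactly 2 timepoints to pair")
    for (w in sort(unique(intake$recall_window_days))) {
      sub <- intake[intake$recall_window_days == w &
                      intake$timepoint %in% tps, , drop = FALSE]
      for (nm in nutrients) {
        rows[[length(rows) + 1]] <- one_cell(
          sub, "respondent_id", "timepoint", tps, nm,
          paste(tps, collapse = "~"),
          tibble::tibble(recall_window_days = w)
        )
      }
    }
  } else {
    ws <- windows %||% utils::head(sort(unique(intake$recall_window_days)), 2)
    if (length(ws) != 2) stop_validation("need exactly 2 recall windows to pair")
    label <- paste0(ws, "d", collapse = "~")
    if (pool_timepoints) {
      sub <- intake[intake$recall_window_days %in% ws, , drop = FALSE]
      for (nm in nutrients) {
        rows[[length(rows) + 1]] <- one_cell(
          sub, c("respondent_id", "timepoint"), "recall_window_days", ws,
          nm, label, tibble::tibble(timepoint = "pooled")
        )
      }
    } else {
      for (tp in sort(unique(intake$timepoint))) {
        sub <- intake[intake$recall_window_days %in% ws &
                        intake$timepoint == tp, , drop = FALSE]
        for (nm in nutrients) {
          rows[[length(rows) + 1]] <- one_cell(
            sub, "respondent_id", "recall_window_days", ws, nm, label,
            tibble::tibble(timepoint = tp)
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      nutrient = character(), pairing = character(),
      pearson_rho = double(), pearson_p = double(), icc2 = double(),
      ci_lower = double(), ci_upper = double(), koo_li_class = character(),
      n = integer(), k = integer()
    )
  }
  class(out) <- c("ffq_reliability", class(out))
  out
}
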