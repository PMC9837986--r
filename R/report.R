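# Response-file readers, the end-to-end runner behind the command line,
# and the human-readable report writer.

#' Read a long-format response CSV
#'
#' Expected header: `respondent_id,timepoint,recall_window_days,item_id,`
#' `frequency_code,amount_code,type_code` plus any demographic columns.
#' Lines starting with `#` are ignored; codes are trimmed and lower-cased
#' at scoring time.
#'
#' @param path CSV path.
#' @return A tibble of responses.
#' @export
read_responses <- function(path) {
  df <- read_csv_prov(path, col_types = readr::cols(
    respondent_id = readr::col_character(),
    timepoint = readr::col_character(),
    recall_window_days = readr::col_integer(),
    item_id = readr::col_character(),
    frequency_code = readr::col_character(),
    amount_code = readr::col_character(),
    type_code = readr::col_character(),
    .default = readr::col_guess()
  ))
  assert_cols(df, c(.KEY_COLS, "item_id", "frequency_code"), path)
  df
}

#' Read a wide (one column per question) response export
#'
#' Survey platforms export one row per respondent with one column per
#' question. A column-mapping table converts this dialect onto the long
#' format used by the engine.
#'
#' @param path CSV path of the wide export.
#' @param mapping Data frame with columns `item_id`, `frequency_col`,
#'   `amount_col` and optionally `type_col`, naming the wide columns
#'   holding each item's answers.
#' @param respondent_col,timepoint_col,window_col Names of the id,
#'   timepoint and recall-window columns in the wide file.
#' @return A long-format response tibble as from [read_responses()].
#' @export
read_responses_wide <- function(path, mapping,
                                respondent_col = "respondent_id",
                                timepoint_col = "timepoint",
                                window_col = "recall_window_days") {
  wide <- read_csv_prov(path, col_types = readr::cols(.default = readr::col_character()))
  mapping <- tibble::as_tibble(mapping)
  assert_cols(mapping, c("item_id", "frequency_col", "amount_col"),
              "column mapping")
  assert_cols(wide, c(respondent_col, timepoint_col, window_col,
                      mapping$frequency_col, mapping$amount_col), path)
  demo_cols <- setdiff(names(wide),
                       c(respondent_col, timepoint_col, window_col,
                         mapping$frequency_col, mapping$amount_col,
                         mapping$type_col))
  rows <- lapply(seq_len(nrow(mapping)), function(i) {
    out <- tibble::tibble(
      respondent_id = wide[[respondent_col]],
      timepoint = wide[[timepoint_col]],
      recall_window_days = as.integer(wide[[window_col]]),
      item_id = mapping$item_id[i],
      frequency_code = wide[[mapping$frequency_col[i]]],
      amount_code = wide[[mapping$amount_col[i]]],
      type_code = if (!is.null(mapping$type_col) &&
                      !is.na(mapping$type_col[i])) {
        wide[[mapping$type_col[i]]]
      } else {
        NA_character_
      }
    )
    dplyr::bind_cols(out, wide[, demo_cols, drop = FALSE])
  })
  dplyr::bind_rows(rows)
}

#' Run one pipeline step from a configuration list
#'
#' The programmatic engine behind the `ffqscore` command line. Each run is
#' deterministic given identical inputs and seed, writes its artifacts with
#' a provenance comment header, and returns an exit status instead of
#' raising: 0 success, 1 validation error, 2 I/O error, 3 statistical
#' precondition violation.
#'
#' @param config Named list with `subcommand` (one of `"simulate"`,
#'   `"score"`, `"adjust"`, `"reliability"`, `"report"`) and the fields
#'   that subcommand needs (`input`, `output`, `schema`, `reference`,
#'   `seed`, `n`, `truth_output`, `mode`, `multiplier`, `per_window`,
#'   `pairing`, `nutrients`, `quantize`, `reliability_input`).
#' @return Integer exit status, invisibly. Messages are logged via
#'   [message()].
#' @export
ffq_run <- function(config) {
  status <- tryCatch({
    run_dispatch(config)
    0L
  },
  ffqscore_validation_error = function(e) { message("validation error: ", conditionMessage(e)); 1L },
  ffqscore_io_error = function(e) { message("I/O error: ", conditionMessage(e)); 2L },
  ffqscore_stat_error = function(e) { message("statistical error: ", conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

run_dispatch <- function(config) {
  sub <- config[["subcommand"]] %||% stop_validation("missing subcommand")
  schema <- if (!is.null(config[["schema"]])) load_schema(config[["schema"]]) else degs1_schema()
  seed <- as.integer(config[["seed"]] %||% 1L)

  if (sub == "simulate") {
    reference <- if (!is.null(config[["reference"]])) {
      load_reference_table(config[["reference"]], schema)
    } else {
      generate_reference_table(schema, seed = seed)
    }
    prof <- diet_profile()
    cfg <- generator_config(
      n_subjects = as.integer(config[["n"]] %||% 100L),
      recall_windows = as.integer(config[["windows"]] %||% 7L),
      missing_rate = config[["missing_rate"]] %||% 0,
      seed = seed
    )
    sim <- generate_cohort(prof, cfg, schema, reference,
                           quantize = !isFALSE(config[["quantize"]]))
    prov <- provenance_header(schema$schema_id,
                              attr(reference, "provenance"), seed)
    write_csv_prov(sim$responses, config[["output"]] %||% "responses.csv", prov)
    if (!is.null(config[["truth_output"]])) {
      write_csv_prov(sim$truth, config[["truth_output"]], prov)
    }
    if (!is.null(config[["reference_output"]])) {
      write_reference_table(reference, config[["reference_output"]])
    }
    message(sprintf("simulate: %d subjects, %d response rows",
                    nrow(sim$subjects), nrow(sim$responses)))
  } else if (sub == "score") {
    if (is.null(config[["reference"]])) stop_io("score: missing reference table path")
    reference <- load_reference_table(config[["reference"]], schema)
    responses <- read_responses(config[["input"]] %||% stop_io("score: missing input"))
    intake <- score_cohort(schema, reference, responses)
    write_intake(intake, config[["output"]] %||% "intake.csv",
                 provenance_header(schema$schema_id,
                                   attr(reference, "provenance"), seed))
    message(sprintf("score: %d records scored", nrow(intake)))
  } else if (sub == "adjust") {
    intake <- read_intake(config[["input"]] %||% stop_io("adjust: missing input"))
    fr <- iqr_energy_filter(intake,
                            multiplier = config[["multiplier"]] %||% 1.5,
                            per_window = !isFALSE(config[["per_window"]]))
    kept <- adjust_nutrients(
      fr$kept,
      nutrients = config[["nutrients"]] %||% c("protein", "fat", "carbohydrates",
                                          "fiber", "sugar"),
      mode = config[["mode"]] %||% "residual"
    )
    write_csv_prov(kept, config[["output"]] %||% "intake_adjusted.csv",
                   provenance_header(schema$schema_id, NA, seed))
    message(sprintf("adjust: %d flagged as energy outliers, %d adjusted",
                    nrow(fr$flagged), nrow(kept)))
  } else if (sub == "reliability") {
    intake <- read_intake(config[["input"]] %||% stop_io("reliability: missing input"))
    rel <- reliability_table(
      intake,
      nutrients = config[["nutrients"]] %||% c("protein", "fat", "carbohydrates",
                                          "fiber", "sugar"),
      pairing = config[["pairing"]] %||% "timepoints"
    )
    write_csv_prov(tibble::as_tibble(rel),
                   config[["output"]] %||% "reliability.csv",
                   provenance_header(schema$schema_id, NA, seed))
    message(sprintf("reliability: %d nutrient pairings", nrow(rel)))
  } else if (sub == "report") {
    intake <- read_intake(config[["input"]] %||% stop_io("report: missing input"))
    rel <- if (!is.null(config[["reliability_input"]])) {
      read_csv_prov(config[["reliability_input"]])
    } else {
      NULL
    }
    write_report(intake, rel, config[["output"]] %||% "report.md")
    message("report written")
  } else {
    stop_validation(sprintf("unknown subcommand '%s'", sub))
  }
  invisible(NULL)
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)

#' Write a human-readable summary report
#'
#' Markdown report with per-window nutrient descriptives in the
#' `Mean (SD)` / `Median [Min, Max]` style, percent-of-reference lines,
#' and the reliability table when one is supplied. Output is deterministic:
#' the same input yields identical bytes.
#'
#' @param intake An intake tibble.
#' @param reliability Optional reliability tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(intake, reliability = NULL, path = "report.md") {
  lines <- c("# FFQ nutrient scoring report", "")
  nut_cols <- intersect(.INTAKE_NUTRIENT_COLS(), names(intake))
  for (w in sort(unique(intake$recall_window_days))) {
    sub <- intake[intake$recall_window_days == w, , drop = FALSE]
    lines <- c(lines, sprintf("## Recall window: %d days (n = %d records)",
                              w, nrow(sub)), "")
    lines <- c(lines,
               "| Nutrient | Mean (SD) | Median [Min, Max] |",
               "|---|---|---|")
    for (col in nut_cols) {
      x <- sub[[col]]
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      lines <- c(lines, sprintf(
        "| %s | %s (%s) | %s [%s, %s] |",
        col, fmt1(mean(x)), if (length(x) > 1) fmt1(sd(x)) else "NA",
        fmt1(median(x)), fmt1(min(x)), fmt1(max(x))
      ))
    }
    pct <- percent_of_reference(sub)
    pc <- pct[!is.na(pct$percent), , drop = FALSE]
    pc <- pc %>%
      dplyr::group_by(.data$metric) %>%
      dplyr::summarise(percent = mean(.data$percent, na.rm = TRUE),
                       .groups = "drop")
    lines <- c(lines, "", "Percent of reference values (cohort mean):", "")
    lines <- c(lines, sprintf("- %s: %s%%", pc$metric, fmt1(pc$percent)))
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Test-retest reliability", "")
  if (is.null(reliability) || nrow(reliability) == 0) {
    lines <- c(lines, "No pairs available for reliability analysis.", "")
  } else {
    lines <- c(lines,
               "| Nutrient | Pairing | Pearson rho | ICC2 [95% CI] | Class |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(reliability))) {
      r <- reliability[i, ]
      lines <- c(lines, sprintf(
        "| %s | %s | %.2f | %.2f [%.2f, %.2f] | %s |",
        r$nutrient, r$pairing, r$pearson_rho, r$icc2,
        r$ci_lower, r$ci_upper, r$koo_li_class
      ))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
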