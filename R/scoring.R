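# Pipeline steps 1-4: mean daily portions -> variant resolution ->
# per-item nutrient contributions -> per-day totals.

# Vectorised variant resolution over a long answers table.
resolve_variants_vec <- function(schema, answers) {
  items <- dplyr::select(schema$items, "item_id", "type_question")
  dv <- schema_default_variants(schema)
  tl <- schema_type_lookup(schema)
  if (!"type_code" %in% names(answers)) answers$type_code <- NA_character_
  df <- answers %>%
    dplyr::mutate(.tc = norm_code(.data$type_code)) %>%
    dplyr::left_join(items, by = "item_id") %>%
    dplyr::left_join(dv, by = "item_id") %>%
    dplyr::left_join(dplyr::rename(tl, .tc = "type_code"),
                     by = c("item_id", ".tc"))
  # no type question -> "default"; unanswered/unresolvable -> default_variant
  out <- dplyr::coalesce(df$variant_key, df$default_variant)
  out[is.na(df$type_question)] <- "default"
  out
}

# Internal workhorse shared by score_response()/score_cohort(): takes a long
# answers table that already has key columns, returns per-key totals.
score_long <- function(schema, reference, answers, missing_as, strict,
                       key_cols) {
  answers$item_id <- as.character(answers$item_id)
  if (!"amount_code" %in% names(answers)) answers$amount_code <- NA_character_

  dup <- answers %>%
    dplyr::count(dplyr::across(dplyr::all_of(c(key_cols, "item_id")))) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_validation(sprintf(
      "duplicate answers for the same key/item: %s",
      paste(utils::head(do.call(paste, dup[c(key_cols, "item_id")]), 5),
            collapse = "; ")
    ))
  }

  scored <- withCallingHandlers(
    mean_daily_portion(answers, schema, strict = strict,
                       missing_as = missing_as),
    ffqscore_missing_answers = function(w) invokeRestart("muffleWarning")
  )
  scored$variant_key <- resolve_variants_vec(schema, scored)

  ref_cols <- .REF_NUTRIENT_COLS()
  joined <- dplyr::left_join(
    scored,
    dplyr::select(tibble::as_tibble(reference), "item_id", "variant_key",
                  dplyr::all_of(ref_cols)),
    by = c("item_id", "variant_key")
  )
  no_entry <- !paste(joined$item_id, joined$variant_key) %in%
    paste(reference$item_id, reference$variant_key)
  if (any(no_entry)) {
    bad <- unique(paste0(joined$item_id[no_entry], "/",
                         joined$variant_key[no_entry]))
    stop_validation(sprintf("no reference entry for: %s",
                            paste(utils::head(bad, 5), collapse = ", ")))
  }

  gpd <- joined$grams_per_day
  miss <- joined$answer_missing
  scale <- ifelse(miss, 0, gpd / 100)
  contrib <- as.matrix(joined[, ref_cols, drop = FALSE]) * scale
  # a zero portion contributes zero even when the nutrient cell is unknown
  contrib[scale == 0 & is.na(contrib)] <- 0

  keys <- joined[, key_cols, drop = FALSE]
  grp <- do.call(paste, c(keys, sep = "\r"))
  grp_f <- factor(grp, levels = unique(grp))
  totals <- rowsum(contrib, grp_f, na.rm = FALSE)

  answered <- rowsum((!miss) * 1L, grp_f)
  n_items <- nrow(schema$items)

  out <- dplyr::distinct(keys)
  out <- out[match(levels(grp_f), do.call(paste, c(out, sep = "\r"))), ,
             drop = FALSE]
  totals <- tibble::as_tibble(totals)
  names(totals) <- c("energy_kcal_d", paste0(.NUTRIENTS, "_mg_d"))
  # g/d reporting boundary: macronutrients converted from mg exactly once
  for (nm in .GRAM_NUTRIENTS) {
    totals[[paste0(nm, "_g_d")]] <- totals[[paste0(nm, "_mg_d")]] / 1000
    totals[[paste0(nm, "_mg_d")]] <- NULL
  }
  totals <- totals[, .INTAKE_NUTRIENT_COLS()]
  out <- dplyr::bind_cols(tibble::as_tibble(out), totals)
  out$items_scored <- as.integer(answered[, 1])
  out$items_missing <- n_items - out$items_scored
  out
}

#' Score one response record into per-day nutrient intake
#'
#' Applies the full per-record scoring chain: mean daily portions from the
#' frequency/portion categories, type-question variant resolution against
#' the reference table, per-item nutrient contributions, and summation to
#' per-day totals. Energy is reported in kcal/d; protein, fat,
#' carbohydrates, fiber and sugar in g/d (one mg-to-g conversion at this
#' boundary); all remaining nutrients in mg/d.
#'
#' Items the record does not answer are excluded from the totals and counted
#' in `items_missing` (or scored as zero with `missing_as = "zero"`).
#' Unknown (empty) nutrient cells in the reference table propagate as `NA`
#' totals when a consumed item touches them.
#'
#' @param schema An [ffq_schema()].
#' @param reference An `ffq_reference` table covering the schema.
#' @param record Data frame of one record's answers: columns `item_id`,
#'   `frequency_code`, `amount_code`, optional `type_code`.
#' @param missing_as `"exclude"` (default) or `"zero"`.
#' @param strict If `TRUE`, unresolvable codes error instead of being
#'   logged and skipped.
#' @return A one-row tibble with the intake columns, `items_scored` and
#'   `items_missing`.
#' @examples
#' sch <- degs1_schema()
#' ref <- generate_reference_table(sch, seed = 1)
#' rec <- tibble::tibble(item_id = "11", frequency_code = "1x_day",
#'                       amount_code = "medium")
#' score_response(sch, ref, rec)
#' @export
score_response <- function(schema, reference, record,
                           missing_as = c("exclude", "zero"),
                           strict = FALSE) {
  missing_as <- match.arg(missing_as)
  record <- tibble::as_tibble(record)
  record$.one <- 1L
  out <- score_long(schema, reference, record, missing_as, strict,
                    key_cols = ".one")
  dplyr::select(out, -".one")
}

#' Score a cohort of responses into an intake table
#'
#' Vectorised scoring of a long-format response table: one output row per
#' `(respondent_id, timepoint, recall_window_days)` key, sorted by key, with
#' demographics carried through untouched. Scoring is permutation-invariant
#' in the input row order.
#'
#' @param schema An [ffq_schema()].
#' @param reference An `ffq_reference`.
#' @param responses Long-format tibble with columns `respondent_id`,
#'   `timepoint`, `recall_window_days`, `item_id`, `frequency_code`,
#'   `amount_code`, optional `type_code`, plus optional demographic columns
#'   (constant within key).
#' @inheritParams score_response
#' @return A tibble of class `ffq_intake`: key columns, intake columns,
#'   `items_scored`, `items_missing`, demographics, and an `outlier_flag`
#'   column (`NA` until [iqr_energy_filter()] sets it).
#' @export
score_cohort <- function(schema, reference, responses,
                         missing_as = c("exclude", "zero"),
                         strict = FALSE) {
  missing_as <- match.arg(missing_as)
  responses <- tibble::as_tibble(responses)
  assert_cols(responses, c(.KEY_COLS, "item_id", "frequency_code"),
              "responses")
  core <- c(.KEY_COLS, "item_id", "frequency_code", "amount_code",
            "type_code")
  demo_cols <- setdiff(names(responses), core)

  if (nrow(responses) == 0) {
    out <- dplyr::bind_cols(
      tibble::tibble(respondent_id = character(), timepoint = character(),
                     recall_window_days = integer()),
      tibble::as_tibble(setNames(
        lapply(.INTAKE_NUTRIENT_COLS(), function(x) double()),
        .INTAKE_NUTRIENT_COLS()
      )),
      tibble::tibble(items_scored = integer(), items_missing = integer(),
                     outlier_flag = logical())
    )
    class(out) <- c("ffq_intake", class(out))
    return(out)
  }

  out <- score_long(schema, reference, responses, missing_as, strict,
                    key_cols = .KEY_COLS)

  if (length(demo_cols) > 0) {
    demo <- responses %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(.KEY_COLS))) %>%
      dplyr::summarise(dplyr::across(dplyr::all_of(demo_cols), dplyr::first),
                       .groups = "drop")
    out <- dplyr::left_join(out, demo, by = .KEY_COLS)
  }
  out$outlier_flag <- NA
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(.KEY_COLS)))
  class(out) <- c("ffq_intake", class(out))
  out
}

#' Macronutrient mass shares
#'
#' Shares of carbohydrates, fat, protein and fiber in their summed daily
#' mass (grams; energy is not considered). Shares sum to one per row.
#'
#' @param intake An intake tibble (or a one-row intake) with the columns
#'   `carbohydrates_g_d`, `fat_g_d`, `protein_g_d`, `fiber_g_d`.
#' @return A tibble of class `ffq_shares`: any key columns present plus
#'   `nutrient` and `share` in long format.
#' @export
macronutrient_shares <- function(intake) {
  intake <- tibble::as_tibble(intake)
  comp <- c("carbohydrates_g_d", "fat_g_d", "protein_g_d", "fiber_g_d")
  assert_cols(intake, comp, "intake")
  m <- as.matrix(intake[, comp])
  tot <- rowSums(m)
  if (any(!is.na(tot) & tot <= 0)) {
    stop_validation("macronutrient shares undefined: all-zero masses in at least one row")
  }
  keys <- intersect(.KEY_COLS, names(intake))
  out <- dplyr::bind_cols(
    intake[, keys, drop = FALSE],
    tibble::as_tibble(m / tot)
  )
  names(out) <- c(keys, c("carbohydrates", "fat", "protein", "fiber"))
  out <- tidyr::pivot_longer(out, dplyr::all_of(c("carbohydrates", "fat",
                                                  "protein", "fiber")),
                             names_to = "nutrient", values_to = "share")
  class(out) <- c("ffq_shares", class(out))
  out
}

#' Write an intake table CSV
#'
#' One row per key, documented column order, unit suffixes in the header
#' (`fiber_g_d`, `tyrosine_mg_d`, ...), with a provenance comment header.
#'
#' @param intake An `ffq_intake` tibble.
#' @param path Output path.
#' @param provenance Character vector of provenance lines.
#' @return The path, invisibly.
#' @export
write_intake <- function(intake, path, provenance = character()) {
  write_csv_prov(tibble::as_tibble(intake), path, provenance)
}

#' Read an intake table CSV written by [write_intake()]
#'
#' @param path CSV path.
#' @return An `ffq_intake` tibble.
#' @export
read_intake <- function(path) {
  df <- read_csv_prov(path, col_types = readr::cols(
    respondent_id = readr::col_character(),
    timepoint = readr::col_character()
  ))
  class(df) <- c("ffq_intake", class(df))
  df
}
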