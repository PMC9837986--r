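# Food composition reference table: per-100 g nutrient vectors per
# item x variant, with unit-checked CSV round-trip.

#' Construct and validate a nutrient reference table
#'
#' A reference table holds one nutrient vector per `(item_id, variant_key)`
#' pair: energy in kcal/100 g, every other nutrient in mg/100 g. The variant
#' key `"default"` is the entry used for items without a type question;
#' items covered by a type question additionally carry one entry per answer
#' variant.
#'
#' @param entries Tibble with columns `item_id`, `variant_key`, `source`,
#'   `energy_kcal_100g` and `<nutrient>_mg_100g` for the 17 tracked
#'   nutrients (protein, fat, carbohydrates, fiber, sugar, the fiber
#'   subclasses cellulose/lignin/soluble/insoluble, tyrosine, tryptophan,
#'   saturated and short/medium/long-chain fatty acids, omega-3, omega-6).
#'   Empty cells mean "unknown" and are distinguished from zero.
#' @param provenance Free-text provenance note.
#' @param schema Optional [ffq_schema()]; when given, coverage is checked:
#'   every schema item needs a `"default"` entry and every variant named by
#'   a type question must exist for each covered item.
#' @return A tibble of class `ffq_reference` with a `provenance` attribute.
#' @export
ffq_reference <- function(entries, provenance = "unspecified", schema = NULL) {
  entries <- tibble::as_tibble(entries)
  assert_cols(entries, c("item_id", "variant_key", .REF_NUTRIENT_COLS()),
              "reference table")
  if (!"source" %in% names(entries)) entries$source <- NA_character_
  entries$item_id <- as.character(entries$item_id)
  key <- paste(entries$item_id, entries$variant_key)
  if (anyDuplicated(key)) {
    stop_validation(sprintf(
      "duplicate (item_id, variant_key) entries: %s",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    ))
  }
  for (col in .REF_NUTRIENT_COLS()) {
    bad <- !is.na(entries[[col]]) & entries[[col]] < 0
    if (any(bad)) {
      stop_validation(sprintf(
        "negative value(s) in '%s' for item(s) %s",
        col, paste(unique(entries$item_id[bad]), collapse = ", ")
      ))
    }
  }
  # fiber subclasses must each stay within total fiber; sugar within carb
  chk_le <- function(part, whole, label) {
    p <- entries[[part]]; w <- entries[[whole]]
    bad <- !is.na(p) & !is.na(w) & p > w * (1 + 1e-9)
    if (any(bad)) {
      stop_validation(sprintf(
        "%s exceeds %s for item(s) %s", label, whole,
        paste(unique(entries$item_id[bad]), collapse = ", ")
      ))
    }
  }
  for (sub in c("cellulose", "lignin", "fiber_soluble", "fiber_insoluble")) {
    chk_le(paste0(sub, "_mg_100g"), "fiber_mg_100g", sub)
  }
  chk_le("sugar_mg_100g", "carbohydrates_mg_100g", "sugar")

  if (!is.null(schema)) {
    defaults <- entries$item_id[entries$variant_key == "default"]
    no_default <- setdiff(schema$items$item_id, defaults)
    if (length(no_default) > 0) {
      stop_validation(sprintf(
        "item(s) %s have no default entry in the reference table",
        paste(no_default, collapse = ", ")
      ))
    }
    for (tq in schema$type_questions) {
      need <- tidyr::expand_grid(item_id = tq$item_ids,
                                 variant_key = unique(tq$options$variant))
      have <- paste(entries$item_id, entries$variant_key)
      miss <- need[!paste(need$item_id, need$variant_key) %in% have, ]
      if (nrow(miss) > 0) {
        stop_validation(sprintf(
          "missing variant entr%s: %s",
          if (nrow(miss) > 1) "ies" else "y",
          paste(sprintf("item %s/%s", miss$item_id, miss$variant_key),
                collapse = ", ")
        ))
      }
    }
  }
  structure(entries, provenance = provenance,
            class = c("ffq_reference", class(entries)))
}

#' Read a reference table CSV
#'
#' The CSV declares units in its header (`energy_kcal_100g`,
#' `fiber_mg_100g`, ...); the header contract is verified on load. Empty
#' cells are unknown values, not zeros, and propagate as `NA` into totals.
#'
#' @param path CSV path. Lines starting with `#` are treated as provenance
#'   comments.
#' @inheritParams ffq_reference
#' @return A validated `ffq_reference` tibble.
#' @export
load_reference_table <- function(path, schema = NULL) {
  df <- read_csv_prov(path, col_types = readr::cols(
    item_id = readr::col_character(),
    variant_key = readr::col_character(),
    source = readr::col_character(),
    .default = readr::col_double()
  ))
  if ("source" %in% names(df)) df$source <- as.character(df$source)
  ffq_reference(df, provenance = path, schema = schema)
}

#' Write a reference table CSV
#'
#' @param table An `ffq_reference` tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_reference_table <- function(table, path) {
  cols <- c("item_id", "variant_key", "source", .REF_NUTRIENT_COLS())
  write_csv_prov(dplyr::select(tibble::as_tibble(table),
                               dplyr::all_of(cols)), path,
                 provenance = sprintf("reference table: %s",
                                      attr(table, "provenance") %||% ""))
  invisible(path)
}

#' Resolve a type-question answer to a reference entry
#'
#' Items covered by a type question carry several nutrient variants (e.g.
#' fried vs. cooked, with vs. without sugar). Given the item and the
#' (possibly missing) type answer, this returns the reference entry that
#' scoring must use: the matching variant when the code resolves, the type
#' question's default variant (logged) when unanswered, and the `"default"`
#' entry for items without a type question.
#'
#' @param schema An [ffq_schema()].
#' @param table An `ffq_reference`.
#' @param item_id Item identifier.
#' @param type_code Answer code of the type question, or `NA`.
#' @param strict If `TRUE`, a type code supplied for an item without a type
#'   question (or an unresolvable code) is an error instead of a warning.
#' @return The matching one-row reference entry tibble.
#' @export
resolve_variant <- function(schema, table, item_id, type_code = NA,
                            strict = FALSE) {
  item_id <- as.character(item_id)
  it <- schema$items[schema$items$item_id == item_id, ]
  if (nrow(it) == 0) {
    stop_validation(sprintf("item '%s' not in schema", item_id))
  }
  tc <- norm_code(type_code)
  variant <- "default"
  if (is.na(it$type_question)) {
    if (!is.na(tc)) {
      msg <- sprintf("item %s has no type question; ignoring type code '%s'",
                     item_id, tc)
      if (strict) stop_validation(msg) else warn(msg)
    }
  } else {
    tq <- schema$type_questions[[it$type_question]]
    if (is.na(tc)) {
      variant <- tq$default_variant
      inform(sprintf("item %s: type question unanswered, using default variant '%s'",
                     item_id, variant))
    } else if (tc %in% tq$options$code) {
      variant <- tq$options$variant[match(tc, tq$options$code)]
    } else {
      msg <- sprintf("item %s: type code '%s' not an option of '%s'",
                     item_id, tc, tq$question_id)
      if (strict) stop_validation(msg)
      warn(msg)
      variant <- tq$default_variant
    }
  }
  entry <- table[table$item_id == item_id & table$variant_key == variant, ]
  if (nrow(entry) == 0) {
    stop_validation(sprintf("no reference entry for item %s variant '%s'",
                            item_id, variant))
  }
  entry
}

#' Per-day nutrient contribution of one item
#'
#' Scales a per-100 g reference entry to the consumed grams per day:
#' energy stays kcal/d, all other nutrients mg/d. The operation is
#' homogeneous of degree one in `grams_per_day`.
#'
#' @param entry A one-row reference entry (from [resolve_variant()]).
#' @param grams_per_day Non-negative grams per day.
#' @return A one-row tibble of per-day contributions, columns
#'   `energy_kcal_d` and `<nutrient>_mg_d`.
#' @export
nutrients_for_portion <- function(entry, grams_per_day) {
  if (any(grams_per_day < 0, na.rm = TRUE)) {
    stop_validation("grams_per_day must be >= 0")
  }
  vals <- as.matrix(entry[, .REF_NUTRIENT_COLS(), drop = FALSE])
  out <- vals * (grams_per_day / 100)
  colnames(out) <- c("energy_kcal_d", paste0(.NUTRIENTS, "_mg_d"))
  tibble::as_tibble(out)
}
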