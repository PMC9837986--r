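# Questionnaire schema: items, frequency/portion category maps, type questions.

#' Construct a food-frequency questionnaire schema
#'
#' A schema describes the structure of an FFQ instrument: the list of food
#' items, the frequency categories (how often something was eaten, as
#' consumption occurrences over a reference period in days), the portion
#' categories (grams per occasion), and the optional "type" follow-up
#' questions that refine an item (e.g. fried vs. cooked, with vs. without
#' sugar) by selecting a nutrient variant in the reference table.
#'
#' All engine code treats category values as data carried by the schema,
#' never as constants: scoring normalises every frequency to per-day, so
#' responses with different recall windows (24 h up to 4 weeks) flow through
#' identical code.
#'
#' @param schema_id Character label identifying the instrument.
#' @param recall_window_days Default recall window of the instrument; one of
#'   1, 7, 14, 28 days.
#' @param items Tibble with columns `item_id`, `name`, `food_group`,
#'   `frequency_map`, `portion_map`, `type_question` (NA when the item has no
#'   type question).
#' @param frequency_maps Named list of tibbles with columns `code`, `label`,
#'   `occurrences` (>= 0) and `period_days` (> 0).
#' @param portion_maps Named list of tibbles with columns `code`, `label`,
#'   `grams` (>= 0 grams per occasion).
#' @param type_questions Named list; each element has `question_id`,
#'   `item_ids`, `options` (a tibble with columns `code`, `variant` in
#'   increasing-energy order) and `default_variant` (used when the type
#'   question is unanswered; must be one of the options' variants).
#'
#' @return An object of class `ffq_schema`.
#' @seealso [load_schema()] to read a schema from a YAML config,
#'   [degs1_schema()] for the shipped 53-item instrument.
#' @export
ffq_schema <- function(schema_id, recall_window_days, items,
                       frequency_maps, portion_maps,
                       type_questions = list()) {
  items <- tibble::as_tibble(items)
  if (!"type_question" %in% names(items)) items$type_question <- NA_character_
  items$item_id <- as.character(items$item_id)
  frequency_maps <- lapply(frequency_maps, function(m) {
    m <- tibble::as_tibble(m)
    m$code <- norm_code(m$code)
    m
  })
  portion_maps <- lapply(portion_maps, function(m) {
    m <- tibble::as_tibble(m)
    m$code <- norm_code(m$code)
    m
  })
  type_questions <- lapply(type_questions, function(tq) {
    tq$options <- tibble::as_tibble(tq$options)
    tq$options$code <- norm_code(tq$options$code)
    tq$item_ids <- as.character(tq$item_ids)
    tq
  })
  out <- structure(
    list(
      schema_id = as.character(schema_id),
      recall_window_days = as.integer(recall_window_days),
      items = items,
      frequency_maps = frequency_maps,
      portion_maps = portion_maps,
      type_questions = type_questions
    ),
    class = "ffq_schema"
  )
  validate_ffq_schema(out)
  out
}

validate_ffq_schema <- function(x) {
  items <- x$items
  assert_cols(items, c("item_id", "name", "food_group",
                       "frequency_map", "portion_map"), "schema items")
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup) > 0) {
    stop_validation(sprintf("duplicate item_id in schema: %s",
                            paste(unique(dup), collapse = ", ")))
  }
  if (!x$recall_window_days %in% .VALID_WINDOWS) {
    stop_validation(sprintf(
      "recall_window_days must be one of %s (got %s)",
      paste(.VALID_WINDOWS, collapse = ", "), x$recall_window_days
    ))
  }
  for (nm in names(x$frequency_maps)) {
    m <- x$frequency_maps[[nm]]
    assert_cols(m, c("code", "occurrences", "period_days"),
                sprintf("frequency map '%s'", nm))
    if (anyDuplicated(m$code)) {
      stop_validation(sprintf("duplicate codes in frequency map '%s'", nm))
    }
    if (any(m$occurrences < 0) || any(m$period_days <= 0)) {
      stop_validation(sprintf(
        "frequency map '%s': occurrences must be >= 0 and period_days > 0", nm
      ))
    }
  }
  for (nm in names(x$portion_maps)) {
    m <- x$portion_maps[[nm]]
    assert_cols(m, c("code", "grams"), sprintf("portion map '%s'", nm))
    if (anyDuplicated(m$code)) {
      stop_validation(sprintf("duplicate codes in portion map '%s'", nm))
    }
    if (any(m$grams < 0)) {
      stop_validation(sprintf("portion map '%s': grams must be >= 0", nm))
    }
  }
  bad_fm <- setdiff(items$frequency_map, names(x$frequency_maps))
  if (length(bad_fm) > 0) {
    stop_validation(sprintf("unknown frequency map(s): %s",
                            paste(bad_fm, collapse = ", ")))
  }
  bad_pm <- setdiff(items$portion_map, names(x$portion_maps))
  if (length(bad_pm) > 0) {
    stop_validation(sprintf("unknown portion map(s): %s",
                            paste(bad_pm, collapse = ", ")))
  }
  tq_ref <- items$type_question[!is.na(items$type_question)]
  bad_tq <- setdiff(tq_ref, names(x$type_questions))
  if (length(bad_tq) > 0) {
    stop_validation(sprintf("unknown type question(s): %s",
                            paste(bad_tq, collapse = ", ")))
  }
  for (nm in names(x$type_questions)) {
    tq <- x$type_questions[[nm]]
    assert_cols(tq$options, c("code", "variant"),
                sprintf("type question '%s' options", nm))
    if (nrow(tq$options) == 0 || any(is.na(tq$options$variant)) ||
        any(tq$options$variant == "")) {
      stop_validation(sprintf(
        "type question '%s' has an option without a variant", nm
      ))
    }
    if (!tq$default_variant %in% tq$options$variant) {
      stop_validation(sprintf(
        "type question '%s': default_variant '%s' is not an option variant",
        nm, tq$default_variant
      ))
    }
    missing_items <- setdiff(tq$item_ids, items$item_id)
    if (length(missing_items) > 0) {
      stop_validation(sprintf(
        "type question '%s' covers unknown item(s): %s",
        nm, paste(missing_items, collapse = ", ")
      ))
    }
  }
  invisible(x)
}

#' @export
print.ffq_schema <- function(x, ...) {
  n_tq <- sum(!is.na(x$items$type_question))
  cat(sprintf(
    "<ffq_schema '%s'> %d items (%d with type questions), default window %d d\n",
    x$schema_id, nrow(x$items), n_tq, x$recall_window_days
  ))
  invisible(x)
}

#' Load a questionnaire schema from a YAML config file
#'
#' The config has top-level keys `schema_id`, `recall_window_days`,
#' `frequency_maps`, `portion_maps`, `type_questions` and `items`; see the
#' shipped `degs1_schema_synthetic.yaml` under `inst/extdata` for the
#' documented layout. Category codes are lower-cased and trimmed on read.
#'
#' @param path Path to the YAML schema config.
#' @return A validated [ffq_schema()] object.
#' @examples
#' sch <- degs1_schema()
#' nrow(sch$items)
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("schema file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_io(sprintf("failed to parse schema '%s': %s", path, conditionMessage(e)))
  })
  for (key in c("schema_id", "items", "frequency_maps", "portion_maps")) {
    if (is.null(raw[[key]])) {
      stop_io(sprintf("schema '%s': missing top-level key '%s'", path, key))
    }
  }
  fmaps <- lapply(raw$frequency_maps, function(m) {
    dplyr::bind_rows(lapply(m, tibble::as_tibble))
  })
  pmaps <- lapply(raw$portion_maps, function(m) {
    dplyr::bind_rows(lapply(m, tibble::as_tibble))
  })
  tqs <- lapply(raw$type_questions %||% list(), function(tq) {
    list(
      question_id = tq$question_id,
      item_ids = as.character(tq$item_ids),
      options = dplyr::bind_rows(lapply(tq$options, tibble::as_tibble)),
      default_variant = tq$default_variant
    )
  })
  if (length(tqs) > 0) {
    names(tqs) <- vapply(tqs, `[[`, character(1), "question_id")
  }
  items <- dplyr::bind_rows(lapply(raw$items, function(it) {
    tibble::tibble(
      item_id = as.character(it$item_id),
      name = it$name,
      food_group = it$food_group,
      frequency_map = it$frequency_map,
      portion_map = it$portion_map,
      type_question = it$type_question %||% NA_character_
    )
  }))
  ffq_schema(
    schema_id = raw$schema_id,
    recall_window_days = raw$recall_window_days %||% 7L,
    items = items,
    frequency_maps = fmaps,
    portion_maps = pmaps,
    type_questions = tqs
  )
}

#' The shipped 53-item DEGS1-style schema
#'
#' Loads the packaged questionnaire structure: 53 food items in nine food
#' groups, 16 of which carry a type question refining preparation, fat
#' content, sweetening or dilution. The category values (grams per portion,
#' occurrences per period) are synthetic representative values — the file is
#' named accordingly — because the original instrument's category tables are
#' distributed separately from any publication; the structure (item count,
#' type-question count, map shapes) matches the instrument.
#'
#' @return An [ffq_schema()] object with 53 items.
#' @export
degs1_schema <- function() {
  load_schema(system.file("extdata", "degs1_schema_synthetic.yaml",
                          package = "ffqscore", mustWork = TRUE))
}

# Flattened lookup tables used by the vectorised scorer ------------------

schema_freq_lookup <- function(schema) {
  dplyr::bind_rows(lapply(names(schema$frequency_maps), function(nm) {
    dplyr::mutate(schema$frequency_maps[[nm]], frequency_map = nm)
  }))
}

schema_portion_lookup <- function(schema) {
  dplyr::bind_rows(lapply(names(schema$portion_maps), function(nm) {
    dplyr::mutate(schema$portion_maps[[nm]], portion_map = nm)
  }))
}

schema_type_lookup <- function(schema) {
  if (length(schema$type_questions) == 0) {
    return(tibble::tibble(item_id = character(), type_code = character(),
                          variant_key = character()))
  }
  dplyr::bind_rows(lapply(schema$type_questions, function(tq) {
    tidyr::expand_grid(
      item_id = tq$item_ids,
      tibble::tibble(type_code = tq$options$code,
                     variant_key = tq$options$variant)
    )
  }))
}

schema_default_variants <- function(schema) {
  items <- schema$items
  dv <- vapply(seq_len(nrow(items)), function(i) {
    tq <- items$type_question[i]
    if (is.na(tq)) "default" else schema$type_questions[[tq]]$default_variant
  }, character(1))
  tibble::tibble(item_id = items$item_id, default_variant = dv)
}

#' Compute mean daily portions in grams per day
#'
#' The first scoring step: each answered item's portion mass (grams per
#' occasion) is multiplied by the reported consumption occurrences and
#' divided by the period those occurrences refer to, yielding grams per day.
#' An `amount_code` that does not resolve in the item's portion map but
#' parses as a number is treated as free grams per occasion.
#'
#' @param answers Data frame with columns `item_id`, `frequency_code`,
#'   `amount_code`. Extra columns are carried through.
#' @param schema An [ffq_schema()].
#' @param strict If `TRUE`, unresolvable codes raise an error naming the
#'   item; otherwise they are marked missing with a warning.
#' @param missing_as Either `"exclude"` (default: missing answers score
#'   `NA` grams/day and are excluded from totals, logged) or `"zero"`.
#' @return The input with columns `grams_per_day` and `answer_missing`
#'   appended. A frequency with zero occurrences scores 0 g/d regardless of
#'   the portion answer.
#' @examples
#' sch <- degs1_schema()
#' ans <- tibble::tibble(item_id = "1", frequency_code = "1x_day",
#'                       amount_code = "2_slices")
#' mean_daily_portion(ans, sch)
#' @export
mean_daily_portion <- function(answers, schema, strict = FALSE,
                               missing_as = c("exclude", "zero")) {
  missing_as <- match.arg(missing_as)
  answers <- tibble::as_tibble(answers)
  assert_cols(answers, c("item_id", "frequency_code", "amount_code"),
              "answers")
  answers$item_id <- as.character(answers$item_id)
  bad_items <- setdiff(unique(answers$item_id), schema$items$item_id)
  if (length(bad_items) > 0) {
    stop_validation(sprintf("answers reference unknown item(s): %s",
                            paste(bad_items, collapse = ", ")))
  }
  df <- answers %>%
    dplyr::mutate(
      .freq_code = norm_code(.data$frequency_code),
      .amt_code = norm_code(.data$amount_code)
    ) %>%
    dplyr::left_join(
      dplyr::select(schema$items, "item_id", "frequency_map", "portion_map"),
      by = "item_id"
    ) %>%
    dplyr::left_join(
      dplyr::select(schema_freq_lookup(schema), "frequency_map",
                    .freq_code = "code", "occurrences", "period_days"),
      by = c("frequency_map", ".freq_code")
    ) %>%
    dplyr::left_join(
      dplyr::select(schema_portion_lookup(schema), "portion_map",
                    .amt_code = "code", "grams"),
      by = c("portion_map", ".amt_code")
    )

  free_grams <- suppressWarnings(as.numeric(df$.amt_code))
  use_free <- is.na(df$grams) & !is.na(free_grams) & free_grams >= 0
  df$grams[use_free] <- free_grams[use_free]

  freq_unresolved <- !is.na(df$.freq_code) & is.na(df$occurrences)
  amt_unresolved <- !is.na(df$.amt_code) & is.na(df$grams)
  if (strict && any(freq_unresolved | amt_unresolved)) {
    bad <- unique(df$item_id[freq_unresolved | amt_unresolved])
    stop_validation(sprintf("unresolvable answer code(s) for item(s): %s",
                            paste(bad, collapse = ", ")))
  }

  gpd <- df$grams * df$occurrences / df$period_days
  # zero occurrences score 0 g/d even when the portion answer is missing
  zero_freq <- !is.na(df$occurrences) & df$occurrences == 0
  gpd[zero_freq] <- 0
  missing <- is.na(gpd)
  if (any(missing) && missing_as == "exclude") {
    warn(sprintf("%d answer(s) missing or unresolvable; excluded from totals",
                 sum(missing)), class = "ffqscore_missing_answers")
  }
  if (missing_as == "zero") {
    gpd[missing] <- 0
    missing[] <- FALSE
  }
  answers$grams_per_day <- gpd
  answers$answer_missing <- missing
  answers
}

#' Validate a response record against a schema
#'
#' Checks one respondent-by-timepoint set of answers for completeness and
#' plausibility: schema items with no answer, answer codes that do not
#' resolve in the item's category maps, unknown items, and a recall window
#' outside the supported set.
#'
#' @param schema An [ffq_schema()].
#' @param record Data frame of answers (one row per item) with columns
#'   `item_id`, `frequency_code`, `amount_code`, optionally `type_code` and
#'   `recall_window_days`.
#' @return A list of class `ffq_validation_report` with `issues` (tibble:
#'   `type`, `item_id`, `detail`) and `completeness` (answered items divided
#'   by the schema's item count). Always returns a report, never errors.
#' @export
validate_response <- function(schema, record) {
  record <- tibble::as_tibble(record)
  assert_cols(record, c("item_id", "frequency_code"), "response record")
  record$item_id <- as.character(record$item_id)
  issues <- list()
  add_issue <- function(type, item_id, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      type = type, item_id = as.character(item_id), detail = detail
    )
  }

  unknown <- setdiff(unique(record$item_id), schema$items$item_id)
  for (id in unknown) add_issue("unknown_item", id, "item not in schema")

  known <- record[record$item_id %in% schema$items$item_id, ]
  answered <- known$item_id[!is.na(norm_code(known$frequency_code))]
  missing_items <- setdiff(schema$items$item_id, answered)
  for (id in missing_items) add_issue("missing", id, "no frequency answer")

  # unresolvable codes
  lk <- dplyr::left_join(
    dplyr::mutate(known, .fc = norm_code(.data$frequency_code),
                  .ac = if ("amount_code" %in% names(known))
                    norm_code(.data$amount_code) else NA_character_),
    dplyr::select(schema$items, "item_id", "frequency_map", "portion_map"),
    by = "item_id"
  )
  fl <- schema_freq_lookup(schema)
  pl <- schema_portion_lookup(schema)
  for (i in seq_len(nrow(lk))) {
    fc <- lk$.fc[i]
    if (!is.na(fc) &&
        !fc %in% fl$code[fl$frequency_map == lk$frequency_map[i]]) {
      add_issue("unresolvable_code", lk$item_id[i],
                sprintf("frequency code '%s' not in map '%s'",
                        fc, lk$frequency_map[i]))
    }
    ac <- lk$.ac[i]
    if (!is.na(ac) &&
        !ac %in% pl$code[pl$portion_map == lk$portion_map[i]] &&
        is.na(suppressWarnings(as.numeric(ac)))) {
      add_issue("unresolvable_code", lk$item_id[i],
                sprintf("amount code '%s' not in map '%s'",
                        ac, lk$portion_map[i]))
    }
  }

  if ("recall_window_days" %in% names(record)) {
    w <- unique(record$recall_window_days)
    w <- w[!is.na(w)]
    for (ww in setdiff(w, .VALID_WINDOWS)) {
      add_issue("window_mismatch", NA,
                sprintf("recall window %s d not in {%s}", ww,
                        paste(.VALID_WINDOWS, collapse = ", ")))
    }
  }

  issues <- if (length(issues) > 0) dplyr::bind_rows(issues) else
    tibble::tibble(type = character(), item_id = character(),
                   detail = character())
  structure(
    list(
      issues = issues,
      completeness = length(unique(answered)) / nrow(schema$items)
    ),
    class = "ffq_validation_report"
  )
}

#' @export
print.ffq_validation_report <- function(x, ...) {
  cat(sprintf("<ffq_validation_report> completeness %.3f, %d issue(s)\n",
              x$completeness, nrow(x$issues)))
  if (nrow(x$issues) > 0) print(utils::head(x$issues, 10))
  invisible(x)
}
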