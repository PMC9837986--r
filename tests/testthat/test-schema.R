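# Schema loading, validation and mean-daily-portion computation.

test_that("shipped schema has the 53-item structure with 16 type questions", {
  sch <- demo_schema()
  expect_s3_class(sch, "ffq_schema")
  expect_equal(nrow(sch$items), 53)
  expect_equal(sum(!is.na(sch$items$type_question)), 16)
  expect_equal(length(sch$type_questions), 16)
  expect_false(anyDuplicated(sch$items$item_id) > 0)
})

test_that("minimal one-item schema is valid and duplicates are rejected", {
  one <- ffq_schema(
    "mini", 7,
    items = tibble::tibble(item_id = "1", name = "x", food_group = "misc",
                           frequency_map = "f", portion_map = "p",
                           type_question = NA_character_),
    frequency_maps = list(f = tibble::tibble(code = "daily", label = "d",
                                             occurrences = 1, period_days = 1)),
    portion_maps = list(p = tibble::tibble(code = "one", label = "o",
                                           grams = 100))
  )
  expect_equal(nrow(one$items), 1)
  expect_equal(length(one$type_questions), 0)

  expect_error(
    ffq_schema(
      "dup", 7,
      items = tibble::tibble(item_id = c("7", "7"), name = c("a", "b"),
                             food_group = "misc", frequency_map = "f",
                             portion_map = "p",
                             type_question = NA_character_),
      frequency_maps = list(f = tibble::tibble(code = "daily", label = "d",
                                               occurrences = 1,
                                               period_days = 1)),
      portion_maps = list(p = tibble::tibble(code = "one", label = "o",
                                             grams = 100))
    ),
    regexp = "duplicate item_id.*7", class = "ffqscore_validation_error"
  )
})

test_that("schema invariants are enforced on load-time validation", {
  sch <- tiny_schema()
  # type question default must be an option variant
  bad <- sch
  bad$type_questions$tq_sugar$default_variant <- "nonexistent"
  expect_error(validate_ffq_schema <- ffqscore:::validate_ffq_schema(bad),
               class = "ffqscore_validation_error")
  # negative grams rejected
  expect_error(
    ffq_schema("x", 7, sch$items, sch$frequency_maps,
               list(por = tibble::tibble(code = "s", label = "s",
                                         grams = -5)),
               sch$type_questions),
    class = "ffqscore_validation_error"
  )
  # recall window restricted
  expect_error(
    ffq_schema("x", 3, sch$items, sch$frequency_maps, sch$portion_maps,
               sch$type_questions),
    regexp = "recall_window_days", class = "ffqscore_validation_error"
  )
})

test_that("mean daily portion follows grams x occurrences / period", {
  sch <- tiny_schema()
  gpd <- function(freq, amt) {
    ans <- tibble::tibble(item_id = "1", frequency_code = freq,
                          amount_code = amt)
    mean_daily_portion(ans, sch)$grams_per_day
  }
  expect_equal(gpd("daily", "large"), 200 * 1 / 1)
  expect_equal(gpd("3x_week", "large"), 200 * 3 / 7)
  expect_equal(gpd("never", "small"), 0)
  # free grams per occasion
  expect_equal(gpd("twice_daily", "150"), 150 * 2)
  # codes are case-insensitive and trimmed
  expect_equal(gpd(" DAILY ", "Large"), 200)
})

test_that("mean daily portion is linear in portions and occurrences", {
  base <- tibble::tibble(code = "c", label = "c", occurrences = 3,
                         period_days = 7)
  mk <- function(occ, period, grams) {
    ffq_schema(
      "lin", 7,
      items = tibble::tibble(item_id = "1", name = "x", food_group = "misc",
                             frequency_map = "f", portion_map = "p",
                             type_question = NA_character_),
      frequency_maps = list(f = tibble::tibble(code = "c", label = "c",
                                               occurrences = occ,
                                               period_days = period)),
      portion_maps = list(p = tibble::tibble(code = "g", label = "g",
                                             grams = grams))
    )
  }
  ans <- tibble::tibble(item_id = "1", frequency_code = "c",
                        amount_code = "g")
  g0 <- mean_daily_portion(ans, mk(3, 7, 100))$grams_per_day
  expect_equal(mean_daily_portion(ans, mk(3, 7, 200))$grams_per_day, 2 * g0)
  expect_equal(mean_daily_portion(ans, mk(6, 7, 100))$grams_per_day, 2 * g0)
  # halving the period doubles the rate
  expect_equal(mean_daily_portion(ans, mk(3, 3.5, 100))$grams_per_day, 2 * g0)
})

test_that("missing and unresolvable answers follow the missing policy", {
  sch <- tiny_schema()
  ans <- tibble::tibble(item_id = c("1", "2"),
                        frequency_code = c("daily", "bogus"),
                        amount_code = c("small", "small"))
  expect_warning(out <- mean_daily_portion(ans, sch),
                 class = "ffqscore_missing_answers")
  expect_true(is.na(out$grams_per_day[2]))
  expect_true(out$answer_missing[2])
  expect_error(mean_daily_portion(ans, sch, strict = TRUE),
               regexp = "item", class = "ffqscore_validation_error")
  out0 <- mean_daily_portion(ans, sch, missing_as = "zero")
  expect_equal(out0$grams_per_day[2], 0)
})

test_that("validate_response reports completeness and issue types", {
  sch <- demo_schema()
  rec <- random_record(sch, seed = 3)
  rep_full <- validate_response(sch, rec)
  expect_equal(rep_full$completeness, 1)
  expect_equal(nrow(rep_full$issues), 0)

  rep_miss <- validate_response(sch, rec[-(1:5), ])
  expect_equal(rep_miss$completeness, 48 / 53)
  expect_equal(sum(rep_miss$issues$type == "missing"), 5)

  rec_bad <- rec
  rec_bad$frequency_code[1] <- "xyz"
  rep_bad <- validate_response(sch, rec_bad)
  expect_true(any(rep_bad$issues$type == "unresolvable_code" &
                    rep_bad$issues$item_id == rec$item_id[1]))
  expect_true(grepl("xyz", rep_bad$issues$detail[
    rep_bad$issues$type == "unresolvable_code"][1]))

  rec_w <- rec
  rec_w$recall_window_days <- 3
  rep_w <- validate_response(sch, rec_w)
  expect_true(any(rep_w$issues$type == "window_mismatch"))
  # completeness is always in [0, 1]
  expect_true(all(vapply(
    list(rep_full, rep_miss, rep_bad),
    function(r) r$completeness >= 0 && r$completeness <= 1, logical(1)
  )))
})
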