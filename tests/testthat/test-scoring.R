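# Per-record and cohort scoring: units, additivity, linearity,
# permutation invariance, cohort-vs-record oracle.

test_that("all-never record scores zero intake with every item scored", {
  sch <- demo_schema()
  ref <- demo_reference()
  rec <- tibble::tibble(item_id = sch$items$item_id,
                        frequency_code = "never", amount_code = NA)
  out <- score_response(sch, ref, rec)
  expect_equal(out$items_scored, 53)
  expect_equal(out$items_missing, 0)
  expect_equal(sum(abs(as.matrix(out[, ffqscore:::.INTAKE_NUTRIENT_COLS()]))),
               0)
})

test_that("single-item record reproduces the unit-scaling arithmetic", {
  sch <- tiny_schema()
  ref <- tiny_reference(sch)
  # 100 g/d of an item with 100 kcal/100 g and 2500 mg fiber/100 g
  rec <- tibble::tibble(item_id = "1", frequency_code = "daily",
                        amount_code = "small")
  out <- suppressWarnings(score_response(sch, ref, rec))
  expect_equal(out$energy_kcal_d, 100)
  expect_equal(out$fiber_g_d, 2.5)      # g/d boundary conversion
  expect_equal(out$protein_g_d, 10)
  expect_equal(out$tyrosine_mg_d, 100)  # stays mg/d
  expect_equal(out$items_scored, 1)
  expect_equal(out$items_missing, 1)
})

test_that("doubling every portion doubles every nutrient total", {
  sch <- demo_schema()
  ref <- demo_reference()
  items <- sch$items$item_id
  g <- seq(10, 530, by = 10)
  rec1 <- tibble::tibble(item_id = items, frequency_code = "1x_day",
                         amount_code = as.character(g))
  rec2 <- dplyr::mutate(rec1, amount_code = as.character(2 * g))
  o1 <- score_response(sch, ref, rec1)
  o2 <- score_response(sch, ref, rec2)
  cols <- ffqscore:::.INTAKE_NUTRIENT_COLS()
  expect_equal(as.numeric(o2[, cols]), 2 * as.numeric(o1[, cols]))
})

test_that("scoring is additive over item-disjoint partial records", {
  sch <- demo_schema()
  ref <- demo_reference()
  rec <- random_record(sch, seed = 11)
  half1 <- rec[1:26, ]
  half2 <- rec[27:53, ]
  cols <- ffqscore:::.INTAKE_NUTRIENT_COLS()
  full <- score_response(sch, ref, rec)
  s1 <- suppressWarnings(score_response(sch, ref, half1))
  s2 <- suppressWarnings(score_response(sch, ref, half2))
  expect_equal(as.numeric(full[, cols]),
               as.numeric(s1[, cols]) + as.numeric(s2[, cols]))
})

test_that("cohort scoring matches an independent per-record loop", {
  sch <- demo_schema()
  ref <- demo_reference()
  cfg <- generator_config(n_subjects = 12, timepoints = c("BL1", "BL2"),
                          recall_windows = 7, seed = 5)
  sim <- generate_cohort(diet_profile(), cfg, sch, ref)
  intake <- score_cohort(sch, ref, sim$responses)
  cols <- ffqscore:::.INTAKE_NUTRIENT_COLS()
  # oracle: score each record independently through score_response
  keys <- dplyr::distinct(sim$responses[, c("respondent_id", "timepoint",
                                            "recall_window_days")])
  for (i in seq_len(nrow(keys))) {
    rec <- dplyr::semi_join(sim$responses, keys[i, ],
                            by = names(keys))
    single <- score_response(sch, ref, rec[, c("item_id", "frequency_code",
                                               "amount_code", "type_code")])
    row <- dplyr::semi_join(intake, keys[i, ], by = names(keys))
    expect_equal(as.numeric(row[, cols]), as.numeric(single[, cols]))
  }
  # ground truth recorded by the generator agrees with the pipeline
  m <- dplyr::inner_join(intake, sim$truth,
                         by = c("respondent_id", "timepoint",
                                "recall_window_days"),
                         suffix = c("", ".t"))
  expect_equal(m$energy_kcal_d, m$energy_kcal_d.t, tolerance = 1e-12)
  expect_equal(m$fiber_g_d, m$fiber_g_d.t, tolerance = 1e-12)
})

test_that("cohort scoring is permutation-invariant and keys are unique", {
  sch <- demo_schema()
  ref <- demo_reference()
  cfg <- generator_config(n_subjects = 8, timepoints = c("BL1", "BL2"),
                          recall_windows = 7, seed = 9)
  sim <- generate_cohort(diet_profile(), cfg, sch, ref)
  set.seed(1)
  shuffled <- sim$responses[sample(nrow(sim$responses)), ]
  a <- score_cohort(sch, ref, sim$responses)
  b <- score_cohort(sch, ref, shuffled)
  expect_equal(as.data.frame(a), as.data.frame(b))
  key <- paste(a$respondent_id, a$timepoint, a$recall_window_days)
  expect_false(anyDuplicated(key) > 0)

  dup <- dplyr::bind_rows(sim$responses, sim$responses[1, ])
  expect_error(score_cohort(sch, ref, dup), regexp = "duplicate",
               class = "ffqscore_validation_error")
})

test_that("empty response set yields an empty table with the full header", {
  sch <- demo_schema()
  ref <- demo_reference()
  out <- score_cohort(sch, ref, tibble::tibble(
    respondent_id = character(), timepoint = character(),
    recall_window_days = integer(), item_id = character(),
    frequency_code = character(), amount_code = character()
  ))
  expect_equal(nrow(out), 0)
  expect_true(all(ffqscore:::.INTAKE_NUTRIENT_COLS() %in% names(out)))
})

test_that("demo reference keeps Atwater plausibility of scored energy", {
  # diagnostic-only sanity: 4*protein + 4*carb + 9*fat within an order of
  # magnitude of scored energy on the demo table
  sch <- demo_schema()
  ref <- demo_reference()
  rec <- random_record(sch, seed = 21)
  out <- score_response(sch, ref, rec)
  atwater <- 4 * out$protein_g_d + 4 * out$carbohydrates_g_d +
    9 * out$fat_g_d
  expect_gt(atwater / out$energy_kcal_d, 0.1)
  expect_lt(atwater / out$energy_kcal_d, 10)
})

test_that("macronutrient shares sum to one and match direct arithmetic", {
  one <- tibble::tibble(carbohydrates_g_d = 200, fat_g_d = 60,
                        protein_g_d = 70, fiber_g_d = 20)
  sh <- macronutrient_shares(one)
  got <- setNames(sh$share, sh$nutrient)
  expect_equal(unname(got["carbohydrates"]), 200 / 350)
  expect_equal(unname(got["fat"]), 60 / 350)
  expect_equal(unname(got["protein"]), 70 / 350)
  expect_equal(unname(got["fiber"]), 20 / 350)

  single <- tibble::tibble(carbohydrates_g_d = 0, fat_g_d = 5,
                           protein_g_d = 0, fiber_g_d = 0)
  s2 <- macronutrient_shares(single)
  expect_equal(setNames(s2$share, s2$nutrient)[["fat"]], 1)

  set.seed(4)
  rnd <- tibble::tibble(carbohydrates_g_d = runif(50, 1, 300),
                        fat_g_d = runif(50, 1, 120),
                        protein_g_d = runif(50, 1, 150),
                        fiber_g_d = runif(50, 0, 40))
  sums <- tapply(macronutrient_shares(rnd)$share,
                 rep(seq_len(50), each = 4), sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  expect_error(macronutrient_shares(tibble::tibble(
    carbohydrates_g_d = 0, fat_g_d = 0, protein_g_d = 0, fiber_g_d = 0
  )), class = "ffqscore_validation_error")
})
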