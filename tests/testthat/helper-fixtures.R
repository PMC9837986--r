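# Fixtures built in code: a 2-item mini schema with hand-set nutrient
# values (for exact-arithmetic oracles) and a cached copy of the shipped
# schema + seeded demo reference table (for realistic-scale tests).

tiny_schema <- function() {
  ffq_schema(
    schema_id = "tiny", recall_window_days = 7,
    items = tibble::tibble(
      item_id = c("1", "2"),
      name = c("oats", "coffee"),
      food_group = c("bread_cereals", "beverages"),
      frequency_map = "freq", portion_map = "por",
      type_question = c(NA, "tq_sugar")
    ),
    frequency_maps = list(freq = tibble::tibble(
      code = c("never", "3x_week", "daily", "twice_daily"),
      label = code,
      occurrences = c(0, 3, 1, 2),
      period_days = c(7, 7, 1, 1)
    )),
    portion_maps = list(por = tibble::tibble(
      code = c("small", "large"), label = code, grams = c(100, 200)
    )),
    type_questions = list(tq_sugar = list(
      question_id = "tq_sugar", item_ids = "2",
      options = tibble::tibble(code = c("no", "yes"),
                               variant = c("without_sugar", "with_sugar")),
      default_variant = "without_sugar"
    ))
  )
}

# Hand-set per-100 g values; energy kcal, others mg.
tiny_reference <- function(schema = tiny_schema()) {
  base <- tibble::tibble(
    cellulose_mg_100g = 0, lignin_mg_100g = 0, fiber_soluble_mg_100g = 0,
    fiber_insoluble_mg_100g = 0, tyrosine_mg_100g = 100,
    tryptophan_mg_100g = 50, sat_fa_mg_100g = 500,
    short_chain_fa_mg_100g = 10, medium_chain_fa_mg_100g = 20,
    long_chain_fa_mg_100g = 400, omega3_mg_100g = 30, omega6_mg_100g = 60
  )
  entries <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(
      item_id = "1", variant_key = "default", source = "fixture",
      energy_kcal_100g = 100, protein_mg_100g = 10000, fat_mg_100g = 2000,
      carbohydrates_mg_100g = 60000, fiber_mg_100g = 2500,
      sugar_mg_100g = 1000
    ), base),
    dplyr::bind_cols(tibble::tibble(
      item_id = "2", variant_key = "without_sugar", source = "fixture",
      energy_kcal_100g = 2, protein_mg_100g = 200, fat_mg_100g = 0,
      carbohydrates_mg_100g = 300, fiber_mg_100g = 0, sugar_mg_100g = 0
    ), base),
    dplyr::bind_cols(tibble::tibble(
      item_id = "2", variant_key = "with_sugar", source = "fixture",
      energy_kcal_100g = 22, protein_mg_100g = 200, fat_mg_100g = 0,
      carbohydrates_mg_100g = 5300, fiber_mg_100g = 0, sugar_mg_100g = 5000
    ), base),
    dplyr::bind_cols(tibble::tibble(
      item_id = "2", variant_key = "default", source = "fixture",
      energy_kcal_100g = 2, protein_mg_100g = 200, fat_mg_100g = 0,
      carbohydrates_mg_100g = 300, fiber_mg_100g = 0, sugar_mg_100g = 0
    ), base)
  )
  ffq_reference(entries, provenance = "tiny fixture", schema = schema)
}

# Cache the shipped schema and a seeded demo reference between tests.
.fixture_env <- new.env(parent = emptyenv())

demo_schema <- function() {
  if (is.null(.fixture_env$schema)) .fixture_env$schema <- degs1_schema()
  .fixture_env$schema
}

demo_reference <- function() {
  if (is.null(.fixture_env$reference)) {
    .fixture_env$reference <- generate_reference_table(demo_schema(), seed = 1)
  }
  .fixture_env$reference
}

# A fully answered record on the shipped schema (deterministic given seed).
random_record <- function(schema = demo_schema(), seed = 1) {
  set.seed(seed)
  fl <- ffqscore:::schema_freq_lookup(schema)
  pl <- ffqscore:::schema_portion_lookup(schema)
  items <- schema$items
  ans <- tibble::tibble(
    item_id = items$item_id,
    frequency_code = vapply(items$frequency_map, function(m) {
      sample(fl$code[fl$frequency_map == m], 1)
    }, character(1)),
    amount_code = vapply(items$portion_map, function(m) {
      sample(pl$code[pl$portion_map == m], 1)
    }, character(1)),
    type_code = vapply(seq_len(nrow(items)), function(i) {
      tq <- items$type_question[i]
      if (is.na(tq)) NA_character_ else {
        sample(schema$type_questions[[tq]]$options$code, 1)
      }
    }, character(1))
  )
  ans
}

# Table 6-style diet-by-DFS-group cohort expanded from printed counts.
dfs_diet_cohort <- function() {
  tibble::tibble(
    dfs_group = rep(c("HFS", "HFS", "LFS", "LFS"), c(32, 3, 27, 14)),
    diet = rep(c("OMN", "VEG", "OMN", "VEG"), c(32, 3, 27, 14))
  )
}
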