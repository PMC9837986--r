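# Synthetic cohorts and a demo reference table with known ground truth.
#
# Latent daily intakes are log-normal (non-negative, right-skewed, matching
# the skew typical of self-reported diet data). Each subject carries a
# habitual item-weight profile; per-timepoint latents share a common factor
# so any two timepoints correlate at the configured test-retest rho, and
# short recall windows receive extra log-scale noise. Latent grams per item
# are quantised to the nearest schema answer category; the induced bias is
# reported, never hidden.

# Per-food-group composition priors (g/100 g ranges) for the demo table.
.GROUP_COMPOSITION <- tibble::tribble(
  ~food_group,      ~pro_lo, ~pro_hi, ~fat_lo, ~fat_hi, ~carb_lo, ~carb_hi, ~fib_lo, ~fib_hi, ~sug_lo, ~sug_hi,
  "bread_cereals",      8,      13,     1.5,      6,      45,       70,       3,       7,     0.05,    0.30,
  "vegetables",       1.5,       4,     0.2,      1,       4,       12,       2,       4,     0.30,    0.60,
  "fruit",            0.5,     1.5,     0.2,    0.8,      10,       20,     1.5,       3,     0.70,    0.95,
  "dairy",            3.4,      25,     1.5,     30,       3,        6,       0,       0,     0.70,    1.00,
  "meat_fish",         18,      26,       2,     20,     0.2,      1.5,       0,       0,     0.30,    0.80,
  "fats_oils",        0.2,       2,      30,     85,     0.5,        3,       0,     0.5,     0.20,    0.50,
  "sweets_snacks",      4,       8,      15,     32,      50,       68,       1,       3,     0.40,    0.80,
  "beverages",          0,     0.5,       0,    0.3,       3,       12,       0,     0.5,     0.80,    1.00,
  "misc",               5,      12,       5,     15,      10,       25,       1,       4,     0.20,    0.50
)

# Food-group energy shares of the habitual diet (sum to 1).
.GROUP_ENERGY_SHARES <- c(
  bread_cereals = 0.29, vegetables = 0.07, fruit = 0.08, dairy = 0.13,
  meat_fish = 0.11, fats_oils = 0.05, sweets_snacks = 0.13,
  beverages = 0.10, misc = 0.04
)

#' Diet profile for the synthetic generator
#'
#' Defines the latent dietary conditions a synthetic cohort emulates:
#' mean and SD of daily energy, the target macronutrient mass shares, the
#' sugar fraction of carbohydrate, a male energy offset, the diet group
#' (vegetarians drop animal items and up-weight fiber-rich plant groups),
#' and the high/low fat-and-sugar (HFS/LFS) group with its energy offset
#' (added for HFS, subtracted for LFS).
#'
#' Defaults correspond to an adult mixed-diet cohort: 2000 kcal/d mean
#' (SD 450), mass shares 58.5% carbohydrate / 16.5% fat / 19% protein /
#' 6% fiber, sugar at 45% of carbohydrate, and +300 kcal/d for males.
#'
#' @param target_energy_mean,target_energy_sd Latent daily energy, kcal/d.
#' @param macro_shares Named shares of (carbohydrates, fat, protein, fiber)
#'   daily mass; must sum to 1.
#' @param sugar_fraction_of_carb Target sugar share of carbohydrate mass.
#' @param sex_energy_offset kcal/d added to the mean for males.
#' @param diet `"OMN"`, `"VEG"` or `NA`.
#' @param veg_fiber_multiplier Weight multiplier for fiber-rich food groups
#'   under a vegetarian profile.
#' @param dfs_group `"HFS"`, `"LFS"` or `NA`.
#' @param dfs_energy_offset kcal/d added (HFS) or subtracted (LFS).
#' @return A list of class `ffq_diet_profile`.
#' @export
diet_profile <- function(target_energy_mean = 2000, target_energy_sd = 450,
                         macro_shares = c(carbohydrates = 0.585, fat = 0.165,
                                          protein = 0.19, fiber = 0.06),
                         sugar_fraction_of_carb = 0.45,
                         sex_energy_offset = 300,
                         diet = "OMN", veg_fiber_multiplier = 1.3,
                         dfs_group = NA, dfs_energy_offset = 415) {
  if (abs(sum(macro_shares) - 1) > 1e-9) {
    stop_validation("macro_shares must sum to 1")
  }
  if (target_energy_sd < 0) stop_validation("target_energy_sd must be >= 0")
  if (sugar_fraction_of_carb < 0 || sugar_fraction_of_carb > 1) {
    stop_validation("sugar_fraction_of_carb must be in [0, 1]")
  }
  structure(
    list(
      target_energy_mean = target_energy_mean,
      target_energy_sd = target_energy_sd,
      macro_shares = macro_shares,
      sugar_fraction_of_carb = sugar_fraction_of_carb,
      sex_energy_offset = sex_energy_offset,
      diet = diet, veg_fiber_multiplier = veg_fiber_multiplier,
      dfs_group = dfs_group, dfs_energy_offset = dfs_energy_offset
    ),
    class = "ffq_diet_profile"
  )
}

#' Generator configuration
#'
#' @param n_subjects Number of subjects.
#' @param timepoints Timepoint labels (e.g. `c("BL1", "BL2")`).
#' @param recall_windows Recall windows to emit, subset of 1/7/14/28 days.
#' @param retest_rho Target test-retest correlation of the latent intake
#'   between any two timepoints, in \[0, 1\].
#' @param window_noise_sd Named extra log-scale noise SD per window; the
#'   default adds noise only to 24 h reports (single days vary more than
#'   weekly habits), leaving longer windows at the bare retest_rho.
#' @param window_energy_offset Named kcal/d mean offset per window; the
#'   default reports 24 h intake 300 kcal/d higher.
#' @param missing_rate Per-answer missingness probability in \[0, 1\].
#' @param seed Integer; fixes all randomness of the generating call.
#' @return A list of class `ffq_generator_config`.
#' @export
generator_config <- function(n_subjects, timepoints = c("BL1", "BL2"),
                             recall_windows = 7,
                             retest_rho = 0.6,
                             window_noise_sd = c("1" = 0.8, "7" = 0,
                                                 "14" = 0, "28" = 0),
                             window_energy_offset = c("1" = 300, "7" = 0,
                                                      "14" = 0, "28" = 0),
                             missing_rate = 0, seed = 1) {
  if (retest_rho < 0 || retest_rho > 1) {
    stop_validation("retest_rho must be in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop_validation("missing_rate must be in [0, 1]")
  }
  if (!all(recall_windows %in% .VALID_WINDOWS)) {
    stop_validation("recall_windows must be a subset of {1, 7, 14, 28}")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), timepoints = timepoints,
         recall_windows = as.integer(recall_windows),
         retest_rho = retest_rho,
         window_noise_sd = window_noise_sd,
         window_energy_offset = window_energy_offset,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "ffq_generator_config"
  )
}

#' Generate a demo per-100 g reference table
#'
#' Draws plausible nutrient vectors per item from food-group composition
#' priors, with energy tied to the macronutrients by Atwater factors
#' (4 kcal/g protein and carbohydrate, 9 kcal/g fat, 2 kcal/g fiber, small
#' multiplicative noise), fiber subclasses and sugar within their parents,
#' amino acids as fixed fractions of protein and fatty-acid classes of fat.
#' Items covered by a type question get one entry per variant with strictly
#' increasing energy in the schema's option order (fat and sugar scaled up
#' per step), plus a `"default"` entry equal to the default variant.
#'
#' The table is synthetic demo data standing in for a licensed food
#' composition database; values are plausible, not measured.
#'
#' @param schema An [ffq_schema()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A validated `ffq_reference` covering the schema.
#' @export
generate_reference_table <- function(schema, seed = 1) {
  set.seed(seed)
  items <- schema$items
  comp <- .GROUP_COMPOSITION
  miss_groups <- setdiff(unique(items$food_group), comp$food_group)
  if (length(miss_groups) > 0) {
    stop_validation(sprintf("no composition prior for food group(s): %s",
                            paste(miss_groups, collapse = ", ")))
  }
  gi <- match(items$food_group, comp$food_group)
  ru <- function(lo, hi) runif(nrow(items), lo, hi)
  protein <- ru(comp$pro_lo[gi], comp$pro_hi[gi])
  fat <- ru(comp$fat_lo[gi], comp$fat_hi[gi])
  carb <- ru(comp$carb_lo[gi], comp$carb_hi[gi])
  fiber <- ru(comp$fib_lo[gi], comp$fib_hi[gi])
  sugar <- carb * ru(comp$sug_lo[gi], comp$sug_hi[gi])
  atwater_noise <- runif(nrow(items), 0.97, 1.03)

  build_vec <- function(protein, fat, carb, fiber, sugar, noise) {
    energy <- (4 * (protein + carb) + 9 * fat + 2 * fiber) * noise
    tibble::tibble(
      energy_kcal_100g = energy,
      protein_mg_100g = protein * 1000,
      fat_mg_100g = fat * 1000,
      carbohydrates_mg_100g = carb * 1000,
      fiber_mg_100g = fiber * 1000,
      sugar_mg_100g = sugar * 1000,
      cellulose_mg_100g = fiber * 1000 * 0.30,
      lignin_mg_100g = fiber * 1000 * 0.05,
      fiber_soluble_mg_100g = fiber * 1000 * 0.30,
      fiber_insoluble_mg_100g = fiber * 1000 * 0.65,
      tyrosine_mg_100g = protein * 1000 * 0.035,
      tryptophan_mg_100g = protein * 1000 * 0.012,
      sat_fa_mg_100g = fat * 1000 * 0.40,
      short_chain_fa_mg_100g = fat * 1000 * 0.03,
      medium_chain_fa_mg_100g = fat * 1000 * 0.07,
      long_chain_fa_mg_100g = fat * 1000 * 0.80,
      omega3_mg_100g = fat * 1000 * 0.02,
      omega6_mg_100g = fat * 1000 * 0.12
    )
  }

  entries <- list()
  for (i in seq_len(nrow(items))) {
    id <- items$item_id[i]
    tq_id <- items$type_question[i]
    if (is.na(tq_id)) {
      row <- build_vec(protein[i], fat[i], carb[i], fiber[i], sugar[i],
                       atwater_noise[i])
      entries[[length(entries) + 1]] <- dplyr::bind_cols(
        tibble::tibble(item_id = id, variant_key = "default",
                       source = "synthetic demo"), row
      )
    } else {
      tq <- schema$type_questions[[tq_id]]
      variants <- unique(tq$options$variant)
      rows <- lapply(seq_along(variants), function(j) {
        # each step up the option order scales fat and sugar by 35%,
        # guaranteeing strictly increasing energy (fried > cooked,
        # with sugar > without)
        m <- 1 + 0.35 * (j - 1)
        sug_j <- sugar[i] * m
        carb_j <- carb[i] + (sug_j - sugar[i])
        dplyr::bind_cols(
          tibble::tibble(item_id = id, variant_key = variants[j],
                         source = "synthetic demo"),
          build_vec(protein[i], fat[i] * m, carb_j, fiber[i], sug_j,
                    atwater_noise[i])
        )
      })
      dflt <- rows[[match(tq$default_variant, variants)]]
      dflt$variant_key <- "default"
      entries <- c(entries, rows, list(dflt))
    }
  }
  ffq_reference(dplyr::bind_rows(entries),
                provenance = sprintf("synthetic demo table (seed %d)", seed),
                schema = schema)
}

# ---------------------------------------------------------------------------
# Cohort generation

# Per-item quantisation tables: sorted unique grams/day values of the
# frequency x portion category grid, with a representative answer pair each.
build_quant_tables <- function(schema) {
  fl <- schema_freq_lookup(schema)
  pl <- schema_portion_lookup(schema)
  lapply(seq_len(nrow(schema$items)), function(i) {
    f <- fl[fl$frequency_map == schema$items$frequency_map[i], ]
    p <- pl[pl$portion_map == schema$items$portion_map[i], ]
    grid <- tidyr::expand_grid(
      tibble::tibble(frequency_code = f$code, occurrences = f$occurrences,
                     period_days = f$period_days),
      tibble::tibble(amount_code = p$code, grams = p$grams)
    )
    # same operation order as mean_daily_portion() so scoring the emitted
    # answers reproduces these grams/day bit-for-bit
    grid$gpd <- grid$grams * grid$occurrences / grid$period_days
    grid <- grid[order(grid$gpd), ]
    grid <- grid[!duplicated(grid$gpd), ]
    # daily frequency code for free-gram (unquantised) emission
    daily <- f$code[abs(f$occurrences / f$period_days - 1) < 1e-9]
    list(grid = grid,
         daily_code = if (length(daily) > 0) daily[1] else NA_character_)
  })
}

nearest_gpd <- function(targets, grid) {
  cuts <- (grid$gpd[-1] + grid$gpd[-nrow(grid)]) / 2
  idx <- findInterval(targets, cuts) + 1L
  idx
}

# Energy density (kcal/100 g) lookup matrix for subject-specific variants.
ref_index_matrix <- function(reference, item_ids, variant_mat) {
  key <- paste(reference$item_id, reference$variant_key)
  idx <- matrix(
    match(paste(rep(item_ids, each = nrow(variant_mat)), variant_mat), key),
    nrow = nrow(variant_mat)
  )
  if (anyNA(idx)) stop_validation("reference table does not cover all generated variants")
  idx
}

totals_from_gpd_matrix <- function(reference, ridx, gpd) {
  scale <- gpd / 100
  cols <- .REF_NUTRIENT_COLS()
  out <- matrix(0, nrow(gpd), length(cols))
  for (ci in seq_along(cols)) {
    vals <- reference[[cols[ci]]][ridx]
    dim(vals) <- dim(gpd)
    out[, ci] <- rowSums(vals * scale)
  }
  colnames(out) <- c("energy_kcal_d", paste0(.NUTRIENTS, "_mg_d"))
  out <- tibble::as_tibble(out)
  for (nm in .GRAM_NUTRIENTS) {
    out[[paste0(nm, "_g_d")]] <- out[[paste0(nm, "_mg_d")]] / 1000
    out[[paste0(nm, "_mg_d")]] <- NULL
  }
  out[, .INTAKE_NUTRIENT_COLS()]
}

#' Generate a synthetic FFQ cohort with known ground truth
#'
#' Draws a latent true daily intake per subject from the profile, spreads
#' it over the schema's food items according to a habitual per-subject
#' weight profile (vegetarian profiles drop animal items and up-weight
#' plant groups), inverts the grams/day targets into schema answer
#' categories by nearest-category quantisation, and emits schema-conformant
#' responses together with demographics and the ground-truth intake.
#'
#' @param profile A [diet_profile()].
#' @param config A [generator_config()].
#' @param schema An [ffq_schema()].
#' @param reference An `ffq_reference` covering the schema.
#' @param quantize If `FALSE`, answers are emitted as free grams at daily
#'   frequency (no quantisation noise; scoring recovers the latent intake
#'   exactly).
#' @return A list of class `ffq_sim`: `responses` (long response tibble
#'   with demographics), `truth` (per respondent x timepoint x window:
#'   `latent_energy_kcal` and the quantised ground-truth intake columns),
#'   `subjects`, `achieved_shares` (mean macronutrient mass shares and
#'   sugar/carb fraction actually realised), `quantization_bias_pct`
#'   (mean percent energy error induced by category quantisation),
#'   `profile`, `config`.
#' @export
generate_cohort <- function(profile, config, schema, reference,
                            quantize = TRUE) {
  set.seed(config$seed)
  n <- config$n_subjects
  items <- schema$items
  J <- nrow(items)

  # --- subjects and demographics
  sex <- sample(c("F", "M"), n, replace = TRUE)
  u <- rnorm(n)  # shared body-composition latent
  subjects <- tibble::tibble(
    respondent_id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    age = round(pmin(pmax(rnorm(n, 30, 8), 18), 65)),
    bmi = round(rnorm(n, 24, 3), 1),
    whr = round(pmin(pmax(rnorm(n, ifelse(sex == "M", 0.88, 0.78), 0.05),
                          0.5), 1.2), 2),
    body_fat = round(ifelse(sex == "M", 20, 30) + 4 * u + rnorm(n, 0, 3), 1),
    fat_free_mass = round(ifelse(sex == "M", 62, 45) - 3 * u + rnorm(n, 0, 3), 1),
    systolic_bp = round(rnorm(n, 120, 12)),
    diastolic_bp = round(rnorm(n, 78, 8)),
    met_minutes = round(pmax(rnorm(n, 2500, 1200), 0)),
    hba1c = round(32 + 1.5 * (!is.na(profile$dfs_group) &
                                profile$dfs_group == "HFS") + rnorm(n, 0, 2.8), 3),
    diet = profile$diet,
    dfs_group = profile$dfs_group
  )

  # --- habitual item weights (energy shares), stable across timepoints
  shares <- .GROUP_ENERGY_SHARES
  if (!is.na(profile$diet) && profile$diet == "VEG") {
    meat <- shares[["meat_fish"]]
    shares[["meat_fish"]] <- 0
    shares[["vegetables"]] <- shares[["vegetables"]] + 0.4 * meat
    shares[["fruit"]] <- shares[["fruit"]] + 0.25 * meat
    shares[["bread_cereals"]] <- shares[["bread_cereals"]] + 0.2 * meat
    shares[["dairy"]] <- shares[["dairy"]] + 0.15 * meat
    for (g in c("vegetables", "fruit", "bread_cereals")) {
      shares[[g]] <- shares[[g]] * profile$veg_fiber_multiplier
    }
    shares <- shares / sum(shares)
  }
  raw_w <- matrix(rgamma(n * J, shape = 2, rate = 1), n, J)
  grp <- items$food_group
  W <- matrix(0, n, J)
  for (g in unique(grp)) {
    cols_g <- which(grp == g)
    block <- raw_w[, cols_g, drop = FALSE]
    W[, cols_g] <- block / rowSums(block) * shares[[g]]
  }

  # --- stable type-question answers per subject
  variant_mat <- matrix("default", n, J)
  type_code_mat <- matrix(NA_character_, n, J)
  for (j in seq_len(J)) {
    tq_id <- items$type_question[j]
    if (!is.na(tq_id)) {
      tq <- schema$type_questions[[tq_id]]
      pick <- sample(nrow(tq$options), n, replace = TRUE)
      type_code_mat[, j] <- tq$options$code[pick]
      variant_mat[, j] <- tq$options$variant[pick]
    }
  }
  ridx <- ref_index_matrix(reference, items$item_id, variant_mat)
  dens <- reference$energy_kcal_100g[ridx]
  dim(dens) <- dim(ridx)

  # --- latent energy scale
  mu_i <- profile$target_energy_mean +
    profile$sex_energy_offset * (sex == "M") +
    ifelse(is.na(profile$dfs_group), 0,
           ifelse(profile$dfs_group == "HFS", profile$dfs_energy_offset,
                  -profile$dfs_energy_offset))
  cv <- profile$target_energy_sd / profile$target_energy_mean
  sigma_log <- sqrt(log(1 + cv^2))
  z_subject <- rnorm(n)
  rho <- config$retest_rho
  n_tp <- length(config$timepoints)
  eps <- matrix(rnorm(n * n_tp), n, n_tp)

  quant <- build_quant_tables(schema)
  state <- list(
    schema = schema, reference = reference, subjects = subjects,
    W = W, variant_mat = variant_mat, type_code_mat = type_code_mat,
    ridx = ridx, dens = dens, mu_i = mu_i, sigma_log = sigma_log,
    z_subject = z_subject, quant = quant, profile = profile,
    config = config, quantize = quantize
  )

  responses <- list()
  truth <- list()
  z_timepoints <- list()
  for (ti in seq_len(n_tp)) {
    z_t <- sqrt(rho) * z_subject + sqrt(1 - rho) * eps[, ti]
    z_timepoints[[config$timepoints[ti]]] <- z_t
    for (w in config$recall_windows) {
      em <- emit_window(state, config$timepoints[ti], w, z_t)
      responses[[length(responses) + 1]] <- em$responses
      truth[[length(truth) + 1]] <- em$truth
    }
  }
  state$z_timepoints <- z_timepoints
  responses <- dplyr::bind_rows(responses)
  truth <- dplyr::bind_rows(truth)

  # achieved macronutrient mass shares and quantisation bias
  mm <- as.matrix(truth[, c("carbohydrates_g_d", "fat_g_d", "protein_g_d",
                            "fiber_g_d")])
  ach <- colMeans(mm / rowSums(mm))
  names(ach) <- c("carbohydrates", "fat", "protein", "fiber")
  ach <- c(ach, sugar_fraction_of_carb =
             mean(truth$sugar_g_d / truth$carbohydrates_g_d))
  bias_pct <- mean((truth$energy_kcal_d - truth$latent_energy_kcal) /
                     truth$latent_energy_kcal) * 100
  target <- profile$macro_shares[c("carbohydrates", "fat", "protein", "fiber")]
  if (max(abs(ach[names(target)] - target)) > 0.08) {
    warn(sprintf(
      "profile macro shares not reachable under the schema/reference: achieved %s",
      paste(sprintf("%s %.3f", names(target), ach[names(target)]),
            collapse = ", ")
    ), class = "ffqscore_share_warning")
  }

  structure(
    list(responses = responses, truth = truth, subjects = subjects,
         achieved_shares = ach, quantization_bias_pct = bias_pct,
         profile = profile, config = config, state = state),
    class = "ffq_sim"
  )
}

# Emit one timepoint x window: responses + ground truth.
emit_window <- function(state, tp, w, z_t) {
  config <- state$config
  n <- nrow(state$subjects)
  J <- ncol(state$W)
  items <- state$schema$items
  sd_w <- unname(state$config$window_noise_sd[as.character(w)] %||% 0)
  off_w <- unname(state$config$window_energy_offset[as.character(w)] %||% 0)
  if (is.na(sd_w)) sd_w <- 0
  if (is.na(off_w)) off_w <- 0
  z <- z_t + sd_w * rnorm(n)
  mu <- state$mu_i + off_w
  energy <- exp(log(mu) - state$sigma_log^2 / 2 + state$sigma_log * z)

  target_g <- state$W * energy * 100 / state$dens  # grams/day per item

  freq <- matrix(NA_character_, n, J)
  amt <- matrix(NA_character_, n, J)
  gpd_q <- matrix(0, n, J)
  for (j in seq_len(J)) {
    q <- state$quant[[j]]
    if (state$quantize) {
      idx <- nearest_gpd(target_g[, j], q$grid)
      freq[, j] <- q$grid$frequency_code[idx]
      amt[, j] <- q$grid$amount_code[idx]
      gpd_q[, j] <- q$grid$gpd[idx]
    } else {
      freq[, j] <- q$daily_code
      amt[, j] <- formatC(target_g[, j], format = "f", digits = 4)
      gpd_q[, j] <- target_g[, j]
    }
  }

  totals <- totals_from_gpd_matrix(state$reference, state$ridx, gpd_q)
  keys <- tibble::tibble(
    respondent_id = state$subjects$respondent_id,
    timepoint = tp, recall_window_days = as.integer(w)
  )
  truth <- dplyr::bind_cols(keys,
                            tibble::tibble(latent_energy_kcal = energy),
                            totals)

  resp <- tibble::tibble(
    respondent_id = rep(state$subjects$respondent_id, times = J),
    timepoint = tp,
    recall_window_days = as.integer(w),
    item_id = rep(items$item_id, each = n),
    frequency_code = as.vector(freq),
    amount_code = as.vector(amt),
    type_code = as.vector(state$type_code_mat)
  )
  if (config$missing_rate > 0) {
    drop <- runif(nrow(resp)) < config$missing_rate
    resp$frequency_code[drop] <- NA_character_
    resp$amount_code[drop] <- NA_character_
  }
  demo <- dplyr::select(state$subjects, -"respondent_id")
  resp <- dplyr::bind_cols(resp, demo[rep(seq_len(n), times = J), ])
  list(responses = resp, truth = truth)
}

#' Generate correlated retest responses for an existing cohort
#'
#' Draws a second latent intake per subject correlated `retest_rho` with
#' the first administration's subject-level latent, and re-quantises it to
#' schema answers for every recall window of the original configuration.
#'
#' @param sim An `ffq_sim` from [generate_cohort()] (typically generated
#'   with a single timepoint).
#' @param retest_rho Target latent test-retest correlation in \[0, 1\].
#' @param seed Integer seed for the retest draw.
#' @param timepoint Label for the new timepoint, default `"RT"`.
#' @return An `ffq_sim`-like list with `responses` and `truth` for the new
#'   timepoint only.
#' @export
generate_retest <- function(sim, retest_rho, seed, timepoint = "RT") {
  if (retest_rho < 0 || retest_rho > 1) {
    stop_validation("retest_rho must be in [0, 1]")
  }
  set.seed(seed)
  state <- sim$state
  n <- nrow(state$subjects)
  # correlate with the first administration's emitted latent
  z1 <- state$z_timepoints[[1]] %||% state$z_subject
  z2 <- retest_rho * z1 + sqrt(1 - retest_rho^2) * rnorm(n)
  responses <- list()
  truth <- list()
  for (w in state$config$recall_windows) {
    em <- emit_window(state, timepoint, w, z2)
    responses[[length(responses) + 1]] <- em$responses
    truth[[length(truth) + 1]] <- em$truth
  }
  structure(
    list(responses = dplyr::bind_rows(responses),
         truth = dplyr::bind_rows(truth),
         subjects = state$subjects,
         profile = sim$profile, config = sim$config, state = state),
    class = "ffq_sim"
  )
}

#' @export
print.ffq_sim <- function(x, ...) {
  cat(sprintf(
    "<ffq_sim> %d subjects, %d response rows, %d truth rows\n",
    nrow(x$subjects), nrow(x$responses), nrow(x$truth)
  ))
  if (!is.null(x$achieved_shares)) {
    cat("achieved mass shares:",
        paste(sprintf("%s %.3f", names(x$achieved_shares),
                      x$achieved_shares), collapse = ", "), "\n")
  }
  invisible(x)
}
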