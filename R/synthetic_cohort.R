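# Synthetic study inputs: a fixture food-composition table, a cohort
# generator with a latent diet-quality factor and configurable biomarker
# effect structure, full-adherence profiles for the six indices, and the
# participant-flow ledger. Everything here is synthetic by construction;
# no real questionnaire wording or database contents are reproduced.

#' Synthetic fixture food-composition table
#'
#' A compact (~40 item) composition table covering every food-group tag the
#' scorers use, with plausible serving sizes and per-100 g nutrient
#' densities. Includes generic base items ("milk", "cooking_fat") and the
#' variant items that the open-section qualifiers substitute.
#'
#' @return A `food_comp_table` with provenance `"synthetic_fixture"`.
#' @export
build_demo_composition_table <- function() {
  it <- function(id, name, tags, serve, energy, fat = 0, sat = 0, mufa = 0,
                 pufa = 0, carb = 0, sugar = 0, prot = 0, alc = 0,
                 na = 0, k = 0, p = 0) {
    data.frame(item_id = id, name = name, tags = tags, serving_size_g = serve,
               energy_kj_100g = energy, fat_g_100g = fat, sat_fat_g_100g = sat,
               mufa_g_100g = mufa, pufa_g_100g = pufa, carb_g_100g = carb,
               added_sugar_g_100g = sugar, protein_g_100g = prot,
               alcohol_g_100g = alc, sodium_mg_100g = na,
               potassium_mg_100g = k, phosphorus_mg_100g = p,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    it("apple", "Apple", "fruit", 150, 220, carb = 12, k = 110),
    it("banana", "Banana", "fruit", 120, 370, carb = 20, k = 350),
    it("orange", "Orange", "fruit", 130, 190, carb = 9, k = 180),
    it("berries", "Mixed berries", "fruit", 150, 180, carb = 8, k = 150),
    it("orange_juice", "Orange juice", "fruit;fruit_juice", 250, 170,
       carb = 9, sugar = 2, k = 160),
    it("broccoli", "Broccoli", "vegetable", 75, 140, carb = 2, prot = 3, k = 300),
    it("carrot", "Carrot", "vegetable", 75, 150, carb = 6, k = 280),
    it("spinach", "Spinach", "vegetable", 75, 100, carb = 1, prot = 3, k = 470),
    it("tomato", "Tomato", "vegetable", 75, 80, carb = 3, k = 240),
    it("capsicum", "Capsicum", "vegetable", 75, 110, carb = 4, k = 210),
    it("potato", "Potato (boiled)", "vegetable", 150, 320, carb = 17, k = 380),
    it("lentils", "Lentils (cooked)", "legume", 75, 420, carb = 13, prot = 8, k = 280),
    it("chickpeas", "Chickpeas (cooked)", "legume", 75, 550, fat = 2.5,
       carb = 17, prot = 8, k = 290),
    it("tofu", "Tofu", "legume;soy", 100, 480, fat = 7, sat = 1, prot = 12, k = 120),
    it("almonds", "Almonds", "nut_seed", 30, 2500, fat = 53, sat = 4,
       mufa = 33, pufa = 13, prot = 21, k = 730, p = 480),
    it("walnuts", "Walnuts", "nut_seed", 30, 2900, fat = 65, sat = 6,
       mufa = 9, pufa = 47, prot = 15, k = 440, p = 350),
    it("milk", "Milk (unspecified)", "dairy", 250, 270, fat = 3.5, sat = 2.3,
       carb = 5, prot = 3.4, na = 45, k = 150, p = 95),
    it("milk_full_cream", "Milk, full cream", "dairy", 250, 270, fat = 3.5,
       sat = 2.3, carb = 5, prot = 3.4, na = 45, k = 150, p = 95),
    it("milk_reduced_fat", "Milk, reduced fat", "dairy;dairy_lowfat", 250, 200,
       fat = 1.4, sat = 0.9, carb = 5, prot = 3.6, na = 45, k = 160, p = 100),
    it("milk_skim", "Milk, skim", "dairy;dairy_lowfat", 250, 150, fat = 0.1,
       carb = 5, prot = 3.7, na = 45, k = 170, p = 105),
    it("yoghurt_lowfat", "Yoghurt, low fat", "dairy;dairy_lowfat", 200, 250,
       fat = 0.2, carb = 7, sugar = 3, prot = 5.5, na = 60, k = 220, p = 140),
    it("cheese", "Cheddar cheese", "dairy;discretionary", 40, 1700, fat = 34,
       sat = 22, mufa = 9, carb = 0.2, prot = 25, na = 650, k = 90, p = 510),
    it("beef", "Beef steak", "red_meat", 100, 900, fat = 10, sat = 4, mufa = 4,
       prot = 28, na = 55, k = 350, p = 210),
    it("lamb", "Lamb chop", "red_meat", 100, 1100, fat = 17, sat = 8, mufa = 7,
       prot = 24, na = 70, k = 310, p = 190),
    it("bacon", "Bacon", "processed_meat;discretionary", 50, 1100, fat = 19,
       sat = 7, mufa = 9, prot = 22, na = 1500, k = 250, p = 220),
    it("sausage", "Sausage", "processed_meat;discretionary", 70, 1250, fat = 24,
       sat = 10, mufa = 11, carb = 4, prot = 14, na = 800, k = 200, p = 150),
    it("chicken", "Chicken breast", "poultry", 100, 700, fat = 3.5, sat = 1,
       mufa = 1.3, prot = 31, na = 60, k = 330, p = 220),
    it("salmon", "Salmon", "fish", 100, 1000, fat = 13, sat = 3, mufa = 4,
       pufa = 4.5, prot = 24, na = 60, k = 380, p = 250),
    it("white_fish", "White fish", "fish", 100, 420, fat = 1.5, prot = 22,
       na = 75, k = 330, p = 200),
    it("egg", "Egg", "egg", 55, 550, fat = 9.5, sat = 3, mufa = 4, prot = 13,
       na = 135, k = 130, p = 190),
    it("oats", "Rolled oats", "wholegrain;high_fibre_grain", 40, 1600, fat = 8,
       sat = 1.5, carb = 56, prot = 13, k = 360, p = 400),
    it("wholemeal_bread", "Wholemeal bread", "wholegrain;high_fibre_grain", 40,
       1000, fat = 3, sat = 0.6, carb = 39, prot = 10, na = 400, k = 220, p = 180),
    it("brown_rice", "Brown rice (cooked)", "wholegrain", 150, 600, fat = 1,
       carb = 30, prot = 3, k = 80, p = 100),
    it("white_bread", "White bread", "refined_grain;white_bread", 40, 1050,
       fat = 2.5, sat = 0.5, carb = 45, sugar = 2, prot = 9, na = 450, k = 120, p = 100),
    it("white_rice", "White rice (cooked)", "refined_grain", 150, 550,
       carb = 29, prot = 2.5, k = 35, p = 40),
    it("chocolate", "Chocolate", "sweets;discretionary", 30, 2200, fat = 30,
       sat = 18, mufa = 9, carb = 57, sugar = 50, prot = 7, na = 80, k = 400, p = 210),
    it("cake", "Cake", "sweets;discretionary", 60, 1600, fat = 17, sat = 7,
       mufa = 6, carb = 55, sugar = 30, prot = 5, na = 350, k = 110, p = 120),
    it("biscuits", "Sweet biscuits", "sweets;discretionary", 25, 2000,
       fat = 22, sat = 11, mufa = 7, carb = 65, sugar = 28, prot = 6,
       na = 400, k = 140, p = 110),
    it("ssb_cola", "Sugar-sweetened soft drink", "ssb;discretionary", 375, 180,
       carb = 11, sugar = 11, na = 10),
    it("cooking_fat", "Cooking fat (unspecified)", "oil_other", 10, 3400,
       fat = 92, sat = 15, mufa = 40, pufa = 30),
    it("oil_olive_cooking", "Olive oil", "oil_olive", 10, 3700, fat = 100,
       sat = 14, mufa = 73, pufa = 8),
    it("oil_vegetable", "Vegetable oil", "oil_other", 10, 3700, fat = 100,
       sat = 12, mufa = 30, pufa = 53),
    it("butter_cooking", "Butter", "butter;discretionary", 10, 3000, fat = 81,
       sat = 52, mufa = 21, na = 520),
    it("wine", "Wine", "wine;alcohol", 150, 290, carb = 2, alc = 10, k = 90),
    it("beer", "Beer", "alcohol;discretionary", 375, 160, carb = 3, alc = 3.6, k = 35),
    it("water", "Water", "water_beverage", 250, 0)
  )
  food_composition(rows, provenance = "synthetic_fixture")
}

# healthiness direction of each fixture item for the latent-factor link
item_health_weight <- function(table) {
  tag_list <- attr(table, "tag_list")
  healthy <- c("fruit", "vegetable", "legume", "soy", "nut_seed", "wholegrain",
               "high_fibre_grain", "fish", "dairy_lowfat", "oil_olive",
               "water_beverage")
  unhealthy <- c("sweets", "discretionary", "processed_meat", "red_meat",
                 "ssb", "butter", "refined_grain", "white_bread")
  vapply(tag_list, function(tg) {
    if (any(tg %in% healthy)) 1 else if (any(tg %in% unhealthy)) -1 else 0
  }, numeric(1))
}

#' Synthetic-cohort configuration
#'
#' Defaults emulate the study's structure: 100 participants, 69% female, 68%
#' at high CVD risk, 46%/54% recruited in 2021/2022; a standardised latent
#' diet-quality effect of -0.35 on log-hsCRP and 0 on log-PAF and Lp-PLA2;
#' right-skewed (log-normal) hsCRP and PAF and Gaussian Lp-PLA2 with a male
#' location shift, with location/spread loosely matching the reported
#' medians/IQRs (approximations, not fitted values). The year-on-PAF shift
#' is off by default and switchable to exercise year-stratified analyses.
#'
#' @param n Number of participants (>= 10).
#' @param prop_female,prop_high_risk,prop_2022 Cohort mix proportions.
#' @param effect_crp,effect_paf,effect_lppla2 Standardised diet-quality
#'   effects on log-hsCRP, log-PAF and Lp-PLA2.
#' @param gender_lppla2_shift Male minus female Lp-PLA2 difference
#'   (nmol/min/mL).
#' @param year_paf_shift 2022 minus 2021 shift on log-PAF in SD units.
#' @param hscrp_meanlog,hscrp_sdlog,paf_meanlog,paf_sdlog Log-normal
#'   biomarker parameters.
#' @param lppla2_mean,lppla2_sd Gaussian Lp-PLA2 parameters.
#' @param latent_gain,latent_noise FFQ link: category shift per latent SD and
#'   response noise SD.
#' @param seed Seed (all generation randomness flows from it).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 100, prop_female = 0.69, prop_high_risk = 0.68,
                          prop_2022 = 0.54, effect_crp = -0.35,
                          effect_paf = 0, effect_lppla2 = 0,
                          gender_lppla2_shift = 3, year_paf_shift = 0,
                          hscrp_meanlog = log(0.96), hscrp_sdlog = 1.1,
                          paf_meanlog = log(7.96), paf_sdlog = 1.0,
                          lppla2_mean = 14.9, lppla2_sd = 4.3,
                          latent_gain = 1.6, latent_noise = 1.2,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (!is.numeric(n) || n < 10) stop_domain("n must be >= 10")
  for (p in c("prop_female", "prop_high_risk", "prop_2022"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop_domain("'", p, "' must lie in [0, 1]")
  for (s in c("hscrp_sdlog", "paf_sdlog", "lppla2_sd", "latent_noise"))
    if (cfg[[s]] <= 0) stop_domain("'", s, "' must be > 0")
  for (e in c("effect_crp", "effect_paf", "effect_lppla2"))
    if (abs(cfg[[e]]) >= 1)
      stop_domain("standardised effects must lie in (-1, 1)")
  structure(cfg, class = "cohort_config")
}

#' Generate a complete synthetic cohort
#'
#' Draws a latent diet-quality factor per participant, induces FFQ frequency
#' responses through an ordered-threshold link (healthier items more frequent
#' at higher latent quality, unfavourable items less frequent), generates
#' demographics, GPAQ activity, triplicate blood pressure, a 3-day beverage
#' diary and screener habit answers, computes the DASH composite through the
#' package's own scoring pipeline, and finally draws biomarkers with the
#' configured linear structure on the standardised composite (so the
#' configured effect is the estimand of the downstream standardised
#' regression).
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, writes `ffq.csv`,
#'   `open_section.csv`, `covariates.csv` and `food_composition.csv`.
#' @return List: `ffq`, `open_section`, `covariates`, `table`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- as.integer(config$n)
  table <- build_demo_composition_table()
  ids <- sprintf("P%03d", seq_len(n))
  z <- stats::rnorm(n)

  # --- FFQ responses: ordered-threshold link on the latent factor ----------
  w <- item_health_weight(table)
  # per-item habitual baseline category (1..9); staples more frequent
  base <- ifelse(w > 0, 5, ifelse(w < 0, 4, 4)) +
    stats::rnorm(nrow(table), 0, 0.5)
  ffq_items <- setdiff(table$item_id,
                       c("milk_full_cream", "milk_reduced_fat", "milk_skim",
                         "oil_olive_cooking", "oil_vegetable", "butter_cooking"))
  keep <- match(ffq_items, table$item_id)
  cat_mat <- outer(z, w[keep] * config$latent_gain, "*") +
    matrix(rep(base[keep], each = n), n) +
    matrix(stats::rnorm(n * length(keep), 0, config$latent_noise), n)
  cat_mat <- pmin(pmax(round(cat_mat), 1), 9)
  ffq <- data.frame(
    participant_id = rep(ids, times = length(keep)),
    item_id = rep(ffq_items, each = n),
    frequency_category = as.integer(cat_mat),
    stringsAsFactors = FALSE)

  # --- open section: milk type and cooking fat ----------------------------
  milk_opts <- c("full_cream", "reduced_fat", "skim")
  milk_p <- function(zi) {  # healthier latent -> more low-fat milk
    p <- c(1, exp(0.8 * zi), exp(0.8 * zi)); p / sum(p)
  }
  milk <- vapply(z, function(zi) sample(milk_opts, 1, prob = milk_p(zi)),
                 character(1))
  fat_opts <- c("olive_oil", "vegetable_oil", "butter")
  fat_p <- function(zi) { p <- c(exp(0.9 * zi), 1, exp(-0.6 * zi)); p / sum(p) }
  cook_fat <- vapply(z, function(zi) sample(fat_opts, 1, prob = fat_p(zi)),
                     character(1))
  open_section <- rbind(
    data.frame(participant_id = ids, qualifier = "milk_type", value = milk,
               stringsAsFactors = FALSE),
    data.frame(participant_id = ids, qualifier = "cooking_fat",
               value = cook_fat, stringsAsFactors = FALSE))

  # --- demographics, GPAQ, blood pressure, diary --------------------------
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  age <- pmin(pmax(round(stats::rnorm(n, 49, 13)), 20), 69)
  height_m <- round(ifelse(sex == "male", stats::rnorm(n, 1.78, 0.07),
                           stats::rnorm(n, 1.64, 0.07)), 2)
  bmi_true <- pmin(pmax(stats::rnorm(n, 28.3, 6.5), 17), 50)
  weight_kg <- round(bmi_true * height_m^2, 1)
  waist_cm <- round(40 + 1.9 * bmi_true + stats::rnorm(n, 0, 5), 1)
  risk <- ifelse(stats::runif(n) < config$prop_high_risk, "high", "low")
  year <- ifelse(stats::runif(n) < config$prop_2022, 2022L, 2021L)

  gpaq <- data.frame(
    vig_work_days = sample(0:3, n, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
    vig_work_min = sample(c(0, 30, 60), n, TRUE),
    mod_work_days = sample(0:5, n, TRUE),
    mod_work_min = sample(c(0, 20, 30, 60), n, TRUE),
    travel_days = sample(0:7, n, TRUE),
    travel_min = sample(c(0, 10, 20, 30), n, TRUE),
    vig_rec_days = sample(0:5, n, TRUE, prob = c(0.35, 0.15, 0.2, 0.15, 0.1, 0.05)),
    vig_rec_min = sample(c(0, 30, 45, 60), n, TRUE),
    mod_rec_days = sample(0:7, n, TRUE),
    mod_rec_min = sample(c(0, 20, 30, 45), n, TRUE))
  met <- do.call(gpaq_met_minutes, gpaq)
  activity <- classify_activity(met)

  sbp_base <- stats::rnorm(n, ifelse(risk == "high", 130, 118), 10)
  dbp_base <- stats::rnorm(n, ifelse(risk == "high", 84, 76), 7)
  bp <- data.frame(
    sbp1 = round(sbp_base + stats::rnorm(n, 4, 4)),
    sbp2 = round(sbp_base + stats::rnorm(n, 0, 3)),
    sbp3 = round(sbp_base + stats::rnorm(n, 0, 3)),
    dbp1 = round(dbp_base + stats::rnorm(n, 3, 3)),
    dbp2 = round(dbp_base + stats::rnorm(n, 0, 2)),
    dbp3 = round(dbp_base + stats::rnorm(n, 0, 2)))

  wf_target <- stats::plogis(stats::rnorm(n, 0.5 + 0.3 * z, 0.8))
  diary <- data.frame(matrix(0, n, 6, dimnames = list(NULL,
    c(paste0("water_ml_d", 1:3), paste0("beverage_ml_d", 1:3)))))
  for (d in 1:3) {
    tot <- pmax(stats::rnorm(n, 2000, 350), 500)
    frac <- pmin(pmax(wf_target + stats::rnorm(n, 0, 0.05), 0), 1)
    diary[[paste0("water_ml_d", d)]] <- round(tot * frac)
    diary[[paste0("beverage_ml_d", d)]] <- round(tot)
  }

  b12_source <- stats::runif(n) < 0.9
  sofrito_per_week <- stats::rpois(n, lambda = pmax(1 + 0.4 * z, 0.1))
  added_sugar_in_drinks <- stats::runif(n) < stats::plogis(-0.2 - 0.5 * z)

  covariates <- data.frame(
    participant_id = ids, age = age, sex = sex, height_m = height_m,
    weight_kg = weight_kg, waist_cm = waist_cm, cvd_risk = risk, year = year,
    gpaq, bp, diary,
    b12_source = b12_source, sofrito_per_week = sofrito_per_week,
    added_sugar_in_drinks = added_sugar_in_drinks,
    stringsAsFactors = FALSE)

  # --- biomarkers: linear structure on the standardised DASH composite ----
  intake <- daily_intake(ffq, table, open_section = open_section,
                         participants = ids)
  energy <- estimate_energy(age, sex, weight_kg, activity)
  dash <- score_dash(intake$servings, energy)
  s <- as.numeric(scale(dash$composite))
  mix <- function(effect, extra = 0) {
    effect * s + extra + sqrt(max(1 - effect^2, 0)) * stats::rnorm(n)
  }
  covariates$hscrp_mg_l <- round(exp(config$hscrp_meanlog +
    config$hscrp_sdlog * mix(config$effect_crp)), 3)
  covariates$paf_ng_ml <- round(exp(config$paf_meanlog +
    config$paf_sdlog * mix(config$effect_paf,
                           config$year_paf_shift * (year == 2022))), 3)
  covariates$lppla2_nmol_min_ml <- round(pmax(
    config$lppla2_mean + config$gender_lppla2_shift * (sex == "male") -
      config$gender_lppla2_shift * config$prop_female +
      config$lppla2_sd * mix(config$effect_lppla2), 0.5), 2)

  out <- list(ffq = ffq, open_section = open_section,
              covariates = covariates, table = table, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ffq, file.path(out_dir, "ffq.csv"), row.names = FALSE)
    utils::write.csv(open_section, file.path(out_dir, "open_section.csv"),
                     row.names = FALSE)
    utils::write.csv(covariates, file.path(out_dir, "covariates.csv"),
                     row.names = FALSE)
    write_food_composition(table, file.path(out_dir, "food_composition.csv"))
    dq_log("synthetic cohort written to %s (n = %d)", out_dir, n)
  }
  out
}

#' Full-adherence profile for one index
#'
#' Programmatically constructs scorer inputs that reach exactly the printed
#' scale maximum of the requested index under the default configuration
#' (80 DASH and dairy-adjusted DASH, 14 Vegetarian Lifestyle, 100 HEIFA,
#' 14 MEDAS, 17 erMedDiet).
#'
#' @param index One of `"dash"`, `"dash_dairy_adj"`, `"vegetarian"`,
#'   `"heifa"`, `"medas"`, `"ermeddiet"`.
#' @return List with `index` and the scorer arguments; score it with
#'   [score_full_adherence()].
#' @export
generate_full_adherence_profile <- function(index) {
  index <- match.arg(index, c("dash", "dash_dairy_adj", "vegetarian",
                              "heifa", "medas", "ermeddiet"))
  pid <- "FULL"
  sv <- function(...) {
    vals <- list(...)
    all_tags <- c("fruit", "vegetable", "legume", "soy", "nut_seed", "dairy",
                  "dairy_lowfat", "red_meat", "processed_meat", "poultry",
                  "fish", "egg", "wholegrain", "refined_grain",
                  "high_fibre_grain", "white_bread", "sweets", "discretionary",
                  "oil_olive", "oil_other", "butter", "ssb", "wine", "alcohol",
                  "water_beverage")
    out <- as.data.frame(as.list(stats::setNames(rep(0, length(all_tags)),
                                                 all_tags)))
    for (nm in names(vals)) out[[nm]] <- vals[[nm]]
    cbind(data.frame(participant_id = pid, stringsAsFactors = FALSE), out)
  }
  switch(index,
    dash = ,
    dash_dairy_adj = list(
      index = index,
      servings = sv(fruit = 4.5, vegetable = 4.5, nut_seed = 0.5, legume = 0.5,
                    dairy = 2.5, dairy_lowfat = 2.5, wholegrain = 4,
                    high_fibre_grain = 4),
      energy = data.frame(bmr_kj = 6000, pa_factor = 1.4, eer_kj = 8400,
                          dash_level_kcal = 2000)),
    vegetarian = list(
      index = index,
      servings = sv(wholegrain = 5, legume = 0.5, soy = 0.5, vegetable = 6,
                    fruit = 3, nut_seed = 1, oil_olive = 1, oil_other = 1),
      eer_kj = 8368, activity_category = 2L, water_fraction = 0.6,
      b12_source = TRUE),
    heifa = list(
      index = index,
      servings = sv(vegetable = 5, fruit = 2, wholegrain = 6, dairy = 2.5,
                    red_meat = 0.5, poultry = 0.5, fish = 0.5, egg = 0.25,
                    legume = 0.5, nut_seed = 0.25),
      nutrients = data.frame(participant_id = pid, energy_kj = 8000,
                             sat_fat_g = 10, added_sugar_g = 10,
                             sodium_mg = 1500, stringsAsFactors = FALSE),
      veg_variety = 5L, fruit_variety = 2L, water_fraction = 0.6),
    medas = list(
      index = index,
      responses = data.frame(
        participant_id = pid, olive_oil_main_fat = TRUE,
        olive_oil_tbsp_day = 4, vegetable_serves_day = 2,
        fruit_serves_day = 3, red_processed_meat_serves_day = 0.5,
        butter_serves_day = 0, ssb_serves_day = 0, wine_glasses_week = 7,
        legume_serves_week = 3, fish_serves_week = 3, sweets_serves_week = 1,
        nut_serves_week = 3, white_meat_preference = TRUE,
        sofrito_per_week = 2, stringsAsFactors = FALSE)),
    ermeddiet = list(
      index = index,
      responses = data.frame(
        participant_id = pid, olive_oil_main_fat = TRUE,
        vegetable_serves_day = 2, fruit_serves_day = 3,
        red_processed_meat_serves_day = 0.5, butter_serves_day = 0,
        ssb_serves_day = 0, wine_glasses_week = 7, legume_serves_week = 3,
        fish_serves_week = 3, sweets_serves_week = 1, nut_serves_week = 3,
        white_meat_preference = TRUE, sofrito_per_week = 2,
        whole_grain_serves_day = 2, white_bread_serves_day = 0,
        refined_grain_serves_week = 0, added_sugar_in_drinks = FALSE,
        stringsAsFactors = FALSE)))
}

#' Score a full-adherence profile
#'
#' @param profile Output of [generate_full_adherence_profile()].
#' @param config Scoring configuration.
#' @return The composite score (length 1).
#' @export
score_full_adherence <- function(profile, config = default_score_config()) {
  res <- switch(profile$index,
    dash = score_dash(profile$servings, profile$energy, FALSE, config$dash),
    dash_dairy_adj = score_dash(profile$servings, profile$energy, TRUE,
                                config$dash),
    vegetarian = score_vegetarian(profile$servings, profile$eer_kj,
                                  profile$activity_category,
                                  profile$water_fraction, profile$b12_source,
                                  config = config$vegetarian),
    heifa = score_heifa(profile$servings, profile$nutrients,
                        profile$veg_variety, profile$fruit_variety,
                        profile$water_fraction, config$heifa),
    medas = score_medas(profile$responses, config = config$medas),
    ermeddiet = score_ermeddiet(profile$responses, config = config$ermeddiet))
  res$composite
}

#' Participant-flow ledger
#'
#' analysed = recruited - ineligible - declined, with consistency checks.
#'
#' @param recruited,ineligible,declined Non-negative counts.
#' @return List: the three inputs plus `analysed`.
#' @export
generate_flow_ledger <- function(recruited, ineligible, declined) {
  for (v in list(recruited = recruited, ineligible = ineligible,
                 declined = declined))
    if (length(v) != 1L || is.na(v) || v < 0 || v != as.integer(v))
      stop_domain("flow counts must be single non-negative integers")
  if (ineligible + declined > recruited)
    stop_domain("inconsistent flow: ineligible + declined exceeds recruited")
  ledger <- list(recruited = as.integer(recruited),
                 ineligible = as.integer(ineligible),
                 declined = as.integer(declined),
                 analysed = as.integer(recruited - ineligible - declined))
  dq_log("participant flow: %d recruited - %d ineligible - %d declined = %d analysed",
         ledger$recruited, ledger$ineligible, ledger$declined, ledger$analysed)
  ledger
}
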