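test_that("proportional points: forward caps at target, reverse decays above", {
  expect_equal(proportional_points(0, 4, 10, "forward"), 0)
  expect_equal(proportional_points(4, 4, 10, "forward"), 10)
  expect_equal(proportional_points(2, 4, 10, "forward"), 5)
  expect_equal(proportional_points(8, 4, 10, "forward"), 10)
  expect_equal(proportional_points(4, 2, 10, "reverse"), 5)  # 2x target
  expect_equal(proportional_points(1, 2, 10, "reverse"), 10)
  expect_equal(proportional_points(0, 0, 10, "reverse"), 10)  # zero target
  expect_equal(proportional_points(1, 0, 10, "reverse"), 0)
  expect_error(proportional_points(1, 0, 10, "forward"), "target")
  expect_error(proportional_points(-1, 2, 10, "forward"), ">= 0")
})

test_that("DASH componentwise oracle: full adherence 80, empty diet 30", {
  full <- generate_full_adherence_profile("dash")
  expect_equal(score_full_adherence(full), 80)

  empty <- full
  empty$servings[, -1] <- 0
  res <- score_dash(empty$servings, empty$energy)
  # reverse components at full points, forward at 0
  expect_equal(res$meat_poultry_fish_egg, 10)
  expect_equal(res$fats_oils, 10)
  expect_equal(res$sweets, 10)
  expect_equal(res$fruit + res$vegetable + res$nuts_seeds_legumes +
                 res$dairy_total + res$dairy_lowfat + res$whole_grain +
                 res$high_fibre_grain, 0)
  expect_equal(res$composite, 30)
  expect_error(score_dash(empty$servings, NULL), "energy")
})

test_that("dairy adjustment dominates, equality iff low-fat criterion met", {
  sv <- random_servings(60, seed = 11)
  en <- default_energy(60)
  plain <- score_dash(sv, en, dairy_adjusted = FALSE)
  adj <- score_dash(sv, en, dairy_adjusted = TRUE)
  expect_true(all(adj$composite >= plain$composite - 1e-12))
  met <- with(sv, dairy > 0 & dairy_lowfat / dairy >= 0.75)
  expect_equal(abs(adj$composite - plain$composite) < 1e-9, met)
  expect_equal(attr(adj, "scale_max"), 80)
})

test_that("vegetarian index: full adherence 14, sunlight always full, codomain", {
  full <- generate_full_adherence_profile("vegetarian")
  expect_equal(score_full_adherence(full), 14)

  sv <- random_servings(40, seed = 3)
  res <- score_vegetarian(sv, eer_kj = runif(40, 6000, 13000),
                          activity_category = sample(0:2, 40, TRUE),
                          water_fraction = runif(40),
                          b12_source = runif(40) > 0.5)
  expect_equal(res$sunlight, rep(1, 40))
  comp_cols <- setdiff(names(res), c("participant_id", "composite"))
  for (cc in comp_cols)
    expect_true(all(res[[cc]] %in% c(0, 0.5, 1)), label = cc)
  expect_true(all(res$composite >= 0 & res$composite <= 14))
  expect_error(score_vegetarian(sv, -1, 1, 0.5, TRUE), "energy")
})

test_that("vegetarian scoring is invariant to energy scale", {
  sv <- random_servings(25, seed = 9)
  eer <- runif(25, 7000, 12000)
  act <- sample(0:2, 25, TRUE); wf <- runif(25); b12 <- runif(25) > 0.3
  a <- score_vegetarian(sv, eer, act, wf, b12)
  sv2 <- sv; sv2[, -1] <- sv2[, -1] * 2
  b <- score_vegetarian(sv2, eer * 2, act, wf, b12)
  expect_equal(a$composite, b$composite, tolerance = 1e-12)
})

test_that("HEIFA: full adherence 100, stated sat-fat and water rules", {
  full <- generate_full_adherence_profile("heifa")
  expect_equal(score_full_adherence(full), 100)

  base <- generate_full_adherence_profile("heifa")
  nutr <- function(satfat_pct, energy = 8000) {
    n <- base$nutrients
    n$energy_kj <- energy
    n$sat_fat_g <- satfat_pct / 100 * energy / 37
    n
  }
  sc <- function(n) score_heifa(base$servings, n, base$veg_variety,
                                base$fruit_variety, base$water_fraction)
  expect_equal(sc(nutr(9.9))$sat_fat, 10)
  expect_equal(sc(nutr(15))$sat_fat, 0)
  expect_equal(sc(nutr(16))$sat_fat, 0)
  expect_equal(sc(nutr(12.5))$sat_fat, 5)  # linear between the thresholds

  wsc <- function(wf) score_heifa(base$servings, base$nutrients,
                                  base$veg_variety, base$fruit_variety, wf)
  expect_equal(wsc(0.5)$water, 5)
  expect_equal(wsc(0.25)$water, 2.5)
  expect_equal(wsc(0.9)$water, 5)

  zero_energy <- base$nutrients; zero_energy$energy_kj <- 0
  expect_error(sc(zero_energy), "energy")
})

test_that("MEDAS: exactly k criteria met scores k (constructed patterns)", {
  cfg <- default_score_config()$medas$criteria
  make_resp <- function(mask) {
    out <- data.frame(participant_id = "X")
    for (i in seq_along(cfg)) {
      nm <- names(cfg)[i]; rule <- cfg[[nm]]; met <- mask[i]
      out[[nm]] <- switch(rule$op,
        ge = if (met) rule$threshold else rule$threshold - 0.5,
        lt = if (met) max(rule$threshold - 0.5, 0) else rule$threshold,
        true = met, false = !met)
    }
    out
  }
  expect_equal(score_medas(make_resp(rep(TRUE, 14)))$composite, 14)
  expect_equal(score_medas(make_resp(rep(FALSE, 14)))$composite, 0)
  set.seed(5)
  for (k in c(1, 3, 7, 10, 13)) {
    mask <- sample(c(rep(TRUE, k), rep(FALSE, 14 - k)))
    expect_equal(score_medas(make_resp(mask))$composite, k, label = paste("k =", k))
  }
})

test_that("erMedDiet: 0-17 range and agreement with MEDAS on shared criteria", {
  full <- generate_full_adherence_profile("ermeddiet")
  expect_equal(score_full_adherence(full), 17)
  resp <- full$responses
  resp[, sapply(resp, is.logical)] <- FALSE
  resp[, sapply(resp, is.numeric)] <- 0
  resp$red_processed_meat_serves_day <- 5
  resp$butter_serves_day <- 2; resp$ssb_serves_day <- 2
  resp$sweets_serves_week <- 10; resp$white_bread_serves_day <- 3
  resp$refined_grain_serves_week <- 9; resp$added_sugar_in_drinks <- TRUE
  expect_equal(score_ermeddiet(resp)$composite, 0)

  # identical answers give identical points on the shared criteria
  sv <- random_servings(30, seed = 21)
  answers <- derive_screener_responses(sv, olive_oil_main_fat = runif(30) > 0.5,
                                       sofrito_per_week = rpois(30, 2),
                                       added_sugar_in_drinks = runif(30) > 0.5)
  m <- score_medas(answers); e <- score_ermeddiet(answers)
  shared <- intersect(names(default_score_config()$medas$criteria),
                      names(default_score_config()$ermeddiet$criteria))
  expect_length(shared, 13)
  for (nm in shared) expect_equal(e[[nm]], m[[nm]], label = nm)
})

test_that("screener missing-data policy: strict errors, lenient scores zero", {
  resp <- generate_full_adherence_profile("medas")$responses
  resp$nut_serves_week <- NULL
  expect_error(score_medas(resp), "nut_serves_week")
  expect_equal(score_medas(resp, strict = FALSE)$composite, 13)
  resp2 <- generate_full_adherence_profile("medas")$responses
  resp2$fruit_serves_day <- NA
  expect_error(score_medas(resp2), "fruit_serves_day")
  expect_equal(score_medas(resp2, strict = FALSE)$composite, 13)
})

test_that("all six composites stay within their printed ranges under fuzzing", {
  maxima <- c(dash = 80, dash_dairy_adjusted = 80, vegetarian_lifestyle = 14,
              heifa = 100, medas = 14, ermeddiet = 17)
  for (seed in 1:5) {
    sv <- random_servings(30, seed = seed)
    set.seed(seed + 100)
    en <- default_energy(30)
    en$dash_level_kcal <- sample(c(1600, 2000, 2600, 3100), 30, TRUE)
    nu <- data.frame(participant_id = sv$participant_id,
                     energy_kj = runif(30, 4000, 15000),
                     sat_fat_g = runif(30, 0, 60),
                     added_sugar_g = runif(30, 0, 120),
                     sodium_mg = runif(30, 500, 5000))
    wf <- runif(30); act <- sample(0:2, 30, TRUE)
    answers <- derive_screener_responses(sv, runif(30) > 0.5, rpois(30, 2),
                                         runif(30) > 0.5)
    res <- list(
      dash = score_dash(sv, en),
      dash_dairy_adjusted = score_dash(sv, en, dairy_adjusted = TRUE),
      vegetarian_lifestyle = score_vegetarian(sv, runif(30, 6000, 13000), act,
                                              wf, runif(30) > 0.5),
      heifa = score_heifa(sv, nu, sample(0:8, 30, TRUE), sample(0:4, 30, TRUE), wf),
      medas = score_medas(answers),
      ermeddiet = score_ermeddiet(answers))
    for (nm in names(res)) {
      expect_true(all(res[[nm]]$composite >= 0 &
                        res[[nm]]$composite <= maxima[[nm]]),
                  label = paste(nm, "seed", seed))
      comp_cols <- setdiff(names(res[[nm]]), c("participant_id", "composite"))
      expect_equal(res[[nm]]$composite,
                   rowSums(res[[nm]][, comp_cols, drop = FALSE]),
                   tolerance = 1e-12)
    }
  }
})

test_that("composites are monotone in forward and reverse foods", {
  sv <- random_servings(20, seed = 31)
  en <- default_energy(20)
  base <- score_dash(sv, en)$composite
  up <- sv; up$fruit <- up$fruit + 1
  expect_true(all(score_dash(up, en)$composite >= base - 1e-12))
  down <- sv; down$sweets <- down$sweets + 1
  expect_true(all(score_dash(down, en)$composite <= base + 1e-12))

  nu <- data.frame(participant_id = sv$participant_id, energy_kj = 9000,
                   sat_fat_g = 20, added_sugar_g = 30, sodium_mg = 2500)
  hbase <- score_heifa(sv, nu, 3, 2, 0.4)$composite
  hup <- sv; hup$vegetable <- hup$vegetable + 1
  expect_true(all(score_heifa(hup, nu, 3, 2, 0.4)$composite >= hbase - 1e-12))
  hdown <- sv; hdown$discretionary <- hdown$discretionary + 1
  expect_true(all(score_heifa(hdown, nu, 3, 2, 0.4)$composite <= hbase + 1e-12))
})

test_that("score config round-trips through YAML and is validated", {
  cfg <- default_score_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_score_config(cfg, path)
  cfg2 <- read_score_config(path)
  expect_equal(cfg2$dash$components$fruit$targets,
               cfg$dash$components$fruit$targets)
  expect_equal(length(cfg2$ermeddiet$criteria), 17)
  # scoring under the round-tripped config is identical
  sv <- random_servings(10, seed = 2); en <- default_energy(10)
  expect_equal(score_dash(sv, en, config = cfg2$dash)$composite,
               score_dash(sv, en)$composite)
  bad <- cfg; bad$medas$criteria$sofrito_per_week <- NULL
  expect_error(dietquality:::validate_score_config(bad), "14 criteria")
  # shipped fixture matches the in-code defaults
  shipped <- read_score_config(system.file("extdata", "score_config.yaml",
                                           package = "dietquality"))
  expect_equal(shipped$dash$components$sweets$targets,
               cfg$dash$components$sweets$targets)
})
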