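test_that("frequency scale maps the 9 categories to occasions/day", {
  sc <- default_frequency_scale()
  expect_equal(frequency_to_daily(1), 0)
  expect_equal(frequency_to_daily(3), 1 / 7, tolerance = 1e-12)
  expect_equal(frequency_to_daily(9), 6)
  expect_equal(frequency_to_daily(c(1, 4, 9)), c(0, 3 / 7, 6))
  expect_false(is.unsorted(sc))
  expect_error(frequency_to_daily(0), "1..9")
  expect_error(frequency_to_daily(10), "1..9")
  expect_error(frequency_to_daily(3, scale = rev(sc)), "non-decreasing")
})

test_that("gram intake is occasions x portion fraction x serving size", {
  tb <- tiny_table()
  resp <- data.frame(participant_id = "A", item_id = "apple",
                     frequency_category = 4)  # 2-4/week -> 3/7 per day
  g <- compute_gram_intake(resp, tb)
  expect_equal(g$grams_per_day, 3 / 7 * 80, tolerance = 1e-12)  # 34.29 g/day

  resp$frequency_category <- 1
  expect_equal(compute_gram_intake(resp, tb)$grams_per_day, 0)

  # portion fraction scales grams
  tb2 <- tb; tb2$portion_fraction <- c(0.5, 1, 1)
  resp$frequency_category <- 6
  expect_equal(compute_gram_intake(resp, tb2)$grams_per_day, 40)

  bad <- data.frame(participant_id = "A", item_id = "dragonfruit",
                    frequency_category = 2)
  expect_error(compute_gram_intake(bad, tb), "dragonfruit")
  dup <- rbind(resp, resp)
  expect_error(compute_gram_intake(dup, tb), "duplicate")
})

test_that("servings, nutrients and energy match an independent naive oracle", {
  tb <- tiny_table()
  resp <- data.frame(
    participant_id = c("A", "A", "A", "B", "B"),
    item_id = c("apple", "bread", "cheese", "apple", "cheese"),
    frequency_category = c(6, 4, 3, 9, 1))
  grams <- compute_gram_intake(resp, tb)
  sv <- compute_servings(grams, tb)
  nu <- compute_nutrients(grams, tb)
  oracle <- naive_intake(resp, tb)
  for (pid in c("A", "B")) {
    i <- which(sv$participant_id == pid)
    for (tg in names(oracle$servings[[pid]]))
      expect_equal(sv[[tg]][i], oracle$servings[[pid]][[tg]],
                   tolerance = 1e-9, label = paste(pid, tg))
    for (nm in names(oracle$nutrients[[pid]]))
      expect_equal(nu[[nm]][i], oracle$nutrients[[pid]][[nm]],
                   tolerance = 1e-9, label = paste(pid, nm))
  }
  # forced arithmetic: 150 g/day of a 75 g-serving fruit item = 2 serves
  tb75 <- tiny_table(); tb75$serving_size_g[1] <- 75
  g2 <- data.frame(participant_id = "C", item_id = "apple", grams_per_day = 150)
  expect_equal(compute_servings(g2, tb75)$fruit, 2)
  # multi-tag item contributes to both groups
  g3 <- data.frame(participant_id = "C", item_id = "cheese", grams_per_day = 80)
  sv3 <- compute_servings(g3, tb)
  expect_equal(sv3$dairy, 2)
  expect_equal(sv3$discretionary, 2)
  # 200 g/day at 250 kJ/100 g -> 500 kJ/day
  g4 <- data.frame(participant_id = "C", item_id = "apple", grams_per_day = 200)
  expect_equal(compute_nutrients(g4, tb)$energy_kj, 500)
})

test_that("intake computation is linear and additive", {
  tb <- tiny_table()
  set.seed(42)
  resp <- data.frame(
    participant_id = "A",
    item_id = sample(tb$item_id, 3),
    frequency_category = sample(2:9, 3))
  sc <- default_frequency_scale()
  base <- compute_gram_intake(resp, tb, sc)
  tripled <- compute_gram_intake(resp, tb, sc * 3)
  expect_equal(tripled$grams_per_day, 3 * base$grams_per_day, tolerance = 1e-12)
  expect_equal(compute_nutrients(tripled, tb)$energy_kj,
               3 * compute_nutrients(base, tb)$energy_kj, tolerance = 1e-12)

  # additivity over disjoint response sets (distinct items, same participant)
  r1 <- resp[1, ]; r2 <- resp[2:3, ]
  g_all <- compute_gram_intake(resp, tb, sc)
  nu_all <- compute_nutrients(g_all, tb)
  nu_split <- compute_nutrients(compute_gram_intake(r1, tb, sc), tb)$energy_kj +
    compute_nutrients(compute_gram_intake(r2, tb, sc), tb)$energy_kj
  expect_equal(nu_all$energy_kj, nu_split, tolerance = 1e-12)

  # group-sum conservation for single-tag items (apple is the only one)
  sv <- compute_servings(g_all, tb)
  expect_equal(sv$fruit * 80, sum(g_all$grams_per_day[g_all$item_id == "apple"]),
               tolerance = 1e-12)
})

test_that("percent energy is correct and scale invariant", {
  expect_equal(percent_energy(20, 7400, 37), 10)
  expect_equal(percent_energy(0, 7400, 37), 0)
  expect_equal(percent_energy(40, 14800, 37), percent_energy(20, 7400, 37))
  expect_error(percent_energy(20, 0, 37), "energy")
})

test_that("open-section qualifiers substitute variant items", {
  tb <- build_demo_composition_table()
  resp <- data.frame(participant_id = c("A", "B"),
                     item_id = c("milk", "milk"),
                     frequency_category = c(6, 6))
  open <- data.frame(participant_id = c("A", "B", "B"),
                     qualifier = c("milk_type", "milk_type", "spread_type"),
                     value = c("skim", "oat_milk", "jam"))
  out <- apply_open_section(resp, open, tb)
  expect_equal(out$item_id[out$participant_id == "A"], "milk_skim")
  # unmatched value and unknown qualifier are ignored, not errors
  expect_equal(out$item_id[out$participant_id == "B"], "milk")
  # substitution changes the low-fat dairy share downstream
  sv <- compute_servings(compute_gram_intake(out, tb), tb)
  expect_gt(sv$dairy_lowfat[sv$participant_id == "A"], 0)
  expect_equal(sv$dairy_lowfat[sv$participant_id == "B"], 0)
})

test_that("composition table validation fails loudly", {
  df <- as.data.frame(tiny_table())
  expect_error(food_composition(df[, -1]), "item_id")
  df2 <- df; df2$serving_size_g[1] <- 0
  expect_error(food_composition(df2), "serving_size_g")
  df3 <- df; df3$tags[2] <- ""
  expect_error(food_composition(df3), "tag")
  df4 <- rbind(df, df[1, ])
  expect_error(food_composition(df4), "unique")
  df5 <- df; df5$energy_kj_100g[1] <- -1
  expect_error(food_composition(df5), "energy_kj_100g")
})

test_that("composition table round-trips through CSV", {
  tb <- build_demo_composition_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_composition(tb, path)
  tb2 <- read_food_composition(path)
  expect_equal(as.data.frame(tb2)[names(as.data.frame(tb))],
               as.data.frame(tb), ignore_attr = TRUE)
})
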