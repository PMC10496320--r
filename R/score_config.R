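# Versioned scoring configuration. The source publications for the six
# indices define component cut-points in supplementary tables; here every
# target, limit and threshold is data, not code, so the constants are
# auditable and replaceable. Defaults are transcribed from the public source
# instruments: the NHLBI DASH eating plan serving recommendations (Gunther
# scoring scheme), the Loma Linda vegetarian food-guide pyramid, HEIFA-2013,
# the published 14-item MEDAS and the PREDIMED-Plus 17-item screener.

#' Default scoring configuration for the six diet-quality indices
#'
#' Returns a nested list with one block per index. DASH component targets are
#' serves/day keyed by assigned calorie level (1600/2000/2600/3100 kcal);
#' weekly recommendations in the source plan are expressed as day rates.
#' Vegetarian Lifestyle Index components carry `full`/`half` thresholds on
#' 2000 kcal-standardised serves (forward: point at >= full, half point at
#' >= half; reverse: point at <= full, half point at <= half). HEIFA blocks
#' carry the serving targets, percent-of-energy bands and the water/alcohol
#' caps. MEDAS and erMedDiet blocks list one binary criterion per screener
#' item.
#'
#' Serialise with [write_score_config()] / [read_score_config()] to audit or
#' override any constant.
#'
#' @return Nested configuration list.
#' @export
default_score_config <- function() {
  list(
    version = "1.0",
    dash = list(
      levels_kcal = c(1600, 2000, 2600, 3100),
      components = list(
        # six 10-point components
        fruit = list(max_points = 10, direction = "forward",
                     groups = "fruit",
                     targets = c(`1600` = 4, `2000` = 4.5, `2600` = 5.5, `3100` = 6)),
        vegetable = list(max_points = 10, direction = "forward",
                         groups = "vegetable",
                         targets = c(`1600` = 3.5, `2000` = 4.5, `2600` = 5.5, `3100` = 6)),
        meat_poultry_fish_egg = list(max_points = 10, direction = "reverse",
                                     groups = c("red_meat", "processed_meat",
                                                "poultry", "fish", "egg"),
                                     targets = c(`1600` = 1.5, `2000` = 2, `2600` = 2, `3100` = 2.5)),
        nuts_seeds_legumes = list(max_points = 10, direction = "forward",
                                  groups = c("nut_seed", "legume"),
                                  targets = c(`1600` = 3/7, `2000` = 4.5/7, `2600` = 1, `3100` = 1)),
        fats_oils = list(max_points = 10, direction = "reverse",
                         groups = c("oil_olive", "oil_other", "butter"),
                         targets = c(`1600` = 2, `2000` = 2.5, `2600` = 3, `3100` = 4)),
        sweets = list(max_points = 10, direction = "reverse",
                      groups = "sweets",
                      targets = c(`1600` = 0, `2000` = 5/7, `2600` = 2/7, `3100` = 2)),
        # four 5-point components
        dairy_total = list(max_points = 5, direction = "forward",
                           groups = "dairy",
                           targets = c(`1600` = 2.5, `2000` = 2.5, `2600` = 3, `3100` = 3.5)),
        dairy_lowfat = list(max_points = 5, type = "share",
                            numerator = "dairy_lowfat", denominator = "dairy",
                            target_share = 0.75),
        whole_grain = list(max_points = 5, direction = "forward",
                           groups = "wholegrain",
                           targets = c(`1600` = 3, `2000` = 4, `2600` = 5.5, `3100` = 6.5)),
        high_fibre_grain = list(max_points = 5, direction = "forward",
                                groups = "high_fibre_grain",
                                targets = c(`1600` = 3, `2000` = 4, `2600` = 5.5, `3100` = 6.5))
      )
    ),
    vegetarian = list(
      reference_kj = 8368,  # 2000 kcal
      diet_components = list(
        whole_grain   = list(direction = "forward", groups = "wholegrain", full = 5, half = 2.5),
        legume_soy    = list(direction = "forward", groups = c("legume", "soy"), full = 1, half = 0.5),
        vegetable     = list(direction = "forward", groups = "vegetable", full = 6, half = 3),
        fruit         = list(direction = "forward", groups = "fruit", full = 3, half = 1.5),
        nut_seed      = list(direction = "forward", groups = "nut_seed", full = 1, half = 0.5),
        vegetable_oil = list(direction = "forward", groups = c("oil_olive", "oil_other"),
                             full = 2, half = 1),
        dairy      = list(direction = "reverse", groups = "dairy", full = 2, half = 4),
        egg        = list(direction = "reverse", groups = "egg", full = 0.5, half = 1),
        sweets     = list(direction = "reverse", groups = "sweets", full = 1, half = 2),
        flesh_food = list(direction = "reverse",
                          groups = c("red_meat", "processed_meat", "poultry", "fish"),
                          full = 0, half = 0.5)
      ),
      exercise = list(full_category = 2, half_category = 1),
      water = list(full = 0.5, half = 0.25),
      sunlight_default = 1
    ),
    heifa = list(
      vegetable = list(quantity_max = 5, target = 5, variety_max = 5, variety_target = 5),
      fruit     = list(quantity_max = 5, target = 2, variety_max = 5, variety_target = 2),
      grain     = list(quantity_max = 5, target = 6,
                       groups = c("wholegrain", "refined_grain"),
                       wholegrain_max = 5, wholegrain_share = 0.5),
      dairy     = list(max_points = 10, target = 2.5, groups = "dairy"),
      meat_alternatives = list(max_points = 10, target = 2.5,
                               groups = c("red_meat", "poultry", "fish", "egg",
                                          "legume", "nut_seed")),
      discretionary = list(max_points = 10, full_at = 2.5, zero_at = 6,
                           groups = "discretionary"),
      sat_fat     = list(max_points = 10, full_at_pct = 10, zero_at_pct = 15),
      added_sugar = list(max_points = 10, full_at_pct = 15, zero_at_pct = 20),
      sodium      = list(max_points = 10, full_at_mg = 2000, zero_at_mg = 3600),
      water       = list(max_points = 5, full_fraction = 0.5),
      alcohol     = list(max_points = 5, limit_serves = 2, groups = "alcohol")
    ),
    medas = list(
      criteria = list(
        olive_oil_main_fat     = list(op = "true"),
        olive_oil_tbsp_day     = list(op = "ge", threshold = 4),
        vegetable_serves_day   = list(op = "ge", threshold = 2),
        fruit_serves_day       = list(op = "ge", threshold = 3),
        red_processed_meat_serves_day = list(op = "lt", threshold = 1),
        butter_serves_day      = list(op = "lt", threshold = 1),
        ssb_serves_day         = list(op = "lt", threshold = 1),
        wine_glasses_week      = list(op = "ge", threshold = 7),
        legume_serves_week     = list(op = "ge", threshold = 3),
        fish_serves_week       = list(op = "ge", threshold = 3),
        sweets_serves_week     = list(op = "lt", threshold = 3),
        nut_serves_week        = list(op = "ge", threshold = 3),
        white_meat_preference  = list(op = "true"),
        sofrito_per_week       = list(op = "ge", threshold = 2)
      )
    ),
    ermeddiet = list(
      criteria = list(
        olive_oil_main_fat     = list(op = "true"),
        vegetable_serves_day   = list(op = "ge", threshold = 2),
        fruit_serves_day       = list(op = "ge", threshold = 3),
        red_processed_meat_serves_day = list(op = "lt", threshold = 1),
        butter_serves_day      = list(op = "lt", threshold = 1),
        ssb_serves_day         = list(op = "lt", threshold = 1),
        wine_glasses_week      = list(op = "ge", threshold = 7),
        legume_serves_week     = list(op = "ge", threshold = 3),
        fish_serves_week       = list(op = "ge", threshold = 3),
        sweets_serves_week     = list(op = "lt", threshold = 3),
        nut_serves_week        = list(op = "ge", threshold = 3),
        white_meat_preference  = list(op = "true"),
        sofrito_per_week       = list(op = "ge", threshold = 2),
        whole_grain_serves_day = list(op = "ge", threshold = 1),
        white_bread_serves_day = list(op = "lt", threshold = 1),
        refined_grain_serves_week = list(op = "lt", threshold = 2),
        added_sugar_in_drinks  = list(op = "false")
      )
    )
  )
}

#' Read / write a scoring configuration (YAML)
#'
#' @param path File path.
#' @param config Configuration list (see [default_score_config()]).
#' @return `read_score_config()` returns the validated configuration list.
#' @export
read_score_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml returns per-level DASH targets as named lists; restore numeric vectors
  cfg$dash$components <- lapply(cfg$dash$components, function(comp) {
    if (!is.null(comp$targets)) comp$targets <- unlist(comp$targets)
    comp
  })
  cfg$dash$levels_kcal <- as.numeric(unlist(cfg$dash$levels_kcal))
  validate_score_config(cfg)
}

#' @rdname read_score_config
#' @export
write_score_config <- function(config, path) {
  # yaml drops names on atomic vectors; keep per-level targets as maps
  config$dash$components <- lapply(config$dash$components, function(comp) {
    if (!is.null(comp$targets)) comp$targets <- as.list(comp$targets)
    comp
  })
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

validate_score_config <- function(cfg) {
  for (block in c("dash", "vegetarian", "heifa", "medas", "ermeddiet"))
    if (is.null(cfg[[block]]))
      stop_domain("score config missing block '", block, "'")
  if (length(cfg$medas$criteria) != 14L)
    stop_domain("MEDAS block must define exactly 14 criteria")
  if (length(cfg$ermeddiet$criteria) != 17L)
    stop_domain("erMedDiet block must define exactly 17 criteria")
  for (comp in cfg$dash$components)
    if (!is.null(comp$targets) &&
        !all(as.character(cfg$dash$levels_kcal) %in% names(comp$targets)))
      stop_domain("every DASH component needs a target per calorie level")
  cfg
}
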