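# The six diet-quality composites. Each scorer returns a data frame with one
# row per participant, per-component point columns, and a `composite` column;
# the index name and scale maximum travel as attributes.

score_result <- function(df, index, scale_max) {
  comp_cols <- setdiff(names(df), c("participant_id", "composite"))
  df$composite <- rowSums(df[, comp_cols, drop = FALSE])
  df <- df[, c("participant_id", comp_cols, "composite")]
  attr(df, "index") <- index
  attr(df, "scale_max") <- scale_max
  class(df) <- c("score_result", "data.frame")
  df
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<%s score, 0-%s, n = %d>\n",
              attr(x, "index"), format(attr(x, "scale_max")), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

# rowSums over the tag columns named in `groups`; absent tags contribute 0
group_serves <- function(servings, groups) {
  present <- intersect(groups, names(servings))
  if (!length(present)) return(rep(0, nrow(servings)))
  rowSums(servings[, present, drop = FALSE])
}

#' Proportional component points
#'
#' Forward components award `max_points * min(intake/target, 1)`: full points
#' at or above the target, proportionally fewer below. Reverse components
#' (where lower intake is favoured) award full points at or below the target
#' and decay as `max_points * target/intake` above it; a reverse target of 0
#' awards full points only for zero intake.
#'
#' @param intake Serves/day (>= 0), vectorised.
#' @param target Target serves/day (> 0 for forward; >= 0 for reverse).
#' @param max_points Component maximum.
#' @param direction `"forward"` or `"reverse"`.
#' @return Points in `[0, max_points]`.
#' @export
proportional_points <- function(intake, target, max_points, direction) {
  direction <- match.arg(direction, c("forward", "reverse"))
  if (anyNA(intake) || any(intake < 0))
    stop_domain("intake must be >= 0")
  if (anyNA(target) || any(target < 0) ||
      (direction == "forward" && any(target == 0)))
    stop_domain("target must be > 0 (forward) or >= 0 (reverse)")
  if (direction == "forward") {
    max_points * pmin(intake / target, 1)
  } else {
    ifelse(intake <= target, max_points,
           max_points * target / intake)
  }
}

# ---------------------------------------------------------------------------
# DASH (0-80) and dairy-adjusted DASH

#' DASH adherence score (0-80)
#'
#' Ten components against the DASH eating-plan serving recommendations at the
#' participant's assigned calorie level: six 10-point components (fruits incl.
#' juice; vegetables incl. potato; meat/poultry/fish/eggs, reverse; nuts,
#' seeds and legumes; fats and oils, reverse; sweets, reverse) and four
#' 5-point components (total dairy; low-fat share of dairy; whole grains;
#' high-fibre grains). Lower intakes score proportionally; reverse scoring
#' applies where lower intakes are favoured.
#'
#' The dairy-adjusted variant drops the requirement that 75% of dairy be
#' low fat by awarding that component's 5 points unconditionally, keeping the
#' 0-80 scale so composites remain comparable.
#'
#' @param servings Wide serves/day frame from [compute_servings()].
#' @param energy Energy assignment from [estimate_energy()] (needs
#'   `dash_level_kcal`), row-aligned with `servings`.
#' @param dairy_adjusted Apply the dairy adjustment?
#' @param config DASH block of the scoring configuration.
#' @return A `score_result` (0-80).
#' @export
score_dash <- function(servings, energy, dairy_adjusted = FALSE,
                       config = default_score_config()$dash) {
  if (is.null(energy) || is.null(energy$dash_level_kcal))
    stop_domain("score_dash requires an energy assignment with dash_level_kcal")
  if (nrow(energy) != nrow(servings))
    stop_domain("servings and energy assignment must have one row per participant")
  lvl <- as.character(energy$dash_level_kcal)
  out <- data.frame(participant_id = servings$participant_id,
                    stringsAsFactors = FALSE)
  for (nm in names(config$components)) {
    comp <- config$components[[nm]]
    if (identical(comp$type, "share")) {
      num <- group_serves(servings, comp$numerator)
      den <- group_serves(servings, comp$denominator)
      share <- ifelse(den > 0, num / den, 0)
      pts <- if (dairy_adjusted) rep(comp$max_points, nrow(servings))
             else comp$max_points * pmin(share / comp$target_share, 1)
    } else {
      intake <- group_serves(servings, comp$groups)
      target <- unname(comp$targets[lvl])
      if (anyNA(target))
        stop_domain("no DASH target for calorie level(s): ",
                    paste(unique(lvl[is.na(target)]), collapse = ", "))
      pts <- proportional_points(intake, target, comp$max_points, comp$direction)
    }
    out[[nm]] <- pts
  }
  score_result(out, if (dairy_adjusted) "dash_dairy_adjusted" else "dash", 80)
}

# ---------------------------------------------------------------------------
# Vegetarian Lifestyle Index (0-14)

# 0 / 0.5 / 1 stepped points on a standardised intake
stepped_point <- function(x, full, half, direction) {
  if (direction == "forward") {
    ifelse(x >= full, 1, ifelse(x >= half, 0.5, 0))
  } else {
    ifelse(x <= full, 1, ifelse(x <= half, 0.5, 0))
  }
}

#' Vegetarian Lifestyle Index (0-14)
#'
#' Fourteen components scored 0, 0.5 or 1: eleven dietary (whole grains,
#' legumes and soy, vegetables, fruits, nuts and seeds, vegetable oils, and
#' reverse-scored dairy, eggs, sweets and flesh foods, plus a reliable
#' vitamin B-12 source) and three lifestyle (daily exercise from the GPAQ
#' activity class, water intake from the diary, and sunlight exposure, which
#' defaults to the full point for a subtropical study setting). Dietary
#' serves are standardised to 2000 kcal (8368 kJ) via the participant's
#' estimated energy requirement before scoring.
#'
#' @param servings Wide serves/day frame.
#' @param eer_kj Estimated energy requirement, kJ/day (from [estimate_energy()]).
#' @param activity_category GPAQ class 0/1/2.
#' @param water_fraction Diary water fraction in `[0, 1]`.
#' @param b12_source Logical: reliable B-12 source consumed.
#' @param sunlight Points for sunlight exposure (default full, per config).
#' @param config Vegetarian block of the scoring configuration.
#' @return A `score_result` (0-14).
#' @export
score_vegetarian <- function(servings, eer_kj, activity_category,
                             water_fraction, b12_source,
                             sunlight = NULL,
                             config = default_score_config()$vegetarian) {
  n <- nrow(servings)
  if (anyNA(eer_kj) || any(eer_kj <= 0))
    stop_domain("score_vegetarian requires a positive energy requirement")
  if (anyNA(activity_category) || !all(activity_category %in% 0:2))
    stop_domain("activity_category must be 0, 1 or 2")
  if (anyNA(water_fraction) || any(water_fraction < 0 | water_fraction > 1))
    stop_domain("water_fraction must lie in [0, 1]")
  if (anyNA(b12_source))
    stop_domain("b12_source flag is required")
  std <- config$reference_kj / eer_kj
  out <- data.frame(participant_id = servings$participant_id,
                    stringsAsFactors = FALSE)
  for (nm in names(config$diet_components)) {
    comp <- config$diet_components[[nm]]
    x <- group_serves(servings, comp$groups) * std
    out[[nm]] <- stepped_point(x, comp$full, comp$half, comp$direction)
  }
  out$b12_source <- as.numeric(as.logical(b12_source))
  out$exercise <- ifelse(activity_category >= config$exercise$full_category, 1,
                         ifelse(activity_category >= config$exercise$half_category,
                                0.5, 0))
  out$water <- stepped_point(water_fraction, config$water$full,
                             config$water$half, "forward")
  out$sunlight <- rep(sunlight %||% config$sunlight_default, n)
  score_result(out, "vegetarian_lifestyle", 14)
}

# ---------------------------------------------------------------------------
# HEIFA (0-100)

# linear band: full points at/below full_at, zero at/above zero_at
linear_band <- function(x, full_at, zero_at, max_points) {
  max_points * pmin(pmax((zero_at - x) / (zero_at - full_at), 0), 1)
}

#' HEIFA diet-quality score (0-100)
#'
#' Eleven components against the Australian Guide to Healthy Eating: nine
#' scored 0-10 (vegetables and fruit, each half quantity / half variety;
#' grains, half quantity / half wholegrain share with full marks when at
#' least 50% of grains are wholegrain; dairy; meat and alternatives;
#' discretionary foods, reverse; saturated fat as % of energy, full below
#' 10%E and zero at 15%E or more, linear between; added sugars % of energy;
#' sodium) and two scored 0-5 (water, full marks at a water fraction of 50%
#' of total beverages, proportional below; alcohol, full marks at or below
#' the serves cap, zero above).
#'
#' @param servings Wide serves/day frame.
#' @param nutrients Wide nutrients/day frame from [compute_nutrients()]
#'   (needs `energy_kj > 0`, `sat_fat_g`, `added_sugar_g`, `sodium_mg`).
#' @param veg_variety,fruit_variety Distinct-item counts from [variety_counts()].
#' @param water_fraction Diary water fraction.
#' @param config HEIFA block of the scoring configuration.
#' @return A `score_result` (0-100).
#' @export
score_heifa <- function(servings, nutrients, veg_variety, fruit_variety,
                        water_fraction, config = default_score_config()$heifa) {
  if (any(nutrients$energy_kj <= 0))
    stop_domain("HEIFA requires positive total energy for every participant")
  kj <- energy_conversions()
  out <- data.frame(participant_id = servings$participant_id,
                    stringsAsFactors = FALSE)

  cv <- config$vegetable
  out$vegetable <- cv$quantity_max * pmin(group_serves(servings, "vegetable") / cv$target, 1) +
    cv$variety_max * pmin(veg_variety / cv$variety_target, 1)
  cf <- config$fruit
  out$fruit <- cf$quantity_max * pmin(group_serves(servings, "fruit") / cf$target, 1) +
    cf$variety_max * pmin(fruit_variety / cf$variety_target, 1)

  cg <- config$grain
  grain <- group_serves(servings, cg$groups)
  whole <- group_serves(servings, "wholegrain")
  share <- ifelse(grain > 0, whole / grain, 0)
  out$grain <- cg$quantity_max * pmin(grain / cg$target, 1) +
    cg$wholegrain_max * pmin(share / cg$wholegrain_share, 1)

  cd <- config$dairy
  out$dairy <- cd$max_points * pmin(group_serves(servings, cd$groups) / cd$target, 1)
  cm <- config$meat_alternatives
  out$meat_alternatives <-
    cm$max_points * pmin(group_serves(servings, cm$groups) / cm$target, 1)

  cdisc <- config$discretionary
  out$discretionary <- linear_band(group_serves(servings, cdisc$groups),
                                   cdisc$full_at, cdisc$zero_at, cdisc$max_points)

  satfat_pct <- percent_energy(nutrients$sat_fat_g, nutrients$energy_kj, kj[["fat"]])
  out$sat_fat <- linear_band(satfat_pct, config$sat_fat$full_at_pct,
                             config$sat_fat$zero_at_pct, config$sat_fat$max_points)
  sugar_pct <- percent_energy(nutrients$added_sugar_g, nutrients$energy_kj, kj[["carb"]])
  out$added_sugar <- linear_band(sugar_pct, config$added_sugar$full_at_pct,
                                 config$added_sugar$zero_at_pct,
                                 config$added_sugar$max_points)
  out$sodium <- linear_band(nutrients$sodium_mg, config$sodium$full_at_mg,
                            config$sodium$zero_at_mg, config$sodium$max_points)

  cw <- config$water
  out$water <- cw$max_points * pmin(water_fraction / cw$full_fraction, 1)
  ca <- config$alcohol
  out$alcohol <- ifelse(group_serves(servings, ca$groups) <= ca$limit_serves,
                        ca$max_points, 0)
  score_result(out, "heifa", 100)
}

# ---------------------------------------------------------------------------
# Binary screeners: MEDAS (0-14) and erMedDiet (0-17)

criterion_met <- function(value, rule) {
  switch(rule$op,
         ge = value >= rule$threshold,
         gt = value > rule$threshold,
         le = value <= rule$threshold,
         lt = value < rule$threshold,
         true = as.logical(value),
         false = !as.logical(value),
         stop_domain("unknown criterion op '", rule$op, "'"))
}

score_screener <- function(responses, criteria, index, scale_max,
                           strict = TRUE) {
  out <- data.frame(participant_id = responses$participant_id,
                    stringsAsFactors = FALSE)
  for (nm in names(criteria)) {
    if (is.null(responses[[nm]])) {
      if (strict)
        stop_domain(index, ": missing screener criterion '", nm, "'")
      dq_log("%s: criterion '%s' absent; scored 0 (lenient mode)", index, nm)
      out[[nm]] <- 0
      next
    }
    val <- responses[[nm]]
    met <- criterion_met(val, criteria[[nm]])
    if (anyNA(met)) {
      if (strict) {
        bad <- responses$participant_id[which(is.na(met))[1L]]
        stop_domain(index, ": criterion '", nm, "' missing for participant ", bad)
      }
      dq_log("%s: %d missing answer(s) for '%s' scored 0 (lenient mode)",
             index, sum(is.na(met)), nm)
      met[is.na(met)] <- FALSE
    }
    out[[nm]] <- as.numeric(met)
  }
  score_result(out, index, scale_max)
}

#' Mediterranean diet adherence screener (MEDAS, 0-14)
#'
#' Fourteen binary criteria, 1 point each when the adherence criterion is
#' met. Criteria and cut-offs come from the configuration; answers are a data
#' frame with `participant_id` plus one column per criterion (quantities in
#' the unit the criterion name states; habit questions logical).
#'
#' @param responses Screener answer frame.
#' @param strict Error on missing criteria/answers (default); otherwise score
#'   0 with a logged warning.
#' @param config MEDAS block of the scoring configuration.
#' @return A `score_result` (0-14).
#' @export
score_medas <- function(responses, strict = TRUE,
                        config = default_score_config()$medas) {
  score_screener(responses, config$criteria, "medas", 14, strict)
}

#' Energy-restricted Mediterranean screener (erMedDiet, 0-17)
#'
#' Seventeen binary criteria: the MEDAS set restructured (the olive-oil
#' quantity question is dropped) plus whole-grain, white-bread and
#' refined-grain items and a no-added-sugar-in-tea/coffee item.
#'
#' @inheritParams score_medas
#' @param config erMedDiet block of the scoring configuration.
#' @return A `score_result` (0-17).
#' @export
score_ermeddiet <- function(responses, strict = TRUE,
                            config = default_score_config()$ermeddiet) {
  score_screener(responses, config$criteria, "ermeddiet", 17, strict)
}

#' Derive screener answers from quantified FFQ intake
#'
#' Maps day-rate serves onto the MEDAS/erMedDiet screener questions (weekly
#' criteria as day rate x 7). Habit questions that the FFQ cannot answer
#' (olive oil as main fat, sofrito, added sugar in drinks) are taken from
#' the open section / supplied flags.
#'
#' @param servings Wide serves/day frame.
#' @param olive_oil_main_fat Logical vector (from the open section).
#' @param sofrito_per_week Numeric vector.
#' @param added_sugar_in_drinks Logical vector.
#' @return Screener answer frame accepted by [score_medas()] and
#'   [score_ermeddiet()].
#' @export
derive_screener_responses <- function(servings,
                                      olive_oil_main_fat = FALSE,
                                      sofrito_per_week = 0,
                                      added_sugar_in_drinks = FALSE) {
  n <- nrow(servings)
  data.frame(
    participant_id = servings$participant_id,
    olive_oil_main_fat = rep_len(olive_oil_main_fat, n),
    olive_oil_tbsp_day = group_serves(servings, "oil_olive"),
    vegetable_serves_day = group_serves(servings, "vegetable"),
    fruit_serves_day = group_serves(servings, "fruit"),
    red_processed_meat_serves_day =
      group_serves(servings, c("red_meat", "processed_meat")),
    butter_serves_day = group_serves(servings, "butter"),
    ssb_serves_day = group_serves(servings, "ssb"),
    wine_glasses_week = group_serves(servings, "wine") * 7,
    legume_serves_week = group_serves(servings, "legume") * 7,
    fish_serves_week = group_serves(servings, "fish") * 7,
    sweets_serves_week = group_serves(servings, "sweets") * 7,
    nut_serves_week = group_serves(servings, "nut_seed") * 7,
    white_meat_preference = group_serves(servings, "poultry") >
      group_serves(servings, c("red_meat", "processed_meat")),
    sofrito_per_week = rep_len(sofrito_per_week, n),
    whole_grain_serves_day = group_serves(servings, "wholegrain"),
    white_bread_serves_day = group_serves(servings, "white_bread"),
    refined_grain_serves_week = group_serves(servings, "refined_grain") * 7,
    added_sugar_in_drinks = rep_len(added_sugar_in_drinks, n),
    stringsAsFactors = FALSE)
}
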