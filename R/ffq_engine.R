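# FFQ engine: convert semi-quantitative food-frequency responses into
# quantified daily gram, serving, and nutrient intakes via a food-composition
# table (the EPIC/FETA-style computation with Australian-style composition data).

NUTRIENT_COLS <- c("energy_kj", "fat_g", "sat_fat_g", "mufa_g", "pufa_g",
                   "carb_g", "added_sugar_g", "protein_g", "alcohol_g",
                   "sodium_mg", "potassium_mg", "phosphorus_mg")

DENSITY_COLS <- paste0(NUTRIENT_COLS, "_100g")

#' Default 9-point frequency scale
#'
#' Maps the nine FFQ frequency categories ("never or less than once a month"
#' up to "6+ per day") to mean consumption occasions per day. The instrument
#' does not print multipliers, so the conventional EPIC values are used:
#' category 2 ("1-3 per month") is 2 occasions per mean month (30.44 days),
#' weekly categories are occasions/7, and daily categories are taken at their
#' midpoint. Editable: pass your own named vector wherever a `scale` argument
#' is accepted; it must be non-negative and non-decreasing.
#'
#' @return Named numeric vector of length 9 (occasions/day).
#' @export
#' @examples
#' default_frequency_scale()["once_a_week"] # 1/7
default_frequency_scale <- function() {
  c(never_or_less_than_once_month = 0,
    one_to_three_per_month        = 2 / 30.44,
    once_a_week                   = 1 / 7,
    two_to_four_per_week          = 3 / 7,
    five_to_six_per_week          = 5.5 / 7,
    once_a_day                    = 1,
    two_to_three_per_day          = 2.5,
    four_to_five_per_day          = 4.5,
    six_plus_per_day              = 6)
}

check_frequency_scale <- function(scale) {
  if (length(scale) != 9L || !is.numeric(scale) || anyNA(scale))
    stop_domain("frequency scale must be a numeric vector of length 9")
  if (any(scale < 0) || is.unsorted(scale))
    stop_domain("frequency scale must be non-negative and non-decreasing")
  invisible(scale)
}

#' Convert a frequency category to occasions per day
#'
#' @param category Integer vector of frequency categories in 1..9
#'   (1 = never/<1 per month ... 9 = 6+ per day).
#' @param scale Mapping of the 9 categories to occasions/day; see
#'   [default_frequency_scale()].
#' @return Numeric vector of occasions/day.
#' @export
frequency_to_daily <- function(category, scale = default_frequency_scale()) {
  check_frequency_scale(scale)
  category <- as.integer(category)
  if (anyNA(category) || any(category < 1L | category > 9L))
    stop_domain("frequency_category must be an integer in 1..9")
  unname(scale[category])
}

#' Construct and validate a food-composition table
#'
#' @param df Data frame with columns `item_id`, `name`, `tags`
#'   (semicolon-separated food-group labels), `serving_size_g`, optionally
#'   `portion_fraction` (per-item multiplier, default 1), and per-100 g
#'   nutrient densities `energy_kj_100g`, `fat_g_100g`, `sat_fat_g_100g`,
#'   `mufa_g_100g`, `pufa_g_100g`, `carb_g_100g`, `added_sugar_g_100g`,
#'   `protein_g_100g`, `alcohol_g_100g`, `sodium_mg_100g`,
#'   `potassium_mg_100g`, `phosphorus_mg_100g` (missing density columns are
#'   filled with 0).
#' @param provenance Text label recording where the table came from.
#' @return The validated table, class `food_comp_table`.
#' @export
food_composition <- function(df, provenance = "unspecified") {
  required <- c("item_id", "name", "tags", "serving_size_g")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_domain("composition table missing columns: ",
                paste(missing_cols, collapse = ", "))
  df$item_id <- as.character(df$item_id)
  if (anyDuplicated(df$item_id))
    stop_domain("composition table item_ids must be unique")
  if (any(!is.finite(df$serving_size_g) | df$serving_size_g <= 0))
    stop_domain("serving_size_g must be > 0 for every item")
  if (is.null(df$portion_fraction)) df$portion_fraction <- 1
  if (any(!is.finite(df$portion_fraction) | df$portion_fraction <= 0))
    stop_domain("portion_fraction must be > 0")
  for (col in DENSITY_COLS) {
    if (is.null(df[[col]])) df[[col]] <- 0
    if (any(!is.finite(df[[col]]) | df[[col]] < 0))
      stop_domain("nutrient density '", col, "' must be >= 0")
  }
  tag_list <- strsplit(as.character(df$tags), ";", fixed = TRUE)
  tag_list <- lapply(tag_list, function(x) trimws(x[nzchar(trimws(x))]))
  if (any(lengths(tag_list) == 0L))
    stop_domain("every item must carry at least one food-group tag")
  attr(df, "tag_list") <- tag_list
  attr(df, "provenance") <- provenance
  class(df) <- c("food_comp_table", "data.frame")
  df
}

table_tags <- function(table) {
  sort(unique(unlist(attr(table, "tag_list"))))
}

lookup_items <- function(table, item_ids) {
  idx <- match(item_ids, table$item_id)
  if (anyNA(idx)) {
    bad <- unique(item_ids[is.na(idx)])
    stop_domain("item(s) not in composition table: ",
                paste(bad, collapse = ", "))
  }
  idx
}

#' Read / write a food-composition table (CSV)
#'
#' Plain CSV with the documented header (see [food_composition()]).
#' @param path File path.
#' @param table A `food_comp_table`.
#' @param provenance Provenance label attached on read.
#' @return `read_food_composition()` returns a `food_comp_table`.
#' @export
read_food_composition <- function(path, provenance = path) {
  food_composition(utils::read.csv(path, stringsAsFactors = FALSE),
                   provenance = provenance)
}

#' @rdname read_food_composition
#' @export
write_food_composition <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read long-format FFQ responses
#'
#' CSV with columns `participant_id`, `item_id`, `frequency_category` (1..9).
#' Duplicate (participant, item) pairs are an error.
#' @param path File path.
#' @return Data frame of validated responses.
#' @export
read_ffq_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ffq_responses(df)
}

validate_ffq_responses <- function(df) {
  required <- c("participant_id", "item_id", "frequency_category")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_domain("FFQ responses missing columns: ",
                paste(missing_cols, collapse = ", "))
  fc <- df$frequency_category
  if (anyNA(fc) || any(fc != as.integer(fc)) || any(fc < 1 | fc > 9)) {
    bad <- which(is.na(fc) | fc != as.integer(fc) | fc < 1 | fc > 9)[1L]
    stop_domain(sprintf(
      "invalid frequency_category at row %d (participant %s, item %s)",
      bad, df$participant_id[bad], df$item_id[bad]))
  }
  key <- paste(df$participant_id, df$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df[duplicated(key), , drop = FALSE][1L, ]
    stop_domain(sprintf("duplicate FFQ response for participant %s, item %s",
                        bad$participant_id, bad$item_id))
  }
  df
}

#' Default open-section substitution map
#'
#' The FFQ's open section qualifies some responses (type of milk, fat used in
#' cooking). Each qualifier re-points a generic base item to a specific
#' variant item in the composition table, swapping its nutrient densities and
#' group tags.
#' @return Named list: qualifier -> list(base_item, variants = c(value = item_id)).
#' @export
default_open_section_map <- function() {
  list(
    milk_type = list(
      base_item = "milk",
      variants = c(full_cream = "milk_full_cream",
                   reduced_fat = "milk_reduced_fat",
                   skim = "milk_skim")),
    cooking_fat = list(
      base_item = "cooking_fat",
      variants = c(olive_oil = "oil_olive_cooking",
                   vegetable_oil = "oil_vegetable",
                   butter = "butter_cooking"))
  )
}

#' Resolve open-section qualifiers against FFQ responses
#'
#' @param responses Long FFQ response frame.
#' @param open_section Data frame `participant_id`, `qualifier`, `value`.
#' @param table Composition table (variant items must exist in it).
#' @param map Substitution map, see [default_open_section_map()].
#' @return Responses with base item ids replaced by matched variants;
#'   unmatched qualifiers or values are logged and ignored.
#' @export
apply_open_section <- function(responses, open_section, table,
                               map = default_open_section_map()) {
  if (is.null(open_section) || nrow(open_section) == 0L) return(responses)
  for (i in seq_len(nrow(open_section))) {
    q <- as.character(open_section$qualifier[i])
    v <- as.character(open_section$value[i])
    pid <- open_section$participant_id[i]
    entry <- map[[q]]
    if (is.null(entry)) {
      dq_log("open section: unknown qualifier '%s' (participant %s) ignored", q, pid)
      next
    }
    variant <- unname(entry$variants[v])
    if (is.na(variant)) {
      dq_log("open section: unmatched value '%s' for qualifier '%s' (participant %s) ignored",
             v, q, pid)
      next
    }
    if (!variant %in% table$item_id) {
      dq_log("open section: variant item '%s' absent from table (participant %s) ignored",
             variant, pid)
      next
    }
    hit <- responses$participant_id == pid & responses$item_id == entry$base_item
    responses$item_id[hit] <- variant
  }
  responses
}

#' Compute daily gram intake per item
#'
#' grams/day = occasions/day (from the frequency scale) x portion fraction
#' x serving size (g). Items without a response contribute zero (missing
#' responses are treated as no consumption).
#'
#' @param responses Validated long FFQ responses.
#' @param table `food_comp_table`.
#' @param scale Frequency scale, see [default_frequency_scale()].
#' @return Long data frame `participant_id`, `item_id`, `grams_per_day`.
#' @export
compute_gram_intake <- function(responses, table, scale = default_frequency_scale()) {
  responses <- validate_ffq_responses(responses)
  idx <- lookup_items(table, responses$item_id)
  occ <- frequency_to_daily(responses$frequency_category, scale)
  data.frame(
    participant_id = responses$participant_id,
    item_id = responses$item_id,
    grams_per_day = occ * table$portion_fraction[idx] * table$serving_size_g[idx],
    stringsAsFactors = FALSE)
}

# grams long frame -> participants x items matrix (zero-filled)
grams_matrix <- function(grams, table, participants = NULL) {
  participants <- participants %||% sort(unique(grams$participant_id))
  m <- matrix(0, nrow = length(participants), ncol = nrow(table),
              dimnames = list(as.character(participants), table$item_id))
  if (nrow(grams)) {
    ri <- match(as.character(grams$participant_id), rownames(m))
    ci <- lookup_items(table, grams$item_id)
    m[cbind(ri, ci)] <- m[cbind(ri, ci)] + grams$grams_per_day
  }
  m
}

#' Convert gram intakes to food-group servings per day
#'
#' For each food-group tag, serves/day is the sum over items carrying that
#' tag of grams/day divided by the item's serving size. Items with several
#' tags contribute to each.
#'
#' @param grams Long gram-intake frame from [compute_gram_intake()].
#' @inheritParams compute_gram_intake
#' @param participants Optional participant ids to include (zero rows for
#'   participants with no responses).
#' @return Wide data frame: `participant_id` plus one serves/day column per tag.
#' @export
compute_servings <- function(grams, table, participants = NULL) {
  m <- grams_matrix(grams, table, participants)
  serves_per_item <- sweep(m, 2L, table$serving_size_g, "/")
  tags <- table_tags(table)
  tag_list <- attr(table, "tag_list")
  out <- vapply(tags, function(tg) {
    cols <- which(vapply(tag_list, function(x) tg %in% x, logical(1)))
    rowSums(serves_per_item[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(m), tags))
  data.frame(participant_id = rownames(m), out, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compute daily nutrient and energy intake
#'
#' nutrient/day = sum over items of grams/day x density per 100 g / 100.
#' Energy (kJ/day) is the `energy_kj` aggregate.
#'
#' @inheritParams compute_servings
#' @return Wide data frame: `participant_id` plus one column per nutrient
#'   (`energy_kj`, `fat_g`, ..., per day).
#' @export
compute_nutrients <- function(grams, table, participants = NULL) {
  m <- grams_matrix(grams, table, participants)
  dens <- as.matrix(as.data.frame(table)[, DENSITY_COLS]) / 100
  out <- m %*% dens
  colnames(out) <- NUTRIENT_COLS
  data.frame(participant_id = rownames(m), out, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full daily-intake computation
#'
#' Convenience wrapper running gram, serving and nutrient computation.
#'
#' @inheritParams compute_gram_intake
#' @param open_section Optional open-section frame, see [apply_open_section()].
#' @param participants Optional participant ids to force into the output.
#' @return A `daily_intake` list: `grams` (long), `servings` (wide),
#'   `nutrients` (wide, includes `energy_kj`).
#' @export
daily_intake <- function(responses, table, scale = default_frequency_scale(),
                         open_section = NULL, participants = NULL) {
  responses <- apply_open_section(responses, open_section, table)
  grams <- compute_gram_intake(responses, table, scale)
  participants <- participants %||% sort(unique(responses$participant_id))
  structure(
    list(grams = grams,
         servings = compute_servings(grams, table, participants),
         nutrients = compute_nutrients(grams, table, participants)),
    class = "daily_intake")
}

#' Percentage of energy from an energy-yielding nutrient
#'
#' @param grams_per_day Nutrient intake, g/day.
#' @param energy_kj_per_day Total energy intake, kJ/day (> 0).
#' @param kj_per_g Energy conversion factor, kJ per gram (37 for fat).
#' @return Percentage of total energy.
#' @export
percent_energy <- function(grams_per_day, energy_kj_per_day, kj_per_g) {
  if (any(!is.finite(energy_kj_per_day) | energy_kj_per_day <= 0))
    stop_domain("total energy must be > 0 to compute percent of energy")
  100 * grams_per_day * kj_per_g / energy_kj_per_day
}

#' Energy conversion factors (kJ per g)
#'
#' Atwater-style factors: 17 kJ/g carbohydrate and protein, 37 kJ/g fat,
#' 29 kJ/g alcohol. Override by passing a modified vector where accepted.
#' @return Named numeric vector.
#' @export
energy_conversions <- function() {
  c(carb = 17, protein = 17, fat = 37, alcohol = 29)
}

#' Count distinct consumed items within a food group
#'
#' Used by variety sub-scores: an item counts as consumed when its intake
#' reaches `min_g` grams/day.
#' @param grams Long gram-intake frame.
#' @param table Composition table.
#' @param tag Food-group tag.
#' @param min_g Consumption threshold in g/day.
#' @param participants Optional participant ids.
#' @return Data frame `participant_id`, `n_items`.
#' @export
variety_counts <- function(grams, table, tag, min_g = 5, participants = NULL) {
  m <- grams_matrix(grams, table, participants)
  tag_list <- attr(table, "tag_list")
  cols <- which(vapply(tag_list, function(x) tag %in% x, logical(1)))
  n <- rowSums(m[, cols, drop = FALSE] >= min_g)
  data.frame(participant_id = rownames(m), n_items = as.integer(n),
             stringsAsFactors = FALSE, row.names = NULL)
}
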