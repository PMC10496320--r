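# Shared fixtures and independent oracles, built in code at test time.

options(dietquality.quiet = TRUE)

# three-item composition table with hand-auditable numbers
tiny_table <- function() {
  food_composition(data.frame(
    item_id = c("apple", "bread", "cheese"),
    name = c("Apple", "Wholemeal bread", "Cheddar"),
    tags = c("fruit", "wholegrain;high_fibre_grain", "dairy;discretionary"),
    serving_size_g = c(80, 40, 40),
    energy_kj_100g = c(250, 1000, 1700),
    fat_g_100g = c(0.2, 3, 34),
    sat_fat_g_100g = c(0, 0.6, 22),
    carb_g_100g = c(12, 39, 0.2),
    added_sugar_g_100g = c(0, 0, 0),
    protein_g_100g = c(0.3, 10, 25),
    sodium_mg_100g = c(1, 400, 650),
    potassium_mg_100g = c(110, 220, 90),
    phosphorus_mg_100g = c(10, 180, 510),
    stringsAsFactors = FALSE), provenance = "test")
}

# naive independent accumulation: plain loops, no shared code path
naive_intake <- function(responses, table, scale = default_frequency_scale()) {
  grams <- list()
  for (i in seq_len(nrow(responses))) {
    row <- responses[i, ]
    j <- which(table$item_id == row$item_id)
    occ <- scale[[row$frequency_category]]
    g <- occ * table$portion_fraction[j] * table$serving_size_g[j]
    key <- paste(row$participant_id, row$item_id)
    grams[[key]] <- (grams[[key]] %||% 0) + g
  }
  tag_list <- attr(table, "tag_list")
  pids <- unique(responses$participant_id)
  servings <- nutrients <- list()
  for (pid in pids) {
    sv <- list(); nu <- stats::setNames(as.list(rep(0, 12)),
      c("energy_kj", "fat_g", "sat_fat_g", "mufa_g", "pufa_g", "carb_g",
        "added_sugar_g", "protein_g", "alcohol_g", "sodium_mg",
        "potassium_mg", "phosphorus_mg"))
    for (j in seq_len(nrow(table))) {
      g <- grams[[paste(pid, table$item_id[j])]] %||% 0
      for (tg in tag_list[[j]]) sv[[tg]] <- (sv[[tg]] %||% 0) + g / table$serving_size_g[j]
      for (nm in names(nu))
        nu[[nm]] <- nu[[nm]] + g * table[[paste0(nm, "_100g")]][j] / 100
    }
    servings[[pid]] <- sv; nutrients[[pid]] <- nu
  }
  list(grams = grams, servings = servings, nutrients = nutrients)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random-but-reproducible servings frame over the scorer tag vocabulary
random_servings <- function(n, seed) {
  set.seed(seed)
  tags <- c("fruit", "vegetable", "legume", "soy", "nut_seed", "dairy",
            "dairy_lowfat", "red_meat", "processed_meat", "poultry", "fish",
            "egg", "wholegrain", "refined_grain", "high_fibre_grain",
            "white_bread", "sweets", "discretionary", "oil_olive",
            "oil_other", "butter", "ssb", "wine", "alcohol")
  out <- data.frame(participant_id = sprintf("R%02d", seq_len(n)))
  for (tg in tags) out[[tg]] <- round(stats::rexp(n, 1), 3)
  out$dairy_lowfat <- pmin(out$dairy_lowfat, out$dairy)
  out
}

default_energy <- function(n) {
  data.frame(bmr_kj = rep(6000, n), pa_factor = 1.4, eer_kj = 8400,
             dash_level_kcal = 2000)
}
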