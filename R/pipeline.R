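# End-to-end pipeline: cohort file set -> six composites -> association
# analysis tables. These functions are the programmatic surface behind the
# command-line front-end in inst/cli/dietquality.R.

SCORE_COLUMNS <- c("dash", "dash_dairy_adjusted", "vegetarian_lifestyle",
                   "heifa", "medas", "ermeddiet")

check_covariates <- function(covariates) {
  need <- c("participant_id", "age", "sex", "weight_kg", "waist_cm",
            "cvd_risk", "year",
            "vig_work_days", "vig_work_min", "mod_work_days", "mod_work_min",
            "travel_days", "travel_min", "vig_rec_days", "vig_rec_min",
            "mod_rec_days", "mod_rec_min",
            paste0("water_ml_d", 1:3), paste0("beverage_ml_d", 1:3))
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols))
    stop_domain("covariate table missing column(s): ",
                paste(missing_cols, collapse = ", "))
  invisible(covariates)
}

#' Score a cohort: FFQ + covariates -> six diet-quality composites
#'
#' Runs the full scoring chain: daily intake from the FFQ (with open-section
#' resolution), GPAQ MET-minutes and activity class, estimated energy
#' requirement and DASH calorie level, diary water fraction, variety counts,
#' then all six indices. Screener answers for MEDAS/erMedDiet are derived
#' from the quantified intake (weekly criteria as day rate x 7) plus the
#' habit flags in the covariate table.
#'
#' @param ffq Long FFQ response frame (or CSV path).
#' @param covariates Covariate frame (or CSV path); see the generated
#'   `covariates.csv` for the documented header.
#' @param table A `food_comp_table` (or CSV path).
#' @param open_section Optional open-section frame (or CSV path).
#' @param config Scoring configuration.
#' @param strict Error on missing screener answers (default) instead of
#'   scoring 0 with a logged warning.
#' @return List: `composites` (participant_id + six composite columns),
#'   `components` (named list of full `score_result` frames), `energy`,
#'   `activity` (MET-minutes and class), `intake`.
#' @export
score_cohort <- function(ffq, covariates, table, open_section = NULL,
                         config = default_score_config(), strict = TRUE) {
  if (is.character(ffq)) ffq <- read_ffq_responses(ffq)
  if (is.character(covariates))
    covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)
  if (is.character(table)) table <- read_food_composition(table)
  if (is.character(open_section))
    open_section <- utils::read.csv(open_section, stringsAsFactors = FALSE)
  check_covariates(covariates)

  ids <- covariates$participant_id
  orphan <- setdiff(unique(ffq$participant_id), ids)
  if (length(orphan))
    stop_domain("FFQ responses for participant(s) absent from covariates: ",
                paste(utils::head(orphan, 5), collapse = ", "))

  intake <- daily_intake(ffq, table, open_section = open_section,
                         participants = ids)
  dq_log("scored intake: %d participants, %d FFQ rows", length(ids), nrow(ffq))

  met <- gpaq_met_minutes(covariates$vig_work_days, covariates$vig_work_min,
                          covariates$mod_work_days, covariates$mod_work_min,
                          covariates$travel_days, covariates$travel_min,
                          covariates$vig_rec_days, covariates$vig_rec_min,
                          covariates$mod_rec_days, covariates$mod_rec_min)
  activity <- classify_activity(met)
  energy <- estimate_energy(covariates$age, covariates$sex,
                            covariates$weight_kg, activity)
  wf <- water_fraction(
    as.matrix(covariates[, paste0("water_ml_d", 1:3)]),
    as.matrix(covariates[, paste0("beverage_ml_d", 1:3)]))

  veg_var <- variety_counts(intake$grams, table, "vegetable",
                            participants = ids)$n_items
  fruit_var <- variety_counts(intake$grams, table, "fruit",
                              participants = ids)$n_items

  olive_main <- if (!is.null(open_section)) {
    of <- open_section[open_section$qualifier == "cooking_fat", ]
    as.character(of$value[match(ids, of$participant_id)]) %in% "olive_oil"
  } else rep(FALSE, length(ids))

  b12 <- covariates$b12_source %||% rep(TRUE, length(ids))
  sofrito <- covariates$sofrito_per_week %||% rep(0, length(ids))
  sugar_drinks <- covariates$added_sugar_in_drinks %||% rep(FALSE, length(ids))

  screener <- derive_screener_responses(intake$servings, olive_main,
                                        sofrito, sugar_drinks)

  components <- list(
    dash = score_dash(intake$servings, energy, FALSE, config$dash),
    dash_dairy_adjusted = score_dash(intake$servings, energy, TRUE,
                                     config$dash),
    vegetarian_lifestyle = score_vegetarian(intake$servings, energy$eer_kj,
                                            activity, wf, b12,
                                            config = config$vegetarian),
    heifa = score_heifa(intake$servings, intake$nutrients, veg_var, fruit_var,
                        wf, config$heifa),
    medas = score_medas(screener, strict, config$medas),
    ermeddiet = score_ermeddiet(screener, strict, config$ermeddiet))

  composites <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (nm in names(components)) composites[[nm]] <- components[[nm]]$composite

  list(composites = composites, components = components, energy = energy,
       activity = data.frame(participant_id = ids, met_min_week = met,
                             activity = activity),
       intake = intake)
}

#' Assemble the analysis frame
#'
#' One row per participant: the six composites, natural-log hsCRP and PAF
#' (raw Lp-PLA2), and the model covariates. Non-positive biomarker values are
#' rejected; missing values are kept as NA and handled complete-case per
#' model.
#'
#' @param composites Composite frame from [score_cohort()].
#' @param covariates Covariate frame with biomarkers `hscrp_mg_l`,
#'   `paf_ng_ml`, `lppla2_nmol_min_ml`.
#' @param activity Activity frame from [score_cohort()] (or NULL to derive
#'   from GPAQ columns).
#' @return Analysis frame for [fit_model()] and friends.
#' @export
build_analysis_frame <- function(composites, covariates, activity = NULL) {
  if (is.null(activity)) {
    met <- gpaq_met_minutes(covariates$vig_work_days, covariates$vig_work_min,
                            covariates$mod_work_days, covariates$mod_work_min,
                            covariates$travel_days, covariates$travel_min,
                            covariates$vig_rec_days, covariates$vig_rec_min,
                            covariates$mod_rec_days, covariates$mod_rec_min)
    activity <- data.frame(participant_id = covariates$participant_id,
                           activity = classify_activity(met))
  }
  idx <- match(composites$participant_id, covariates$participant_id)
  if (anyNA(idx))
    stop_domain("composites contain participants absent from covariates")
  frame <- data.frame(
    participant_id = composites$participant_id,
    composites[, setdiff(names(composites), "participant_id"), drop = FALSE],
    age = covariates$age[idx],
    gender = covariates$sex[idx],
    year = covariates$year[idx],
    waist_cm = covariates$waist_cm[idx],
    risk = covariates$cvd_risk[idx],
    activity = activity$activity[match(composites$participant_id,
                                       activity$participant_id)],
    stringsAsFactors = FALSE)
  frame$log_hscrp <- log_transform(covariates$hscrp_mg_l[idx],
                                   composites$participant_id)
  frame$log_paf <- log_transform(covariates$paf_ng_ml[idx],
                                 composites$participant_id)
  frame$lppla2 <- covariates$lppla2_nmol_min_ml[idx]
  frame
}

model_fit_row <- function(fit) {
  data.frame(outcome = fit$outcome, score = fit$score,
             model = fit$model_id, n_used = fit$n_used,
             beta_std = fit$beta_std, p_value = fit$p_value,
             exp_beta = fit$exp_beta, pct_change = fit$pct_change,
             vif_max = max(fit$vif), tolerance_min = min(fit$tolerance),
             stringsAsFactors = FALSE)
}

#' Run the full association analysis
#'
#' Produces the four analysis tables: score-score correlations, score-marker
#' correlations, the two adjusted regression models per score x outcome
#' (with exp(beta) and percent change), the year-stratified re-fits for the
#' novel markers (year covariate dropped), and descriptive quartile means.
#'
#' @param frame Analysis frame from [build_analysis_frame()].
#' @param scores Score columns to analyse.
#' @param out_dir Optional directory for the CSV outputs
#'   (`correlations_scores.csv`, `correlations_markers.csv`, `models.csv`,
#'   `models_stratified.csv`, `quartiles.csv`).
#' @return List of the five tables.
#' @export
analyze_scores <- function(frame, scores = intersect(SCORE_COLUMNS, names(frame)),
                           out_dir = NULL) {
  outcomes <- c("log_paf", "lppla2", "log_hscrp")

  cm <- pearson_matrix(frame[, scores, drop = FALSE])
  cor_scores <- do.call(rbind, lapply(seq_along(scores), function(i) {
    do.call(rbind, lapply(seq_len(i - 1L), function(j) {
      data.frame(score_a = scores[j], score_b = scores[i],
                 r = cm$r[i, j], p_value = cm$p[i, j], n = cm$n[i, j],
                 magnitude = cm$magnitude[i, j], stringsAsFactors = FALSE)
    }))
  }))

  cor_markers <- do.call(rbind, lapply(scores, function(sc) {
    do.call(rbind, lapply(outcomes, function(oc) {
      ok <- !is.na(frame[[sc]]) & !is.na(frame[[oc]])
      ct <- stats::cor.test(frame[[sc]][ok], frame[[oc]][ok])
      data.frame(score = sc, outcome = oc, r = unname(ct$estimate),
                 p_value = ct$p.value, n = sum(ok),
                 magnitude = correlation_magnitude(unname(ct$estimate)),
                 stringsAsFactors = FALSE)
    }))
  }))

  models <- do.call(rbind, lapply(outcomes, function(oc) {
    do.call(rbind, lapply(scores, function(sc) {
      do.call(rbind, lapply(1:2, function(m) {
        model_fit_row(fit_model(frame, oc, sc, m))
      }))
    }))
  }))

  strat <- do.call(rbind, lapply(c(2021, 2022), function(yr) {
    sub <- frame[frame$year == yr, , drop = FALSE]
    do.call(rbind, lapply(c("log_paf", "lppla2"), function(oc) {
      do.call(rbind, lapply(scores, function(sc) {
        do.call(rbind, lapply(1:2, function(m) {
          row <- tryCatch(
            model_fit_row(fit_model(sub, oc, sc, m, include_year = FALSE)),
            error = function(e) {
              dq_log("stratified fit skipped (%s, %s, model %d, %d): %s",
                     oc, sc, m, yr, conditionMessage(e))
              NULL
            })
          if (!is.null(row)) row$year <- yr
          row
        }))
      }))
    }))
  }))

  quartiles <- do.call(rbind, lapply(scores, function(sc) {
    do.call(rbind, lapply(c("hscrp" = "log_hscrp", "paf" = "log_paf",
                            "lppla2" = "lppla2"), function(oc) {
      q <- quartile_summary(frame, sc, oc)
      cbind(data.frame(score = sc, outcome = oc, stringsAsFactors = FALSE), q)
    }))
  }))
  rownames(quartiles) <- NULL

  out <- list(cor_scores = cor_scores, cor_markers = cor_markers,
              models = models, models_stratified = strat,
              quartiles = quartiles)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cor_scores, file.path(out_dir, "correlations_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(cor_markers,
                     file.path(out_dir, "correlations_markers.csv"),
                     row.names = FALSE)
    utils::write.csv(models, file.path(out_dir, "models.csv"),
                     row.names = FALSE)
    utils::write.csv(strat, file.path(out_dir, "models_stratified.csv"),
                     row.names = FALSE)
    utils::write.csv(quartiles, file.path(out_dir, "quartiles.csv"),
                     row.names = FALSE)
    dq_log("analysis tables written to %s", out_dir)
  }
  out
}

#' Simulate a cohort file set with a manifest
#'
#' Thin wrapper over [generate_cohort()] that also writes `manifest.yaml`
#' recording the seed and an MD5 hash of the full configuration, so runs are
#' auditable and reproducible.
#'
#' @param out_dir Output directory.
#' @param n,seed,effect_crp,effect_paf Passed to [cohort_config()].
#' @param ... Further [cohort_config()] arguments.
#' @return The generated cohort (invisibly).
#' @export
simulate_cohort <- function(out_dir, n = 100, seed = 1L,
                            effect_crp = -0.35, effect_paf = 0, ...) {
  config <- cohort_config(n = n, seed = seed, effect_crp = effect_crp,
                          effect_paf = effect_paf, ...)
  cohort <- generate_cohort(config, out_dir = out_dir)
  cfg_path <- file.path(out_dir, "cohort_config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(seed = as.integer(seed), n = as.integer(n),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   files = c("ffq.csv", "open_section.csv", "covariates.csv",
                             "food_composition.csv"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(cohort)
}
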