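# Non-FFQ covariate derivation: GPAQ physical activity, anthropometry,
# blood-pressure averaging, diary water fraction, and estimated energy
# requirements with DASH calorie-level assignment.

KJ_PER_KCAL <- 4.184

#' GPAQ MET-minutes per week
#'
#' Aggregates the five GPAQ activity domains using the GPAQ analysis-guide
#' MET weights: 8 for vigorous work and vigorous recreation, 4 for moderate
#' work, travel and moderate recreation. All arguments are days/week (0..7)
#' and minutes/day (0..960); vectors are recycled participant-wise.
#'
#' @param vig_work_days,vig_work_min Vigorous work.
#' @param mod_work_days,mod_work_min Moderate work.
#' @param travel_days,travel_min Walking/cycling for travel.
#' @param vig_rec_days,vig_rec_min Vigorous recreation.
#' @param mod_rec_days,mod_rec_min Moderate recreation.
#' @return MET-minutes/week (numeric vector).
#' @export
gpaq_met_minutes <- function(vig_work_days = 0, vig_work_min = 0,
                             mod_work_days = 0, mod_work_min = 0,
                             travel_days = 0, travel_min = 0,
                             vig_rec_days = 0, vig_rec_min = 0,
                             mod_rec_days = 0, mod_rec_min = 0) {
  days <- cbind(vig_work_days, mod_work_days, travel_days,
                vig_rec_days, mod_rec_days)
  mins <- cbind(vig_work_min, mod_work_min, travel_min,
                vig_rec_min, mod_rec_min)
  if (anyNA(days) || any(days < 0 | days > 7))
    stop_domain("GPAQ days/week must lie in 0..7")
  if (anyNA(mins) || any(mins < 0 | mins > 960))
    stop_domain("GPAQ minutes/day must lie in 0..960")
  weights <- c(8, 4, 4, 8, 4)
  as.numeric((days * mins) %*% weights)
}

#' Classify physical activity from MET-minutes/week
#'
#' WHO cut-offs: 0 = low (< 600), 1 = moderate (>= 600 and < 1500),
#' 2 = high (>= 1500).
#'
#' @param met_min_week Non-negative MET-minutes/week.
#' @return Integer vector in \{0, 1, 2\}.
#' @export
classify_activity <- function(met_min_week) {
  if (anyNA(met_min_week) || any(met_min_week < 0))
    stop_domain("MET-minutes/week must be >= 0")
  ifelse(met_min_week >= 1500, 2L, ifelse(met_min_week >= 600, 1L, 0L))
}

#' Body mass index
#'
#' @param weight_kg Weight in kg (> 0).
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) {
  if (anyNA(weight_kg) || anyNA(height_m) || any(weight_kg <= 0) || any(height_m <= 0))
    stop_domain("weight and height must be > 0")
  weight_kg / height_m^2
}

#' Average triplicate blood-pressure readings
#'
#' The first reading is discarded; the second and third are averaged,
#' componentwise.
#'
#' @param sbp,dbp Systolic/diastolic readings: length-3 vectors (one
#'   participant) or n x 3 matrices in measurement order.
#' @return Data frame with columns `sbp` and `dbp` (one row per participant).
#' @export
mean_blood_pressure <- function(sbp, dbp) {
  to_mat <- function(x, name) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    if (ncol(x) != 3L)
      stop_domain("exactly 3 ", name, " readings are required per participant")
    x
  }
  sbp <- to_mat(sbp, "systolic"); dbp <- to_mat(dbp, "diastolic")
  if (nrow(sbp) != nrow(dbp))
    stop_domain("systolic and diastolic reading counts differ")
  data.frame(sbp = rowMeans(sbp[, 2:3, drop = FALSE]),
             dbp = rowMeans(dbp[, 2:3, drop = FALSE]))
}

#' Schofield basal metabolic rate
#'
#' Age/sex-banded Schofield weight equations, returned in kJ/day.
#'
#' @param age Years (10+ supported).
#' @param sex "male"/"female" (or "M"/"F").
#' @param weight_kg Body weight in kg.
#' @return BMR, kJ/day.
#' @export
schofield_bmr <- function(age, sex, weight_kg) {
  sex <- tolower(substr(as.character(sex), 1, 1))
  if (anyNA(age) || anyNA(weight_kg) || any(age <= 0) || any(weight_kg <= 0) ||
      !all(sex %in% c("m", "f")))
    stop_domain("estimate_energy needs valid age, sex and weight")
  band <- findInterval(age, c(10, 18, 30, 60))  # 1:10-17, 2:18-29, 3:30-59, 4:60+
  if (any(band < 1))
    stop_domain("Schofield equations implemented for ages 10 and over")
  male_coef   <- rbind(c(0.074, 2.754), c(0.063, 2.896),
                       c(0.048, 3.653), c(0.049, 2.459))
  female_coef <- rbind(c(0.056, 2.898), c(0.062, 2.036),
                       c(0.034, 3.538), c(0.038, 2.755))
  coef <- ifelse(sex == "m", male_coef[band, 1], female_coef[band, 1])
  icpt <- ifelse(sex == "m", male_coef[band, 2], female_coef[band, 2])
  (coef * weight_kg + icpt) * 1000  # MJ/day -> kJ/day
}

#' Estimated energy requirement and DASH calorie-level assignment
#'
#' EER = BMR (Schofield) x physical-activity factor, then assigned the
#' nearest of the four DASH plan energy levels (1600, 2000, 2600, 3100 kcal,
#' compared on the kJ scale). An exact midpoint resolves to the lower level.
#'
#' @param age,sex,weight_kg Demographics (see [schofield_bmr()]).
#' @param activity_category GPAQ activity class 0/1/2 from [classify_activity()].
#' @param pa_factors Activity factors for categories 0/1/2.
#' @param levels_kcal Admissible DASH plan energy levels.
#' @return Data frame: `bmr_kj`, `pa_factor`, `eer_kj`, `dash_level_kcal`.
#' @export
estimate_energy <- function(age, sex, weight_kg, activity_category,
                            pa_factors = c(1.4, 1.6, 1.8),
                            levels_kcal = c(1600, 2000, 2600, 3100)) {
  if (anyNA(activity_category) || !all(activity_category %in% 0:2))
    stop_domain("activity_category must be 0, 1 or 2")
  bmr <- schofield_bmr(age, sex, weight_kg)
  pa <- pa_factors[activity_category + 1L]
  eer <- bmr * pa
  data.frame(bmr_kj = bmr, pa_factor = pa, eer_kj = eer,
             dash_level_kcal = assign_dash_level(eer, levels_kcal))
}

#' Assign the nearest DASH plan energy level
#'
#' Levels are compared on the kJ scale; an exact midpoint (to within
#' numerical tolerance) resolves to the lower level. Requirements beyond the
#' extreme levels clamp to the nearest extreme.
#'
#' @param eer_kj Estimated energy requirement(s), kJ/day.
#' @param levels_kcal Admissible plan levels.
#' @return Assigned level(s) in kcal.
#' @export
assign_dash_level <- function(eer_kj, levels_kcal = c(1600, 2000, 2600, 3100)) {
  if (anyNA(eer_kj) || any(eer_kj <= 0))
    stop_domain("eer_kj must be > 0")
  levels_kcal <- sort(levels_kcal)
  levels_kj <- levels_kcal * KJ_PER_KCAL
  vapply(eer_kj, function(e) {
    d <- abs(levels_kj - e)
    levels_kcal[which(d <= min(d) + 1e-9)[1L]]  # tie -> lower level
  }, numeric(1))
}

#' Diary water fraction
#'
#' Mean daily water intake divided by mean daily total beverage intake over
#' the (up to 3) diary days.
#'
#' @param water_ml,total_ml Daily volumes: vectors (one participant) or
#'   n x days matrices. Missing days may be NA but at least one day with
#'   total beverages > 0 is required per participant.
#' @return Water fraction in [0, 1] per participant.
#' @export
water_fraction <- function(water_ml, total_ml) {
  if (is.null(dim(water_ml))) water_ml <- matrix(water_ml, nrow = 1L)
  if (is.null(dim(total_ml))) total_ml <- matrix(total_ml, nrow = 1L)
  if (!identical(dim(water_ml), dim(total_ml)))
    stop_domain("water and total beverage diaries must have the same shape")
  if (any(water_ml < 0, na.rm = TRUE) || any(total_ml < 0, na.rm = TRUE))
    stop_domain("diary volumes must be >= 0")
  if (any(water_ml > total_ml, na.rm = TRUE))
    stop_domain("daily water cannot exceed total beverages")
  mw <- rowMeans(water_ml, na.rm = TRUE)
  mt <- rowMeans(total_ml, na.rm = TRUE)
  if (any(!is.finite(mt) | mt <= 0))
    stop_domain("each participant needs >= 1 diary day with total beverages > 0")
  as.numeric(mw / mt)
}
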