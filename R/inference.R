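# Statistical pipeline: transformations, group comparisons, Pearson
# correlation matrices with magnitude labels, the two covariate-adjusted
# standardised-coefficient regression models with VIF/tolerance diagnostics
# and exponentiated-coefficient back-transformation, quartile summaries, and
# the Pearson-correlation power computation.

#' Natural-log transform positive biomarker concentrations
#'
#' Right-skewed biomarkers (hsCRP, PAF) are log transformed before analysis.
#' Natural logs are used so that exponentiating a fitted coefficient recovers
#' the multiplicative effect on the raw scale. Missing values pass through.
#'
#' @param values Positive concentrations (NA allowed).
#' @param ids Optional participant ids used in error messages.
#' @return Natural-log values.
#' @export
log_transform <- function(values, ids = NULL) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    who <- if (is.null(ids)) paste("position", bad[1L]) else
      paste("participant", ids[bad[1L]])
    stop_domain("log transform requires positive values (", who,
                " has value ", values[bad[1L]], ")")
  }
  log(values)
}

#' Two-group comparison
#'
#' Independent t-test for variables flagged as normally distributed,
#' Mann-Whitney U (Wilcoxon rank-sum) otherwise; two-sided.
#'
#' @param values Numeric vector.
#' @param groups Binary grouping (factor/character/logical), two levels.
#' @param normal Is the variable normally distributed?
#' @return List: `statistic`, `p_value`, `method`, group `n`.
#' @export
group_compare <- function(values, groups, normal = FALSE) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.factor(as.character(groups[keep]))
  if (nlevels(groups) != 2L || any(table(groups) == 0L))
    stop_domain("group_compare needs exactly two non-empty groups")
  x <- values[groups == levels(groups)[1L]]
  y <- values[groups == levels(groups)[2L]]
  res <- if (normal) stats::t.test(x, y) else
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = if (normal) "t_test" else "mann_whitney",
       n = c(length(x), length(y)))
}

#' Correlation magnitude label
#'
#' Cohen-style bands: 0.10-0.29 small, 0.30-0.50 medium, 0.51-1 large
#' (on |r|); below 0.10 "negligible".
#'
#' @param r Correlation coefficient(s).
#' @return Character vector of labels.
#' @export
correlation_magnitude <- function(r) {
  a <- abs(r)
  out <- rep(NA_character_, length(r))
  out[!is.na(a) & a < 0.10] <- "negligible"
  out[!is.na(a) & a >= 0.10 & a < 0.30] <- "small"
  out[!is.na(a) & a >= 0.30 & a <= 0.50] <- "medium"
  out[!is.na(a) & a > 0.50] <- "large"
  out
}

#' Pairwise Pearson correlation matrix with p-values and magnitude labels
#'
#' Pairwise-complete Pearson correlations between every pair of columns;
#' symmetric with unit diagonal. A constant column yields NA (flagged), never
#' a silent zero.
#'
#' @param df Data frame of numeric variables (a `participant_id` column is
#'   ignored).
#' @param min_pairs Minimum complete pairs per cell.
#' @return List of matrices `r`, `p`, `n`, and character matrix `magnitude`.
#' @export
pearson_matrix <- function(df, min_pairs = 3L) {
  df <- df[, setdiff(names(df), "participant_id"), drop = FALSE]
  vars <- names(df)
  k <- length(vars)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    n[i, i] <- sum(!is.na(df[[i]]))
    for (j in seq_len(k)) {
      if (j >= i) next
      ok <- !is.na(df[[i]]) & !is.na(df[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < min_pairs) next
      if (stats::sd(df[[i]][ok]) == 0 || stats::sd(df[[j]][ok]) == 0) {
        dq_log("pearson_matrix: constant column in pair (%s, %s); r undefined",
               vars[i], vars[j])
        next
      }
      ct <- stats::cor.test(df[[i]][ok], df[[j]][ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  mag <- matrix(correlation_magnitude(r), k, k, dimnames = list(vars, vars))
  list(r = r, p = p, n = n, magnitude = mag)
}

#' Automated normality assessment
#'
#' Shapiro-Wilk at alpha = 0.05 as the automatable stand-in for visual Q-Q
#' inspection; used to route [group_compare()] and to decide which biomarkers
#' are log transformed in automated runs.
#'
#' @param values Numeric vector (NA dropped).
#' @param alpha Significance level.
#' @return Logical: consistent with normality?
#' @export
assess_normality <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 4L || stats::sd(values) == 0) return(NA)
  stats::shapiro.test(values)$p.value >= alpha
}

# ---------------------------------------------------------------------------
# Regression models

# VIF: diagonal of the inverse correlation matrix of the (non-constant)
# design columns; tolerance is its reciprocal.
design_vif <- function(X) {
  X <- X[, apply(X, 2L, stats::sd) > 0, drop = FALSE]
  if (ncol(X) < 2L) {
    v <- rep(1, ncol(X)); names(v) <- colnames(X); return(v)
  }
  R <- stats::cor(X)
  diag(solve(R))
}

MODEL_COVARIATES <- list(
  `1` = c("age", "gender", "year"),
  `2` = c("age", "gender", "year", "waist_cm", "activity", "risk")
)

#' Fit a diet-score / biomarker regression model
#'
#' Ordinary least squares of a (log-transformed where flagged) biomarker on
#' one diet score plus covariates. Model 1 adjusts for age, gender and year
#' of data collection; model 2 additionally for waist circumference,
#' physical activity (ordinal tertile) and CVD risk class. Models of the
#' Vegetarian Lifestyle Index omit physical activity from model 2 because
#' activity is a component of that score. The outcome and continuous
#' predictors (score, age, waist) are z-scored, so the reported coefficient
#' for the score is a standardised beta; binary covariates enter as 0/1
#' indicators. Rows with any missing model variable are dropped
#' (complete-case).
#'
#' @param frame Analysis frame: one row per participant with the score
#'   column, the outcome column, and covariates `age`, `gender`
#'   ("male"/"female"), `year` (2021/2022), `waist_cm`, `activity` (0/1/2),
#'   `risk` ("high"/"low").
#' @param outcome Outcome column name (e.g. `"log_hscrp"`).
#' @param score Diet-score column name.
#' @param model_id 1 or 2.
#' @param include_year Keep the year covariate (dropped in year-stratified
#'   re-fits).
#' @param exclude_activity Omit the activity covariate; defaults to TRUE for
#'   the Vegetarian Lifestyle Index score columns.
#' @return A `model_fit` list: `outcome`, `score`, `model_id`, `beta_std`,
#'   `se`, `p_value`, `ci95`, `exp_beta`, `pct_change`, `n_used`, `vif`,
#'   `tolerance`, and the underlying `lm` fit.
#' @export
fit_model <- function(frame, outcome, score, model_id = 1,
                      include_year = TRUE,
                      exclude_activity = grepl("vegetarian", score)) {
  model_id <- as.character(model_id)
  if (!model_id %in% names(MODEL_COVARIATES))
    stop_domain("model_id must be 1 or 2")
  covars <- MODEL_COVARIATES[[model_id]]
  if (!include_year) covars <- setdiff(covars, "year")
  if (exclude_activity) covars <- setdiff(covars, "activity")
  covars <- intersect(covars, names(frame))
  need <- c(outcome, score, covars)
  missing_cols <- setdiff(need, names(frame))
  if (length(missing_cols))
    stop_domain("analysis frame missing column(s): ",
                paste(missing_cols, collapse = ", "))

  d <- frame[, need, drop = FALSE]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < length(need) + 2L)
    stop_domain("too few complete cases (", n, ") to fit the model")

  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  X <- data.frame(score = zscore(d[[score]]))
  for (cv in covars) {
    X[[cv]] <- switch(cv,
      age = zscore(d$age),
      waist_cm = zscore(d$waist_cm),
      gender = as.numeric(tolower(substr(as.character(d$gender), 1, 1)) == "f"),
      year = as.numeric(as.numeric(as.character(d$year)) == 2022),
      risk = as.numeric(tolower(as.character(d$risk)) == "high"),
      activity = as.numeric(d$activity))
  }
  y <- zscore(d[[outcome]])

  Xm <- as.matrix(X)
  qrX <- qr(cbind(1, Xm))
  if (qrX$rank < ncol(Xm) + 1L) {
    piv <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(Xm), colnames(Xm)[piv[piv > 1L] - 1L])
    stop_domain("rank-deficient design; collinear column(s): ",
                paste(dropped, collapse = ", "))
  }

  fit <- stats::lm(y ~ ., data = X)
  cf <- summary(fit)$coefficients
  beta <- cf["score", "Estimate"]
  se <- cf["score", "Std. Error"]
  pval <- cf["score", "Pr(>|t|)"]
  bt <- back_transform(beta)
  vif <- design_vif(Xm)
  structure(
    list(outcome = outcome, score = score, model_id = as.integer(model_id),
         beta_std = beta, se = se, p_value = pval,
         ci95 = beta + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se,
         exp_beta = bt$exp_beta, pct_change = bt$pct_change,
         n_used = n, vif = vif, tolerance = 1 / vif, fit = fit),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "<model %d: %s ~ %s> n = %d, beta_std = %.3f (p = %.3g), exp(beta) = %.3f (%+.1f%%)\n",
    x$model_id, x$outcome, x$score, x$n_used, x$beta_std, x$p_value,
    x$exp_beta, -x$pct_change))
  invisible(x)
}

#' Back-transform a coefficient from a natural-log outcome model
#'
#' `exp_beta = exp(beta)`; `pct_change = 100 * (1 - exp(beta))` is read as
#' the percent decrease in the raw-scale biomarker per one-point increase in
#' the diet score (a back-transformed value of 0.70 means a 30% decrease).
#' Rounding happens only at presentation.
#'
#' @param beta Finite coefficient(s) from a model with natural-log outcome.
#' @return List: `exp_beta`, `pct_change`.
#' @export
back_transform <- function(beta) {
  if (anyNA(beta) || any(!is.finite(beta)))
    stop_domain("back_transform requires finite coefficients")
  eb <- exp(beta)
  list(exp_beta = eb, pct_change = 100 * (1 - eb))
}

#' Mean biomarker per diet-score quartile
#'
#' Descriptive only (excluded from modelling): participants are binned at the
#' 25/50/75 rank percentiles of the score (boundary values fall in the lower
#' bin) and the biomarker mean is reported per bin. With fewer than four
#' distinct score values, fewer bins are returned with a warning.
#'
#' @param frame Analysis frame.
#' @param score,marker Column names.
#' @return Data frame: `quartile`, `n`, `score_range`, `marker_mean`.
#' @export
quartile_summary <- function(frame, score, marker) {
  d <- frame[!is.na(frame[[score]]) & !is.na(frame[[marker]]), c(score, marker)]
  s <- d[[score]]
  if (length(unique(s)) < 4L)
    warning("fewer than 4 distinct score values; returning fewer bins",
            call. = FALSE)
  cuts <- unique(stats::quantile(s, c(0.25, 0.5, 0.75), type = 7))
  q <- findInterval(s, cuts, left.open = TRUE) + 1L  # boundaries -> lower bin
  out <- do.call(rbind, lapply(sort(unique(q)), function(k) {
    data.frame(quartile = k, n = sum(q == k),
               score_min = min(s[q == k]), score_max = max(s[q == k]),
               marker_mean = mean(d[[marker]][q == k]))
  }))
  rownames(out) <- NULL
  out
}

#' Power of the two-sided Pearson correlation test
#'
#' Either the Fisher-z normal approximation (atanh(r) with standard error
#' 1/sqrt(n-3)) or Monte-Carlo simulation drawing bivariate normal samples
#' and counting two-sided rejections of `cor.test()`.
#'
#' @param n Sample size (>= 4).
#' @param rho True correlation, 0 < |rho| < 1.
#' @param alpha Significance level in (0, 1).
#' @param method `"fisher_z"` or `"simulation"`.
#' @param reps Simulation replicates.
#' @param seed Seed for the simulation method.
#' @return Power in `[0, 1]`.
#' @export
power_pearson <- function(n, rho, alpha = 0.05,
                          method = c("fisher_z", "simulation"),
                          reps = 10000L, seed = NULL) {
  method <- match.arg(method)
  check_scalar(n, "n"); check_scalar(rho, "rho"); check_scalar(alpha, "alpha")
  if (n < 4) stop_domain("n must be >= 4")
  if (abs(rho) >= 1 || rho == 0) stop_domain("rho must satisfy 0 < |rho| < 1")
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must lie in (0, 1)")
  if (method == "fisher_z") {
    delta <- atanh(rho) * sqrt(n - 3)
    zc <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(-zc - delta) + stats::pnorm(-zc + delta)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rej <- vapply(seq_len(reps), function(i) {
      x <- stats::rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
      stats::cor.test(x, y)$p.value < alpha
    }, logical(1))
    mean(rej)
  }
}
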