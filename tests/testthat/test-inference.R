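test_that("log transform is natural log, passes NA, rejects non-positive", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(exp(1)), 1)
  x <- rlnorm(50)
  expect_equal(exp(log_transform(x)), x, tolerance = 1e-12)
  expect_equal(log_transform(c(2, NA, 4)), c(log(2), NA, log(4)))
  expect_error(log_transform(c(1, 0), ids = c("P1", "P2")), "P2")
})

test_that("group comparison routes to t-test or Mann-Whitney", {
  g <- rep(c("a", "b"), each = 6)
  same <- rep(c(1, 2, 3, 4, 5, 6), 2)
  mw <- group_compare(same, g, normal = FALSE)
  expect_equal(mw$method, "mann_whitney")
  expect_gt(mw$p_value, 0.9)

  set.seed(1)
  far <- c(rnorm(50), rnorm(50, 5))
  gg <- rep(c("lo", "hi"), each = 50)
  expect_lt(group_compare(far, gg, normal = TRUE)$p_value, 0.001)
  expect_lt(group_compare(far, gg, normal = FALSE)$p_value, 0.001)

  # 10-point fixture vs hand-computed Welch t statistic
  x <- c(4.1, 5.2, 3.8, 6.0, 4.9); y <- c(7.3, 6.8, 8.1, 7.7, 6.9)
  tt <- group_compare(c(x, y), rep(c("x", "y"), each = 5), normal = TRUE)
  welch <- (mean(x) - mean(y)) / sqrt(var(x) / 5 + var(y) / 5)
  expect_equal(tt$statistic, welch, tolerance = 1e-12)
  # and the Mann-Whitney U from explicit pair counting
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(group_compare(c(x, y), rep(c("x", "y"), each = 5))$statistic, u)
  expect_error(group_compare(x, rep("x", 5)), "two non-empty")
})

test_that("pearson matrix: symmetry, unit diagonal, magnitude labels", {
  set.seed(7)
  d <- data.frame(a = rnorm(40))
  d$b <- -d$a
  d$c <- d$a + rnorm(40, 0, 2)
  d$const <- 1
  pm <- pearson_matrix(d)
  expect_equal(pm$r["a", "a"], 1)
  expect_equal(pm$r["a", "b"], -1, tolerance = 1e-12)
  expect_equal(pm$r, t(pm$r))
  expect_true(all(is.na(pm$r["const", c("a", "b", "c")])))  # flagged, not 0
  expect_equal(correlation_magnitude(c(0.05, 0.124, 0.3, 0.5, 0.800, -0.365)),
               c("negligible", "small", "medium", "medium", "large", "medium"))
})

test_that("standardised model: identity, invariances, VIF diagnostics", {
  set.seed(11)
  n <- 80
  frame <- data.frame(participant_id = seq_len(n), y = rnorm(n))
  frame$s <- frame$y  # score identical to outcome, no covariates present
  # perfect fit by construction; lm flags the zero-residual summary
  fit <- suppressWarnings(fit_model(frame, "y", "s", 1))
  expect_equal(fit$beta_std, 1, tolerance = 1e-12)
  expect_equal(fit$n_used, n)

  frame2 <- data.frame(
    participant_id = seq_len(n), s = rnorm(n), age = runif(n, 20, 69),
    gender = sample(c("male", "female"), n, TRUE),
    year = sample(c(2021, 2022), n, TRUE), waist_cm = rnorm(n, 95, 12),
    activity = sample(0:2, n, TRUE), risk = sample(c("high", "low"), n, TRUE))
  frame2$y <- -0.4 * scale(frame2$s)[, 1] + rnorm(n, 0, 0.8)

  f1 <- fit_model(frame2, "y", "s", 2, exclude_activity = FALSE)
  rescaled <- frame2; rescaled$s <- rescaled$s * 1000; rescaled$age <- rescaled$age / 10
  f2 <- fit_model(rescaled, "y", "s", 2, exclude_activity = FALSE)
  expect_equal(f1$beta_std, f2$beta_std, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)

  shuffled <- frame2[sample(n), ]
  f3 <- fit_model(shuffled, "y", "s", 2, exclude_activity = FALSE)
  expect_equal(f1$beta_std, f3$beta_std, tolerance = 1e-12)

  expect_true(all(f1$vif >= 1))
  expect_equal(f1$vif * f1$tolerance, rep(1, length(f1$vif)),
               ignore_attr = TRUE)
  expect_equal(f1$exp_beta, exp(f1$beta_std), tolerance = 1e-15)

  # collinear design fails loudly
  degenerate <- frame2; degenerate$waist_cm <- degenerate$age * 2
  expect_error(fit_model(degenerate, "y", "s", 2, exclude_activity = FALSE),
               "collinear")
  expect_error(fit_model(frame2, "y", "s", 3), "model_id")
})

test_that("VIF matches the car reference implementation", {
  skip_if_not_installed("car")
  set.seed(13)
  n <- 120
  frame <- data.frame(
    participant_id = seq_len(n), s = rnorm(n), age = rnorm(n, 50, 12),
    gender = sample(c("male", "female"), n, TRUE),
    year = sample(c(2021, 2022), n, TRUE),
    waist_cm = rnorm(n, 95, 12), activity = sample(0:2, n, TRUE),
    risk = sample(c("high", "low"), n, TRUE))
  frame$waist_cm <- frame$waist_cm + 5 * scale(frame$age)[, 1]
  frame$y <- rnorm(n)
  fit <- fit_model(frame, "y", "s", 2, exclude_activity = FALSE)
  ref <- stats::lm(y ~ scale(s) + scale(age) + I(gender == "female") +
                     I(year == 2022) + scale(waist_cm) + activity +
                     I(risk == "high"), data = frame)
  expect_equal(unname(fit$vif),
               unname(car::vif(ref)), tolerance = 1e-8)
})

test_that("fit_model recovers a configured standardised effect (oracle frames)", {
  set.seed(17)
  reps <- 60; n <- 100; eff <- -0.35
  est <- replicate(reps, {
    s <- rnorm(n)
    frame <- data.frame(
      participant_id = seq_len(n), s = s, age = rnorm(n, 50, 12),
      gender = sample(c("male", "female"), n, TRUE),
      year = sample(c(2021, 2022), n, TRUE))
    frame$y <- eff * scale(s)[, 1] + sqrt(1 - eff^2) * rnorm(n)
    fit_model(frame, "y", "s", 1)$beta_std
  })
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - eff), 3 * mc_se + 0.005)
})

test_that("back transformation: identity at zero, printed-value convention", {
  bt <- back_transform(0)
  expect_equal(bt$exp_beta, 1)
  expect_equal(bt$pct_change, 0)
  expect_equal(round(back_transform(-0.352)$exp_beta, 3), 0.703)
  expect_equal(round(back_transform(-0.352)$pct_change), 30)
  expect_equal(round(back_transform(-0.394)$pct_change), 33)
  expect_error(back_transform(Inf), "finite")
  # log-then-exponentiate round trip: zero coefficient = exactly no change
  expect_equal(back_transform(log(1))$pct_change, 0)
})

test_that("quartile summary bins at rank percentiles, boundaries to lower bin", {
  frame <- data.frame(s = 1:8, m = seq(10, 80, by = 10))
  q <- quartile_summary(frame, "s", "m")
  expect_equal(q$quartile, 1:4)
  expect_equal(q$n, rep(2L, 4))
  expect_equal(q$marker_mean, c(15, 35, 55, 75))

  flat <- data.frame(s = rnorm(40), m = rep(3.3, 40))
  expect_equal(unique(quartile_summary(flat, "s", "m")$marker_mean), 3.3)

  mono <- data.frame(s = 1:40, m = (1:40)^2)
  expect_false(is.unsorted(quartile_summary(mono, "s", "m")$marker_mean))

  few <- data.frame(s = rep(1:2, 10), m = rnorm(20))
  expect_warning(quartile_summary(few, "s", "m"), "distinct")
})

test_that("Pearson power: approximation, simulation and monotonicity", {
  # closed form at the design point
  expect_gte(power_pearson(100, 0.3, 0.05), 0.80)
  # null limit: power approaches alpha as rho -> 0
  expect_equal(power_pearson(100, 1e-6, 0.05), 0.05, tolerance = 1e-3)
  # monotone in n and |rho|
  pw_n <- sapply(c(20, 50, 100, 200), power_pearson, rho = 0.3)
  expect_false(is.unsorted(pw_n))
  pw_r <- sapply(c(0.1, 0.2, 0.3, 0.5), function(r) power_pearson(80, r))
  expect_false(is.unsorted(pw_r))
  # simulation agrees with the approximation within 2 Monte-Carlo SE
  reps <- 4000
  sim <- power_pearson(100, 0.3, 0.05, method = "simulation",
                       reps = reps, seed = 42)
  fz <- power_pearson(100, 0.3, 0.05)
  expect_lt(abs(sim - fz), 2 * sqrt(fz * (1 - fz) / reps) + 0.01)
  expect_error(power_pearson(3, 0.3), "n")
  expect_error(power_pearson(100, 0), "rho")
  expect_error(power_pearson(100, 0.3, 1.2), "alpha")
})

test_that("normality assessment separates skewed from Gaussian samples", {
  set.seed(23)
  expect_true(assess_normality(rnorm(100)))
  expect_false(assess_normality(rlnorm(100, sdlog = 1.1)))
  expect_true(is.na(assess_normality(rep(1, 10))))
})
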