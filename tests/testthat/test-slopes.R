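test_that("representative metric is the oriented mean of item z-scores", {
  cat <- feature_catalog()
  sessions <- data.frame(participant_id = "P1",
                         diet_quality = c(3, 4, 5, 6, 7),
                         fruit_veg_servings = c(2, 2, 4, 6, 6),
                         sugar_intake = c(7, 6, 5, 4, 3))
  # single-item domain behaves like the oriented z-score of that item
  single <- feature_catalog(data.frame(
    feature = "diet_quality", domain = "diet", source = "ema",
    aggregation = "last_value", orientation = 1))
  m1 <- representative_metric(sessions, single, "diet")
  expect_equal(m1, as.numeric(scale(sessions$diet_quality)))
  # orientation -1 flips a rising series into a falling metric
  neg <- feature_catalog(data.frame(
    feature = "sugar_intake", domain = "diet", source = "ema",
    aggregation = "last_value", orientation = -1))
  m2 <- representative_metric(sessions, neg,
                              "diet")
  expect_true(all(diff(m2) < 0) == FALSE)  # sugar falls, so metric rises
  expect_equal(m2, as.numeric(-scale(sessions$sugar_intake)))
  # two-item domain: hand-computed oriented mean
  two <- feature_catalog(data.frame(
    feature = c("diet_quality", "sugar_intake"),
    domain = "diet", source = "ema", aggregation = "last_value",
    orientation = c(1, -1)))
  m3 <- representative_metric(sessions, two, "diet")
  hand <- (as.numeric(scale(sessions$diet_quality)) +
             -as.numeric(scale(sessions$sugar_intake))) / 2
  expect_equal(m3, hand, tolerance = 1e-12)
  expect_error(representative_metric(sessions, two, "sleep"), "no catalog")
})

test_that("phase-1 z-scoring matches the definition value by value", {
  expect_equal(phase_z(4, c(2, 4, 6)), 0)
  expect_equal(phase_z(6, c(2, 6)), 1 * (6 - 4) / sd(c(2, 6)))
  b <- c(2, 4, 6)  # mean 4, sd 2
  expect_equal(phase_z(6, b), 1)
  x <- rnorm(20, 5, 2)
  z <- phase_z(x, b)
  for (i in seq_along(x)) expect_equal(z[i], (x[i] - 4) / 2)
  expect_error(phase_z(1, c(3, 3, 3), name = "mood"), "mood")
})

test_that("slope fitting matches the closed-form OLS oracle", {
  s <- 0:19
  expect_equal(z_slope(0.1 * s, s), 0.1)
  expect_equal(z_slope(rep(0.3, 20), s), 0)
  set.seed(44)
  y <- 0.05 * s + rnorm(20, 0, 0.3)
  expect_equal(z_slope(y, s), oracle_ols_slope(s, y), tolerance = 1e-10)
  expect_true(is.na(z_slope(c(1, 2))))
})

test_that("falling depressed-mood ratings give a positive (alleviation) mood slope", {
  ema <- toy_two_phase_ema(
    n1 = 20, n2 = 15,
    mood_fun = function(i, tp) {
      base <- round(4 + sin(i / 3))
      ifelse(tp == "intervention", pmax(base - (i - 20) %/% 5, 1), base)
    },
    item_funs = list(
      sleep_quality = function(i, tp) round(4 + cos(i / 4)),
      exercise_minutes = function(i, tp) round(4 + sin(i / 5)),
      diet_quality = function(i, tp) round(4 + cos(i / 6)),
      social_quality = function(i, tp) round(4 + sin(i / 7))))
  sl <- participant_slopes(ema, "sleep", feature_catalog())
  expect_gt(sl$mood_slope, 0)
  expect_false(sl$excluded)
  expect_equal(sl$n_phase2_emas, 15)
})

test_that("participants with too few phase-2 EMAs are flagged excluded", {
  ema <- toy_two_phase_ema(
    n1 = 10, n2 = 2,
    mood_fun = function(i, tp) round(4 + sin(i)),
    item_funs = list(sleep_quality = function(i, tp) round(4 + cos(i)),
                     exercise_minutes = function(i, tp) round(4 + sin(i / 2)),
                     diet_quality = function(i, tp) round(4 + cos(i / 2)),
                     social_quality = function(i, tp) round(4 + sin(i / 3))))
  sl <- participant_slopes(ema, "diet", feature_catalog())
  expect_true(sl$excluded)
  expect_true(is.na(sl$mood_slope))
})

make_slope_frame <- function(n = 30, seed = 1,
                             mood_fun = function(tgt, off, e) tgt + e) {
  set.seed(seed)
  tgt <- rnorm(n, 0.03, 0.02)
  off <- rnorm(n, 0, 0.02)
  data.frame(participant_id = sprintf("P%02d", 1:n),
             mood_slope = mood_fun(tgt, off, rnorm(n, 0, 1e-6)),
             target_slope = tgt, offtarget_slope = off,
             n_phase2_emas = 20, mean_z_mood = 0, mean_z_target = 0,
             mean_z_offtarget = 0, excluded = FALSE)
}

test_that("identity regression recovers beta_target ~ 1 and beta_offtarget ~ 0", {
  sl <- make_slope_frame()
  res <- specificity_regression(sl)
  expect_equal(res$beta_target, 1, tolerance = 1e-3)
  expect_lt(abs(res$beta_offtarget), 1e-3)
  expect_lt(res$p_target, 1e-10)
  expect_equal(res$n, 30)
})

test_that("robust betas track OLS on clean data", {
  # bisquare reweighting keeps ~95% Gaussian efficiency, so on clean data
  # the robust betas sit within a small band of OLS, not exactly on it
  for (seed in c(7, 19, 23)) {
    sl <- make_slope_frame(n = 60, seed = seed,
                           mood_fun = function(tgt, off, e) {
      0.5 * tgt + 0.1 * off + rnorm(length(tgt), 0, 0.01)
    })
    res <- specificity_regression(sl)
    zs <- function(x) (x - mean(x)) / sd(x)
    ols <- lm(zs(mood_slope) ~ zs(target_slope) + zs(offtarget_slope),
              data = sl)
    expect_lt(abs(res$beta_target - coef(ols)[2]), 0.06)
    expect_lt(abs(res$beta_offtarget - coef(ols)[3]), 0.06)
  }
  # with an exact linear relationship the two estimators coincide
  sl0 <- make_slope_frame(n = 30, seed = 5, mood_fun = function(tgt, off, e) {
    0.5 * tgt + 0.1 * off
  })
  res0 <- specificity_regression(sl0)
  zs <- function(x) (x - mean(x)) / sd(x)
  ols0 <- lm(zs(mood_slope) ~ zs(target_slope) + zs(offtarget_slope),
             data = sl0)
  expect_equal(res0$beta_target, unname(coef(ols0)[2]), tolerance = 1e-6)
  expect_equal(res0$beta_offtarget, unname(coef(ols0)[3]), tolerance = 1e-6)
})

test_that("degenerate specificity inputs raise errors", {
  sl <- make_slope_frame(n = 5)
  expect_error(specificity_regression(sl), ">= 10")
  sl2 <- make_slope_frame(n = 20, seed = 3)
  sl2$offtarget_slope <- sl2$target_slope * 1.0000001
  expect_error(specificity_regression(sl2), "collinear")
})

test_that("simulated target-only improvement yields specific slopes end to end", {
  coh <- simulate_cohort(15, master_seed = 314,
                         scenario = sim_scenario(),
                         missing_rate_phase2 = 0.2)
  truth_assign <- data.frame(participant_id = coh$truth$participant_id,
                             assigned = coh$truth$target_domain)
  sl <- cohort_slopes(coh$ema, truth_assign, feature_catalog())
  expect_equal(nrow(sl), 15)
  res <- specificity_regression(sl)
  # mood improves with the planted target-domain gain
  expect_gt(mean(sl$target_slope, na.rm = TRUE), 0)
  expect_gt(mean(sl$mood_slope, na.rm = TRUE), 0)
  expect_gt(res$beta_target, 0)
})
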