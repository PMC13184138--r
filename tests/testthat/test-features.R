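mini_catalog <- function() {
  feature_catalog(data.frame(
    feature = c("hr_bpm", "steps", "diet_quality", "sleep_duration"),
    domain = c("watch", "watch", "diet", "sleep"),
    source = c("watch", "watch", "ema", "ema"),
    aggregation = c("mean_since_prev", "sum_since_prev", "last_value",
                    "carry_forward"),
    orientation = c(1, 1, 1, 1), stringsAsFactors = FALSE))
}

hand_ema <- function(times, mood = 4, items = list()) {
  df <- data.frame(participant_id = "P1",
                   timestamp = as.POSIXct(times, tz = "UTC"),
                   phase = "monitoring", mood = mood,
                   stringsAsFactors = FALSE)
  for (nm in names(items)) df[[nm]] <- items[[nm]]
  df
}

hand_watch <- function(times, hr = 70, steps = 0) {
  data.frame(participant_id = "P1",
             timestamp = as.POSIXct(times, tz = "UTC"),
             hr_bpm = hr, steps = steps, step_speed = 1, distance_m = 0,
             calories = 0, stringsAsFactors = FALSE)
}

test_that("a constant watch stream aggregates to its constant", {
  ema <- hand_ema(c("2023-01-02 08:00:00", "2023-01-02 12:00:00",
                    "2023-01-02 16:00:00"))
  watch <- hand_watch(sprintf("2023-01-02 %02d:30:00", 5:15), hr = 70)
  ft <- align_features(ema, watch, mini_catalog())
  expect_equal(unname(ft$X[, "hr_bpm"]), c(70, 70, 70))
})

test_that("step counts sum over the half-open inter-session interval", {
  ema <- hand_ema(c("2023-01-02 08:00:00", "2023-01-02 12:00:00"))
  watch <- hand_watch(c("2023-01-02 09:00:00", "2023-01-02 11:00:00",
                        "2023-01-02 12:00:00", "2023-01-02 08:00:00"),
                      steps = c(1000, 500, 250, 99))
  ft <- align_features(ema, watch, mini_catalog())
  # (08:00, 12:00] contains 09:00, 11:00 and the boundary 12:00 sample;
  # the 08:00 sample belongs to the first session's lookback window
  expect_equal(unname(ft$X[2, "steps"]), 1750)
  expect_equal(unname(ft$X[1, "steps"]), 99)
})

test_that("every aggregated watch cell matches a brute-force interval recomputation", {
  tr <- ground_truth("P1", "exercise",
                     c(sleep = 0, exercise = -1.5, diet = 0, social = 0),
                     seed = 31)
  sim <- simulate_participant(tr, sim_scenario())
  cat <- feature_catalog()
  p1 <- sim$ema[sim$ema$phase == "monitoring", ]
  ft <- align_features(p1, sim$watch, cat)
  t_dv <- as.numeric(as.POSIXct(p1$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC"))
  tw <- as.numeric(as.POSIXct(sim$watch$timestamp,
                              format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  prev <- c(t_dv[1] - 24 * 3600, utils::head(t_dv, -1))
  for (feat in c("hr_bpm", "steps", "calories")) {
    rule <- cat$entries$aggregation[cat$entries$feature == feat]
    fun <- if (rule == "sum_since_prev") sum else mean
    for (i in seq_along(t_dv)) {
      expect_equal(unname(ft$X[i, feat]),
                   oracle_watch_cell(tw, sim$watch[[feat]], prev[i],
                                     t_dv[i], fun))
    }
  }
})

test_that("features are causal: truncating future raw data leaves earlier cells unchanged", {
  tr <- ground_truth("P1", "sleep",
                     c(sleep = -1.5, exercise = 0, diet = 0, social = 0),
                     seed = 13)
  sim <- simulate_participant(tr, sim_scenario())
  p1 <- sim$ema[sim$ema$phase == "monitoring", ]
  full <- align_features(p1, sim$watch, feature_catalog())
  cut_i <- 30
  t_cut <- as.POSIXct(p1$timestamp[cut_i], format = "%Y-%m-%dT%H:%M:%S",
                      tz = "UTC")
  ema_tr <- p1[as.POSIXct(p1$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                          tz = "UTC") <= t_cut, ]
  watch_tr <- sim$watch[as.POSIXct(sim$watch$timestamp,
                                   format = "%Y-%m-%dT%H:%M:%S",
                                   tz = "UTC") <= t_cut, ]
  trunc <- align_features(ema_tr, watch_tr, feature_catalog())
  expect_equal(trunc$X[seq_len(cut_i), ], full$X[seq_len(cut_i), ])
})

test_that("carry-forward respects the 36 h staleness horizon", {
  ema <- hand_ema(c("2023-01-02 08:00:00", "2023-01-03 10:00:00",
                    "2023-01-05 10:00:00"),
                  items = list(sleep_duration = c(6, NA, NA)))
  ft <- align_features(ema, hand_watch("2023-01-02 00:00:00"),
                       mini_catalog())
  expect_equal(unname(ft$X[1, "sleep_duration"]), 6)
  expect_equal(unname(ft$X[2, "sleep_duration"]), 6)   # 26 h old
  expect_true(is.na(ft$X[3, "sleep_duration"]))        # 74 h old
})

test_that("row count equals the number of DV observations", {
  tr <- ground_truth("P1", "diet",
                     c(sleep = 0, exercise = 0, diet = -1.3, social = 0),
                     seed = 4)
  sim <- simulate_participant(tr, sim_scenario())
  p1 <- sim$ema[sim$ema$phase == "monitoring", ]
  ft <- align_features(p1, sim$watch, feature_catalog())
  expect_equal(nrow(ft$X), nrow(p1))
  expect_equal(length(ft$dv), nrow(p1))
})

test_that("imputation uses within-participant medians and standardization is exact", {
  X <- cbind(a = c(1, NA, 3, 5), b = c(2, 2, 2, 2), c = c(NA, NA, NA, NA),
             d = c(1, 4, 2, 8))
  tab <- make_table(X, dv = c(4, 4, 5, 3))
  expect_warning(expect_warning(prep <- preproc_fit(tab), "all-missing"),
                 "constant")
  out <- preproc_apply(tab, prep)
  expect_equal(colnames(out$X), c("a", "d"))
  # median of (1,3,5) = 3 fills the gap before standardization
  imp <- c(1, 3, 3, 5)
  expect_equal(unname(out$X[, "a"]), (imp - mean(imp)) / sd(imp))
  expect_lt(abs(mean(out$X[, "a"])), 1e-9)
  expect_lt(abs(sd(out$X[, "a"]) - 1), 1e-9)
})

test_that("a three-value feature with one gap imputes to the median of the rest", {
  X <- cbind(a = c(1, NA, 3), b = c(0, 1, 2))
  tab <- make_table(X, dv = c(4, 5, 4))
  prep <- preproc_fit(tab)
  expect_equal(unname(prep$median["a"]), 2)
})

test_that("preprocessing is the identity when nothing is missing (up to scaling)", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(5, 1, 2, 2))
  tab <- make_table(X, dv = c(4, 4, 5, 3))
  out <- impute_and_standardize(tab)
  expect_equal(unname(out$X[, "a"]), unname(scale(X[, "a"])[, 1]))
})

test_that("training-fold statistics never depend on held-out rows", {
  set.seed(8)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, letters[1:4]))
  tab <- make_table(X, dv = rnorm(20, 4))
  prep1 <- preproc_fit(tab, rows = 1:12)
  tab2 <- tab
  tab2$X[13:20, ] <- 999  # corrupt the held-out block
  prep2 <- preproc_fit(tab2, rows = 1:12)
  expect_identical(prep1, prep2)
})
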