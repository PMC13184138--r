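#' Simulation scenario: study-design parameters for the synthetic cohort
#'
#' Encodes the two-phase design: a digital monitoring phase with up to four
#' EMAs per day (notifications at 08:00/12:00/16:00/20:00, a 2 h refractory
#' gap, 60 sessions completed over 2-4 weeks), followed by a 6-week
#' intervention phase with once-daily EMAs.
#'
#' @param n_monitoring_sessions phase-1 EMA sessions per participant (60).
#' @param phase2_days length of the intervention phase in days (42).
#' @param emas_per_day_phase1 notifications per day in phase 1 (4).
#' @param notification_times clock hours of the daily notifications.
#' @param refractory_hours minimum gap between consecutive EMAs (2).
#' @param rating_bounds integer rating scale bounds, default 1..7.
#' @param watch_sampling_minutes smartwatch sampling period (30 min).
#' @param response_prob_phase1 probability a phase-1 notification is answered;
#'   0.85 yields 60 sessions over roughly 15-28 calendar days.
#' @param ar_rho AR(1) autocorrelation of the latent behavior z-scores (0.5).
#' @param jitter_minutes EMA response jitter around the notification time.
#' @param round_ratings clip ratings to the scale and round to integers
#'   (TRUE); FALSE keeps the continuous latent mood, used for exact
#'   identity checks.
#' @param outcome_effect scaling from cumulative target-domain behavior
#'   change (mood-scale points) to primary-outcome improvement (PHQ9 points).
#' @param fu_missing_rates missingness of the 6- and 12-week follow-ups.
#' @return an object of class \code{sim_scenario}.
#' @export
sim_scenario <- function(n_monitoring_sessions = 60,
                         phase2_days = 42,
                         emas_per_day_phase1 = 4,
                         notification_times = c(8, 12, 16, 20),
                         refractory_hours = 2,
                         rating_bounds = c(1L, 7L),
                         watch_sampling_minutes = 30,
                         response_prob_phase1 = 0.85,
                         ar_rho = 0.5,
                         jitter_minutes = 45,
                         round_ratings = TRUE,
                         outcome_effect = 2,
                         fu_missing_rates = c(FU6 = 0.30, FU12 = 0.45)) {
  if (rating_bounds[1] >= rating_bounds[2]) {
    stop_config("rating_bounds must satisfy min < max")
  }
  if (emas_per_day_phase1 * refractory_hours >= 24) {
    stop_config("infeasible schedule: %d EMAs/day with a %.1f h refractory gap cannot fit in a day",
                emas_per_day_phase1, refractory_hours)
  }
  if (length(notification_times) != emas_per_day_phase1) {
    stop_config("need one notification time per phase-1 EMA slot")
  }
  gaps <- diff(sort(notification_times))
  if (length(gaps) && min(gaps) - 2 * jitter_minutes / 60 < refractory_hours) {
    stop_config("infeasible schedule: notification spacing %.2f h minus jitter violates the %.1f h refractory gap",
                min(gaps), refractory_hours)
  }
  structure(list(
    n_monitoring_sessions = n_monitoring_sessions, phase2_days = phase2_days,
    emas_per_day_phase1 = emas_per_day_phase1,
    notification_times = notification_times,
    refractory_hours = refractory_hours, rating_bounds = rating_bounds,
    watch_sampling_minutes = watch_sampling_minutes,
    response_prob_phase1 = response_prob_phase1, ar_rho = ar_rho,
    jitter_minutes = jitter_minutes, round_ratings = round_ratings,
    outcome_effect = outcome_effect, fu_missing_rates = fu_missing_rates
  ), class = "sim_scenario")
}

#' Ground truth for one simulated participant
#'
#' @param participant_id opaque id string.
#' @param target_domain the domain with the dominant lifestyle-mood coupling;
#'   the intervention "should" target this domain.
#' @param coupling named numeric vector over sleep/exercise/diet/social:
#'   effect of a one-z-unit increase in healthy behavior on the depressed-mood
#'   rating (negative = healthier behavior lowers depressed mood). Exactly one
#'   domain must have the maximum absolute coupling.
#' @param noise_sd residual mood noise, mood-scale units (> 0).
#' @param phase2_target_gain upward drift of the target domain's behavior
#'   z-score per phase-2 session; off-target domains have zero drift.
#' @param baseline_mood intercept of the mood model.
#' @param missing_rate_phase2 probability a phase-2 daily EMA is skipped.
#' @param seed per-participant RNG seed.
#' @return an object of class \code{ground_truth}.
#' @export
ground_truth <- function(participant_id, target_domain, coupling,
                         noise_sd = 0.4, phase2_target_gain = 0.03,
                         baseline_mood = 4, missing_rate_phase2 = 0.35,
                         seed = 1L) {
  stopifnot(target_domain %in% LIFESTYLE_DOMAINS,
            all(LIFESTYLE_DOMAINS %in% names(coupling)))
  coupling <- coupling[LIFESTYLE_DOMAINS]
  if (noise_sd <= 0) stop_config("noise_sd must be > 0")
  if (missing_rate_phase2 < 0 || missing_rate_phase2 > 1) {
    stop_config("missing_rate_phase2 must lie in [0, 1]")
  }
  amax <- which(abs(coupling) == max(abs(coupling)))
  if (length(amax) != 1) {
    stop_config("exactly one domain must carry the maximum absolute coupling")
  }
  if (LIFESTYLE_DOMAINS[amax] != target_domain) {
    stop_config("target_domain must be the domain with the largest |coupling|")
  }
  structure(list(participant_id = as.character(participant_id),
                 target_domain = target_domain, coupling = coupling,
                 noise_sd = noise_sd, phase2_target_gain = phase2_target_gain,
                 baseline_mood = baseline_mood,
                 missing_rate_phase2 = missing_rate_phase2,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

# phase-1 EMA timestamps: answer each notification with prob
# response_prob_phase1, jittered, until the session quota is met
phase1_times <- function(scenario, t0) {
  n_needed <- scenario$n_monitoring_sessions
  times <- numeric(0)
  day <- 0
  while (length(times) < n_needed && day < 2000) {
    for (h in scenario$notification_times) {
      if (length(times) >= n_needed) break
      if (stats::runif(1) <= scenario$response_prob_phase1) {
        jit <- stats::runif(1, -scenario$jitter_minutes,
                            scenario$jitter_minutes) * 60
        times <- c(times, t0 + day * 86400 + h * 3600 + jit)
      }
    }
    day <- day + 1
  }
  times
}

# stationary AR(1) with unit marginal variance
ar1_series <- function(n, rho) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, sd = sqrt(1 - rho^2))
    for (t in 2:n) z[t] <- rho * z[t - 1] + innov[t - 1]
  }
  z
}

OUTCOME_TIMEPOINTS <- c("screening", "pre", "GS1", "GS3", "GS5", "post",
                        "FU6", "FU12")

# fraction of the eventual specific improvement realized at each timepoint;
# GS1 includes a small nonspecific monitoring-phase effect
.progress <- c(screening = 0, pre = 0, GS1 = 0.15, GS3 = 0.45, GS5 = 0.8,
               post = 1, FU6 = 1, FU12 = 0.9)

#' Simulate one participant's EMA, watch and outcome data
#'
#' Latent behavior z-scores for the four lifestyle domains evolve as AR(1)
#' across sessions; each depressed-mood rating is the clipped, rounded value
#' of \code{baseline_mood + sum_d coupling[d] * z[d] + N(0, noise_sd)}.
#' During phase 2 the target domain's z drifts upward by
#' \code{phase2_target_gain} per daily session; off-target domains do not
#' drift. Sleep items are probed once per day (first EMA of the day), other
#' items at every session. Watch samples are generated on a regular grid with
#' step attributes coupled to the day's exercise z.
#'
#' @param truth a \code{ground_truth}.
#' @param scenario a \code{sim_scenario}.
#' @param catalog a \code{feature_catalog} naming the EMA items to emit.
#' @param include_watch generate the smartwatch stream (TRUE); analyses
#'   that only consume EMA series can skip it.
#' @return list with data.frames \code{ema}, \code{watch}, \code{outcomes}
#'   and a \code{latent} matrix of per-session domain z-scores (with the
#'   continuous linear predictor as attribute \code{linpred}).
#' @export
simulate_participant <- function(truth, scenario = sim_scenario(),
                                 catalog = feature_catalog(),
                                 include_watch = TRUE) {
  set.seed(truth$seed)
  t0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")
  b <- scenario$rating_bounds

  t1 <- phase1_times(scenario, as.numeric(t0))
  n1 <- length(t1)
  # phase-2: one notification per day at 12:00, answered with prob 1 - missing
  keep2 <- stats::runif(scenario$phase2_days) > truth$missing_rate_phase2
  day2_0 <- floor((max(t1) - as.numeric(t0)) / 86400) + 1
  t2_all <- as.numeric(t0) + (day2_0 + seq_len(scenario$phase2_days) - 1) * 86400 +
    12 * 3600 + stats::runif(scenario$phase2_days, -scenario$jitter_minutes,
                             scenario$jitter_minutes) * 60
  t2 <- t2_all[keep2]
  phase2_session <- which(keep2) - 1L  # drift index: phase-2 day, 0-based

  n2 <- length(t2)
  n <- n1 + n2
  z <- sapply(LIFESTYLE_DOMAINS, function(d) ar1_series(n, scenario$ar_rho))
  if (n == 1) z <- matrix(z, nrow = 1, dimnames = list(NULL, LIFESTYLE_DOMAINS))
  # phase-2 target drift on the mean level
  if (n2 > 0) {
    z[n1 + seq_len(n2), truth$target_domain] <-
      z[n1 + seq_len(n2), truth$target_domain] +
      truth$phase2_target_gain * phase2_session
  }
  linpred <- truth$baseline_mood + as.vector(z %*% truth$coupling)
  mood_raw <- linpred + stats::rnorm(n, sd = truth$noise_sd)
  mood <- if (scenario$round_ratings) clip_round_rating(mood_raw, b) else mood_raw

  times <- c(t1, t2)
  day_of <- floor((times - as.numeric(t0)) / 86400)
  first_of_day <- !duplicated(day_of)

  items <- catalog$entries[catalog$entries$source == "ema", ]
  item_mat <- matrix(NA_real_, n, nrow(items),
                     dimnames = list(NULL, items$feature))
  center <- mean(b)
  for (j in seq_len(nrow(items))) {
    d <- items$domain[j]
    raw <- center + items$orientation[j] * 1.2 * z[, d] +
      stats::rnorm(n, sd = 0.5)
    val <- if (scenario$round_ratings) clip_round_rating(raw, b) else raw
    # sleep duration is a morning question (first EMA of the day, carried
    # forward by the aligner); momentary items are probed at every session
    probe <- if (items$feature[j] == "sleep_duration") first_of_day else
      rep(TRUE, n)
    item_mat[probe, j] <- val[probe]
  }

  ema <- data.frame(
    participant_id = truth$participant_id,
    timestamp = format(as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
                       "%Y-%m-%dT%H:%M:%S"),
    phase = rep(c("monitoring", "intervention"), c(n1, n2)),
    mood = mood, stringsAsFactors = FALSE
  )
  ema <- cbind(ema, as.data.frame(item_mat))

  if (!include_watch) {
    watch <- data.frame(participant_id = character(0),
                        timestamp = character(0), hr_bpm = numeric(0),
                        steps = integer(0), step_speed = numeric(0),
                        distance_m = numeric(0), calories = numeric(0))
    outcomes <- simulate_outcomes(truth, scenario)
    return(list(ema = ema, watch = watch, outcomes = outcomes,
                latent = structure(z, linpred = linpred, n_phase1 = n1)))
  }
  # daily exercise level for the watch stream: mean session z of that day
  total_days <- max(day_of) + 1
  z_ex_day <- vapply(seq_len(total_days) - 1, function(dd) {
    s <- z[day_of == dd, "exercise"]
    if (length(s)) mean(s) else NA_real_
  }, numeric(1))
  z_ex_day <- zoo::na.locf(zoo::na.locf(z_ex_day, na.rm = FALSE),
                           fromLast = TRUE, na.rm = FALSE)
  z_ex_day[is.na(z_ex_day)] <- 0

  step_min <- scenario$watch_sampling_minutes
  wt <- as.numeric(t0) + seq(0, total_days * 86400 - 1, by = step_min * 60)
  wd <- floor((wt - as.numeric(t0)) / 86400) + 1
  hour <- (wt - as.numeric(t0)) %% 86400 / 3600
  awake <- hour >= 7 & hour <= 22
  lambda <- ifelse(awake, 180 * exp(0.4 * z_ex_day[wd]), 2) *
    step_min / 30
  steps <- stats::rpois(length(wt), lambda)
  speed <- ifelse(steps > 0, pmax(stats::rnorm(length(wt), 1.2, 0.2), 0.3), 0)
  watch <- data.frame(
    participant_id = truth$participant_id,
    timestamp = format(as.POSIXct(wt, origin = "1970-01-01", tz = "UTC"),
                       "%Y-%m-%dT%H:%M:%S"),
    hr_bpm = round(70 + 3 * z_ex_day[wd] * awake +
                     stats::rnorm(length(wt), 0, 5), 1),
    steps = steps,
    step_speed = round(speed, 2),
    distance_m = round(steps * 0.75, 1),
    calories = round(steps * 0.04 + stats::rnorm(length(wt), 0, 0.5), 2),
    stringsAsFactors = FALSE
  )
  watch$hr_bpm <- clip(watch$hr_bpm, 40, 180)
  watch$calories <- pmax(watch$calories, 0)

  outcomes <- simulate_outcomes(truth, scenario)

  list(ema = ema, watch = watch, outcomes = outcomes,
       latent = structure(z, linpred = linpred, n_phase1 = n1))
}

# clinical outcome trajectories: baseline + improvement proportional to the
# cumulative target-domain behavior change, plus noise
simulate_outcomes <- function(truth, scenario) {
  # mood-scale points of specific improvement accrued by end of phase 2
  improve <- -truth$coupling[[truth$target_domain]] *
    truth$phase2_target_gain * scenario$phase2_days
  eff <- scenario$outcome_effect

  phq_base <- clip(round(stats::rnorm(1, 9.2, 5.1)), 5, 17)
  gad_base <- clip(round(7.1 + 0.63 * (phq_base - 9.2) + stats::rnorm(1, 0, 3)),
                   0, 21)
  tp_phq <- OUTCOME_TIMEPOINTS
  tp_gad <- setdiff(OUTCOME_TIMEPOINTS, "screening")

  make <- function(instrument, base, tps, scale, lo, hi, direction = -1) {
    score <- base + direction * scale * .progress[tps] +
      stats::rnorm(length(tps), 0, 0.35 * abs(scale) + 0.5)
    data.frame(participant_id = truth$participant_id, instrument = instrument,
               timepoint = tps, score = clip(round(score), lo, hi),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    make("PHQ9", phq_base, tp_phq, eff * improve, 0, 27),
    make("GAD7", gad_base, tp_gad, 0.7 * eff * improve, 0, 21),
    make("HDRS", clip(round(phq_base * 1.6 + stats::rnorm(1, 0, 3)), 0, 52),
         c("pre", "post"), 2 * eff * improve, 0, 52),
    make("MCS12", clip(round(stats::rnorm(1, 38, 8)), 10, 70),
         c("pre", "post"), 3 * eff * improve, 10, 70, direction = +1),
    make("MAAS", clip(round(stats::rnorm(1, 3.5, 0.9)), 1, 6),
         c("pre", "post"), 0.3 * eff * improve, 1, 6, direction = +1)
  )
  for (task in c("attention", "interference", "working_memory",
                 "emotion_bias")) {
    gain <- if (task == "emotion_bias") 0 else 0.08 * eff * improve
    pre <- cognitive_efficiency(clip(stats::rnorm(1, 0.8, 0.08), 0.3, 1),
                                max(stats::rnorm(1, 1.5, 0.3), 0.5))
    post <- pre + gain + stats::rnorm(1, 0, 0.15)
    out <- rbind(out, data.frame(
      participant_id = truth$participant_id,
      instrument = paste0("cognition_", task),
      timepoint = c("pre", "post"), score = round(c(pre, max(post, 0)), 3),
      stringsAsFactors = FALSE))
  }
  # follow-ups missing at the configured rates
  for (fu in names(scenario$fu_missing_rates)) {
    if (stats::runif(1) < scenario$fu_missing_rates[[fu]]) {
      out <- out[out$timepoint != fu, ]
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate a cohort with planted target domains
#'
#' @param n number of participants.
#' @param scenario a \code{sim_scenario}.
#' @param master_seed master seed; per-participant seeds are derived with
#'   \code{\link{split_seed}}, so results do not depend on processing order.
#' @param target_domains optional explicit character vector (length n) of
#'   planted target domains; by default domains are drawn with probabilities
#'   proportional to the assignment frequencies seen in practice
#'   (sleep 5 : exercise 13 : diet 5 : social 17 out of 40).
#' @param catalog a \code{feature_catalog}.
#' @param coupling_target range of the (negative) target-domain coupling
#'   magnitude; off-target couplings are drawn small.
#' @param coupling_offtarget range the off-target couplings are drawn from
#'   uniformly; shrink both ranges toward zero for a mood-behavior null.
#' @param phase2_target_gain,noise_sd,missing_rate_phase2 passed per
#'   participant to \code{\link{ground_truth}}.
#' @param include_watch generate smartwatch streams (TRUE).
#' @return list with stacked \code{ema}, \code{watch}, \code{outcomes}
#'   data.frames, a \code{truth} manifest data.frame and the list of
#'   \code{ground_truth} objects.
#' @export
simulate_cohort <- function(n, scenario = sim_scenario(), master_seed = 1L,
                            target_domains = NULL,
                            catalog = feature_catalog(),
                            coupling_target = c(1.2, 1.8),
                            coupling_offtarget = c(-0.25, 0.25),
                            phase2_target_gain = 0.03,
                            noise_sd = 0.4,
                            missing_rate_phase2 = 0.35,
                            include_watch = TRUE) {
  stopifnot(n >= 1)
  set.seed(split_seed(master_seed, 0))
  if (is.null(target_domains)) {
    target_domains <- sample(LIFESTYLE_DOMAINS, n, replace = TRUE,
                             prob = c(5, 13, 5, 17) / 40)
  }
  stopifnot(length(target_domains) == n,
            all(target_domains %in% LIFESTYLE_DOMAINS))

  truths <- vector("list", n)
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(split_seed(master_seed, i))
    tgt <- target_domains[i]
    coup <- stats::runif(4, coupling_offtarget[1], coupling_offtarget[2])
    names(coup) <- LIFESTYLE_DOMAINS
    coup[tgt] <- -stats::runif(1, coupling_target[1], coupling_target[2])
    truths[[i]] <- ground_truth(
      participant_id = sprintf("P%03d", i), target_domain = tgt,
      coupling = coup, noise_sd = noise_sd,
      phase2_target_gain = phase2_target_gain,
      missing_rate_phase2 = missing_rate_phase2,
      seed = split_seed(master_seed, 10000 + i))
    parts[[i]] <- simulate_participant(truths[[i]], scenario, catalog,
                                       include_watch = include_watch)
  }
  manifest <- data.frame(
    participant_id = vapply(truths, `[[`, "", "participant_id"),
    target_domain = vapply(truths, `[[`, "", "target_domain"),
    t(vapply(truths, function(tr) tr$coupling, numeric(4))),
    noise_sd = noise_sd, phase2_target_gain = phase2_target_gain,
    stringsAsFactors = FALSE)
  names(manifest)[3:6] <- paste0("coupling_", LIFESTYLE_DOMAINS)

  list(ema = do.call(rbind, lapply(parts, `[[`, "ema")),
       watch = do.call(rbind, lapply(parts, `[[`, "watch")),
       outcomes = do.call(rbind, lapply(parts, `[[`, "outcomes")),
       truth = manifest, ground_truths = truths,
       latent = lapply(parts, `[[`, "latent"))
}

#' Write a simulated cohort to disk
#'
#' Emits \code{ema.csv}, \code{watch.csv}, \code{outcomes.csv} and a
#' \code{truth.json} manifest under \code{dir}.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$ema, file.path(dir, "ema.csv"), row.names = FALSE)
  utils::write.csv(cohort$watch, file.path(dir, "watch.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
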