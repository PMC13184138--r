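outcome_rows <- function(id, instrument, scores,
                         tps = c("screening", "pre", "GS1", "GS3", "GS5",
                                 "post")[seq_along(scores)]) {
  data.frame(participant_id = id, instrument = instrument,
             timepoint = factor(tps, levels = idiomood:::OUTCOME_TIMEPOINTS,
                                ordered = TRUE),
             score = scores, stringsAsFactors = FALSE)
}

test_that("interior gaps interpolate linearly; edges and follow-ups never do", {
  tab <- rbind(outcome_rows("P1", "PHQ9", c(12, 10, NA, 6),
                            tps = c("pre", "GS1", "GS3", "GS5")),
               outcome_rows("P2", "PHQ9", c(9, 9, 9, 9),
                            tps = c("pre", "GS1", "GS3", "GS5")))
  tab <- tab[!is.na(tab$score), ]
  out <- interpolate_missing(tab, "PHQ9")
  gs3 <- out[out$participant_id == "P1" & out$timepoint == "GS3", ]
  expect_equal(gs3$score, 8)   # midpoint of 10 and 6
  expect_true(gs3$imputed)
  # untouched participant unchanged
  expect_equal(out[out$participant_id == "P2", ]$score, rep(9, 4))
  expect_false(any(out[out$participant_id == "P2", ]$imputed))
  # leading gap stays missing, with a warning
  tab2 <- outcome_rows("P3", "PHQ9", c(10, 8), tps = c("GS1", "GS3"))
  tab2 <- rbind(tab2, outcome_rows("P4", "PHQ9", c(7, NA, 9, 8),
                                   tps = c("pre", "GS1", "GS3", "GS5")))
  tab2 <- tab2[!is.na(tab2$score), ]
  expect_warning(out2 <- interpolate_missing(tab2, "PHQ9"), "leading")
  expect_false("pre" %in%
                 as.character(out2$timepoint[out2$participant_id == "P3"]))
  # follow-ups are never imputed even when interior logic runs
  tab3 <- rbind(outcome_rows("P5", "PHQ9", c(10, 8, 7),
                             tps = c("pre", "GS1", "post")),
                outcome_rows("P5", "PHQ9", 6, tps = "FU12"))
  out3 <- interpolate_missing(tab3, "PHQ9")
  expect_false(any(out3$timepoint == "FU6"))
  expect_error(interpolate_missing(tab3, "HDRS"), "absent")
})

test_that("the study-like missingness pattern yields ~4.6% missing cells, all recovered", {
  # 40 participants x 6 timepoints; 1 missing screening, 2 missing GS3,
  # 8 missing GS5 -> 11/240 = 4.6% missing
  set.seed(60)
  tps <- c("screening", "pre", "GS1", "GS3", "GS5", "post")
  tab <- do.call(rbind, lapply(1:40, function(i) {
    outcome_rows(sprintf("P%02d", i), "PHQ9",
                 round(pmin(pmax(rnorm(6, 9, 4), 0), 27)), tps = tps)
  }))
  drop <- rbind(data.frame(p = "P01", tp = "screening"),
                data.frame(p = c("P02", "P03"), tp = "GS3"),
                data.frame(p = sprintf("P%02d", 4:11), tp = "GS5"))
  keep <- !(paste(tab$participant_id, tab$timepoint) %in%
              paste(drop$p, drop$tp))
  miss_frac <- mean(!keep)
  expect_equal(round(100 * miss_frac, 1), 4.6)
  expect_warning(out <- interpolate_missing(tab[keep, ], "PHQ9"),
                 "leading")  # screening gap cannot be interpolated
  expect_equal(sum(out$imputed), 10)  # GS3 + GS5 gaps are interior
})

test_that("Friedman statistic equals the independent rank computation, with exact p", {
  # identical scores across timepoints: no change, chi-square 0, p 1
  flat <- do.call(rbind, lapply(1:4, function(i) {
    outcome_rows(sprintf("P%d", i), "PHQ9", rep(7, 4),
                 tps = c("pre", "GS1", "GS3", "post"))
  }))
  r0 <- friedman_rm(flat, "PHQ9", c("pre", "GS1", "GS3", "post"))
  expect_equal(r0$chisq, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$p_exact, 1)

  set.seed(71)
  for (dims in list(c(3, 3), c(4, 3), c(5, 4))) {
    n <- dims[1]; k <- dims[2]
    M <- matrix(sample(1:6, n * k, replace = TRUE), n, k)
    tps <- c("pre", "GS1", "GS3", "post")[seq_len(k)]
    tab <- do.call(rbind, lapply(seq_len(n), function(i) {
      outcome_rows(sprintf("P%d", i), "GAD7", M[i, ], tps = tps)
    }))
    res <- friedman_rm(tab, "GAD7", tps)
    expect_equal(res$chisq, oracle_friedman_stat(M), tolerance = 1e-10)
    expect_equal(res$df, k - 1)
    if (n <= 3) {  # full (k!)^n enumeration is feasible
      expect_equal(res$p_exact, oracle_friedman_exact_p(M),
                   tolerance = 1e-12)
    }
  }
  # DP-based exact p equals literal enumeration on a 4x3 fixture too
  M <- matrix(c(5, 3, 1, 2, 2, 4, 6, 5, 5, 1, 2, 3), 4, 3)
  tab <- do.call(rbind, lapply(1:4, function(i) {
    outcome_rows(sprintf("P%d", i), "GAD7", M[i, ],
                 tps = c("pre", "GS1", "post"))
  }))
  res <- friedman_rm(tab, "GAD7", c("pre", "GS1", "post"))
  expect_equal(res$p_exact, oracle_friedman_exact_p(M), tolerance = 1e-12)
})

test_that("the parametric companion reports Mauchly and Greenhouse-Geisser", {
  set.seed(5)
  tps <- c("pre", "GS1", "GS3", "post")
  tab <- do.call(rbind, lapply(1:12, function(i) {
    outcome_rows(sprintf("P%02d", i), "PHQ9",
                 round(10 - (0:3) + rnorm(4, 0, 2)), tps = tps)
  }))
  res <- friedman_rm(tab, "PHQ9", tps)
  expect_true(is.finite(res$rm_anova$F))
  expect_true(res$rm_anova$gg_epsilon <= 1 && res$rm_anova$gg_epsilon > 0)
  expect_gte(res$rm_anova$p_gg, res$rm_anova$p)
  expect_true(is.finite(res$rm_anova$mauchly_p))
})

test_that("signed-rank exact p equals the 2^n sign-flip enumeration", {
  r0 <- signed_rank_test(c(3, 4, 5), c(3, 4, 5))
  expect_true(r0$all_zero)
  expect_equal(r0$p, 1)
  expect_warning(signed_rank_test(c(3, 4, 5), c(3, 5, 5)), "fewer than 5")

  d6 <- c(2, -1, 3, 1, 4, -2)
  r <- signed_rank_test(rep(0, 6), d6)
  expect_equal(r$p, oracle_signed_rank_p(d6), tolerance = 1e-12)

  set.seed(81)
  for (i in 1:8) {
    n <- sample(6:12, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # ties guaranteed
    r <- signed_rank_test(rep(0, n), d)
    expect_equal(r$p, oracle_signed_rank_p(d), tolerance = 1e-12)
    for (alt in c("greater", "less")) {
      ra <- signed_rank_test(rep(0, n), d, alternative = alt)
      expect_equal(ra$p, oracle_signed_rank_p(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("adding a majority-direction pair never increases the one-sided exact p", {
  set.seed(9)
  for (i in 1:10) {
    d <- sample(c(-2:-1, 1:5), 8, replace = TRUE)
    p_before <- signed_rank_test(rep(0, 8), d, alternative = "greater")$p
    d2 <- c(d, 5)  # strong positive addition
    p_after <- signed_rank_test(rep(0, 9), d2, alternative = "greater")$p
    expect_lte(p_after, p_before + 1e-12)
  }
})

test_that("post-hoc battery is BH-corrected and uses available cases at follow-up", {
  set.seed(12)
  tab <- do.call(rbind, lapply(1:20, function(i) {
    sc <- round(pmin(pmax(c(10, 9, 7, 6, 5, 5, 5) + rnorm(7, 0, 2), 0), 27))
    outcome_rows(sprintf("P%02d", i), "PHQ9", sc,
                 tps = c("pre", "GS1", "GS3", "GS5", "post", "FU6", "FU12"))
  }))
  tab <- tab[!(tab$timepoint == "FU6" & tab$participant_id %in%
                 sprintf("P%02d", 1:6)), ]  # 30% FU6 missing
  res <- signed_rank_posthoc(tab, "PHQ9")
  expect_equal(res$n[res$timepoint == "FU6"], 14)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-12))
  expect_equal(res$p_adjusted,
               p.adjust(res$p_raw, "BH"))
})

test_that("paired Cohen's d and its noncentral-t CI are mutually consistent", {
  pre <- c(12, 9, 15, 11, 8, 14, 10, 13, 9, 12)
  post <- c(8, 7, 12, 6, 9, 10, 6, 9, 8, 7)
  es <- cohens_d_paired(pre, post)
  diffs <- post - pre
  expect_equal(es$d, mean(diffs) / sd(diffs), tolerance = 1e-12)
  expect_lt(es$ci[1], es$d)
  expect_gt(es$ci[2], es$d)
  # CI endpoints invert the noncentral-t tail probabilities (simulation check)
  set.seed(100)
  n <- length(diffs)
  t_obs <- es$d * sqrt(n)
  for (side in 1:2) {
    ncp <- es$ci[side] * sqrt(n)
    sim <- rt(100000, df = n - 1, ncp = ncp)
    tail_p <- mean(sim >= t_obs)
    # at the lower ncp bound, exceeding t_obs is the 2.5% event; at the
    # upper bound it is the 97.5% event
    expect_lt(abs(tail_p - c(0.025, 0.975)[side]), 0.005)
  }
  # CI excludes zero exactly when the paired t-test is significant
  expect_equal(es$ci[1] > 0 || es$ci[2] < 0, es$p < 0.05)
  tt <- t.test(post, pre, paired = TRUE)
  expect_equal(es$p, tt$p.value, tolerance = 1e-12)
  # degenerate cases
  expect_error(cohens_d_paired(pre, pre + 3), "zero variance")
  anti <- c(-2, 2, -1, 1, -3, 3)
  expect_equal(cohens_d_paired(rep(0, 6), anti)$d, 0)
})

test_that("the normality gate picks the right branch for known distributions", {
  t_branch <- 0
  sr_branch <- 0
  for (seed in 1:60) {
    set.seed(seed)
    g <- paired_gate(rnorm(40, 10, 2), rnorm(40, 9, 2))
    if (g$test == "paired_t") t_branch <- t_branch + 1
    set.seed(seed + 500)
    heavy <- rt(40, df = 1)
    g2 <- paired_gate(rep(0, 40), heavy)
    if (g2$test == "signed_rank") sr_branch <- sr_branch + 1
  }
  expect_gte(t_branch / 60, 0.9)
  expect_gte(sr_branch / 60, 0.9)
  # decision is deterministic given the data
  set.seed(3)
  a <- rnorm(20, 10); b <- rnorm(20, 9)
  expect_identical(paired_gate(a, b)$test, paired_gate(a, b)$test)
})

test_that("change regression recovers a planted standardized coefficient", {
  set.seed(42)
  n <- 40
  mcs <- rnorm(n, 0, 1)
  other <- rnorm(n, 0, 1)
  # raw coefficient -0.6 with residual sd 0.8 gives a standardized beta
  # near -0.6 (total sd of the outcome is ~1)
  primary <- -0.6 * mcs + rnorm(n, 0, 0.8)
  res <- change_regression(primary,
                           data.frame(MCS12 = mcs, OTHER = other))
  b <- res$coefficients
  expect_lt(b$beta[b$term == "MCS12"], -0.45)
  expect_gt(b$beta[b$term == "MCS12"], -0.75)
  expect_equal(b$label[b$term == "MCS12"], "large")
  expect_lt(b$p[b$term == "MCS12"], 0.001)
  # standardized betas are invariant to affine rescaling of an input
  res2 <- change_regression(primary,
                            data.frame(MCS12 = 10 + 25 * mcs, OTHER = other))
  expect_equal(res2$coefficients$beta, b$beta, tolerance = 1e-9)
  # zero-variance columns are dropped with a warning
  expect_warning(
    res3 <- change_regression(primary,
                              data.frame(MCS12 = mcs, FLAT = rep(1, n))),
    "zero-variance")
  expect_false("FLAT" %in% res3$coefficients$term)
})

test_that("remission contrasts separate groups and respect FDR", {
  # empty-group fixture: everyone remits, contrasts are skipped
  tab_all <- do.call(rbind, lapply(1:10, function(i) {
    outcome_rows(sprintf("P%02d", i), "PHQ9", c(10, 4),
                 tps = c("pre", "post"))
  }))
  base_all <- data.frame(participant_id = sprintf("P%02d", 1:10),
                         GAD7 = rnorm(10, 7))
  rc <- remission_contrast(tab_all, base_all)
  expect_true(all(rc$results$skipped))
  expect_equal(rc$n_remitted, 10)

  # perfectly balanced 2x2 gender table gives chi-square 0
  set.seed(77)
  tab2 <- do.call(rbind, lapply(1:20, function(i) {
    outcome_rows(sprintf("P%02d", i), "PHQ9",
                 c(10, ifelse(i <= 10, 3, 8)), tps = c("pre", "post"))
  }))
  base2 <- data.frame(participant_id = sprintf("P%02d", 1:20),
                      gender = rep(c("F", "M", "F", "M"), each = 5),
                      stringsAsFactors = FALSE)
  rc2 <- remission_contrast(tab2, base2)
  expect_equal(rc2$results$statistic[rc2$results$measure == "gender"], 0)

  # planted 1-SD anxiety difference is detected under FDR most of the time;
  # the theoretical power of this contrast (d = 1, 20 vs 20, BH across
  # three measures) is ~0.75-0.8, so the pass bar sits at 0.7
  hits <- 0
  n_rep <- 60
  for (seed in seq_len(n_rep)) {
    set.seed(seed + 2000)
    remit <- rep(c(TRUE, FALSE), each = 20)
    tab3 <- do.call(rbind, lapply(1:40, function(i) {
      outcome_rows(sprintf("P%02d", i), "PHQ9",
                   c(10, ifelse(remit[i], 3, 9)), tps = c("pre", "post"))
    }))
    # remitters show lower baseline anxiety and higher mindfulness
    base3 <- data.frame(participant_id = sprintf("P%02d", 1:40),
                        GAD7 = rnorm(40, 7, 1) - 1 * remit,
                        MAAS = rnorm(40, 3.5, 1) + 1 * remit,
                        age = rnorm(40, 43, 16))
    rc3 <- remission_contrast(tab3, base3)
    p <- rc3$results$p_adjusted[rc3$results$measure == "GAD7"]
    if (!is.na(p) && p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.7)
})

test_that("cognitive efficiency is the accuracy-speed product with guarded bounds", {
  expect_equal(cognitive_efficiency(1, 2.5), 2.5)
  expect_equal(cognitive_efficiency(0, 3), 0)
  expect_equal(cognitive_efficiency(0.8, 2.5), 2)
  expect_error(cognitive_efficiency(1.2, 1), "accuracy")
  expect_error(cognitive_efficiency(0.5, 0), "speed")
})

test_that("minimum detectable paired effect size matches the design target and limits", {
  expect_equal(round(min_detectable_d(40), 2), 0.45)
  # large-sample normal approximation
  expect_equal(min_detectable_d(10000), (qnorm(0.975) + qnorm(0.8)) / 100,
               tolerance = 1e-3)
  # strictly decreasing in n
  ds <- vapply(c(10, 20, 40, 80, 160), min_detectable_d, numeric(1))
  expect_true(all(diff(ds) < 0))
  # one-sided detection needs a smaller effect
  expect_lt(min_detectable_d(40, two_sided = FALSE), min_detectable_d(40))
})

test_that("domain covariate check is the rank-based group comparison", {
  set.seed(15)
  change <- rnorm(40, -3, 2)
  domain <- sample(c("sleep", "exercise", "diet", "social"), 40,
                   replace = TRUE)
  res <- domain_covariate_check(change, domain)
  kt <- kruskal.test(change, factor(domain))
  expect_equal(res$statistic, unname(kt$statistic))
  expect_equal(res$p, kt$p.value)
})
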