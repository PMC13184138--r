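#' Interpolate interior missing outcome timepoints
#'
#' Per-participant linear interpolation on the ordered timepoint index, for
#' the screening-to-post grid only; 6- and 12-week follow-ups are never
#' imputed (follow-up analyses use available cases). Leading or trailing
#' gaps are left missing with a warning.
#'
#' @param table outcome data.frame (see \code{\link{read_outcomes}}).
#' @param instrument instrument to impute.
#' @return the table with interpolated rows added and an \code{imputed}
#'   flag column.
#' @export
interpolate_missing <- function(table, instrument) {
  sub <- table[table$instrument == instrument, , drop = FALSE]
  if (nrow(sub) == 0) stop_config("instrument '%s' absent", instrument)
  if (is.null(table$imputed)) table$imputed <- FALSE
  grid <- intersect(setdiff(OUTCOME_TIMEPOINTS, c("FU6", "FU12")),
                    as.character(unique(sub$timepoint)))
  leading_trailing <- FALSE
  new_rows <- list()
  for (id in unique(sub$participant_id)) {
    rows <- sub[sub$participant_id == id, ]
    scores <- rows$score[match(grid, as.character(rows$timepoint))]
    if (!anyNA(scores)) next
    filled <- zoo::na.approx(scores, x = seq_along(grid), na.rm = FALSE)
    if (anyNA(filled)) leading_trailing <- TRUE
    fill_idx <- which(is.na(scores) & !is.na(filled))
    if (length(fill_idx)) {
      new_rows[[length(new_rows) + 1]] <- data.frame(
        participant_id = id, instrument = instrument,
        timepoint = factor(grid[fill_idx], levels = OUTCOME_TIMEPOINTS,
                           ordered = TRUE),
        score = filled[fill_idx], imputed = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (leading_trailing) {
    warning("leading/trailing missing timepoints left unimputed",
            call. = FALSE)
  }
  if (length(new_rows)) table <- rbind(table, do.call(rbind, new_rows))
  table[order(table$participant_id, table$instrument, table$timepoint), ,
        drop = FALSE]
}

# complete participants x timepoints score matrix for one instrument
outcome_matrix <- function(table, instrument, timepoints) {
  sub <- table[table$instrument == instrument &
                 as.character(table$timepoint) %in% timepoints, ]
  ids <- unique(sub$participant_id)
  M <- matrix(NA_real_, length(ids), length(timepoints),
              dimnames = list(ids, timepoints))
  M[cbind(match(sub$participant_id, ids),
          match(as.character(sub$timepoint), timepoints))] <- sub$score
  M
}

# Exact permutation p for the Friedman statistic: dynamic programming over
# the distribution of column rank-sum vectors (rows permute independently,
# and the tie-correction factor is permutation-invariant). Feasible for
# small matrices only.
friedman_exact_p <- function(M) {
  n <- nrow(M); k <- ncol(M)
  ranks <- t(apply(M, 1, rank))
  C <- 1 - sum(vapply(seq_len(n), function(i) {
    tt <- table(ranks[i, ]); sum(tt^3 - tt)
  }, numeric(1))) / (n * k * (k^2 - 1))
  stat_of <- function(colsums) {
    S <- 12 / (n * k * (k + 1)) * sum((colsums - n * (k + 1) / 2)^2)
    if (C == 0) 0 else S / C
  }
  obs <- stat_of(colSums(ranks))
  # row orderings: all permutations of each row's rank multiset
  perm_idx <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perm_idx <- perm_idx[apply(perm_idx, 1, function(z)
    length(unique(z)) == k), , drop = FALSE]
  dist <- new.env(hash = TRUE)
  assign(paste(rep(0, k), collapse = ","), 1, envir = dist)
  for (i in seq_len(n)) {
    nxt <- new.env(hash = TRUE)
    keys <- ls(dist)
    for (key in keys) {
      base <- as.numeric(strsplit(key, ",", fixed = TRUE)[[1]])
      w <- get(key, envir = dist)
      for (m in seq_len(nrow(perm_idx))) {
        s <- base + ranks[i, perm_idx[m, ]]
        k2 <- paste(s, collapse = ",")
        prev <- if (exists(k2, envir = nxt, inherits = FALSE))
          get(k2, envir = nxt) else 0
        assign(k2, prev + w, envir = nxt)
      }
    }
    dist <- nxt
  }
  keys <- ls(dist)
  tot <- 0; ge <- 0
  for (key in keys) {
    w <- get(key, envir = dist)
    s <- stat_of(as.numeric(strsplit(key, ",", fixed = TRUE)[[1]]))
    tot <- tot + w
    if (s >= obs - 1e-9) ge <- ge + w
  }
  ge / tot
}

#' Friedman repeated-measures test (with parametric companion)
#'
#' Nonparametric Friedman chi-square (df = k - 1) on within-participant
#' ranks, plus the parametric repeated-measures ANOVA companion with
#' Mauchly's sphericity test and the Greenhouse-Geisser-corrected p value.
#' Both are reported; neither is silently preferred.
#'
#' @param table outcome data.frame (post-imputation).
#' @param instrument instrument to test.
#' @param timepoints ordered character vector of timepoints.
#' @param exact also compute the exact permutation p (feasible for small
#'   matrices only; auto-enabled up to 6 participants x 4 timepoints).
#' @return list with \code{chisq}, \code{df}, \code{p} (Friedman; plus
#'   \code{p_exact} when computed) and \code{rm_anova}: F, uncorrected p,
#'   Greenhouse-Geisser epsilon and corrected p, Mauchly p.
#' @export
friedman_rm <- function(table, instrument, timepoints, exact = NULL) {
  M <- outcome_matrix(table, instrument, timepoints)
  if (anyNA(M)) {
    stop_config("missing cells remain for %s; impute interior timepoints first",
                instrument)
  }
  fr <- stats::friedman.test(M)
  if (!is.finite(fr$statistic)) {
    # every participant fully tied across timepoints: no evidence of change
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  k <- ncol(M)
  rm_anova <- NULL
  if (k >= 3) {
    mlmfit <- stats::lm(M ~ 1)
    idata <- data.frame(time = factor(timepoints, levels = timepoints))
    av <- car::Anova(mlmfit, idata = idata, idesign = ~time, type = "III")
    sm <- summary(av, multivariate = FALSE)
    uni <- sm$univariate.tests
    adj <- sm$pval.adjustments
    sph <- sm$sphericity.tests
    grab <- function(tab, col) {
      tryCatch(unname(tab["time", col]), error = function(e) NA_real_)
    }
    rm_anova <- list(
      F = grab(uni, "F value"),
      df = c(grab(uni, "num Df"), grab(uni, "den Df")),
      p = grab(uni, "Pr(>F)"),
      gg_epsilon = grab(adj, "GG eps"),
      p_gg = grab(adj, "Pr(>F[GG])"),
      mauchly_p = grab(sph, "p-value"))
  }
  if (is.null(exact)) exact <- nrow(M) <= 6 && k <= 4
  p_exact <- if (exact) friedman_exact_p(M) else NULL
  list(chisq = unname(fr$statistic), df = unname(fr$parameter),
       p = fr$p.value, p_exact = p_exact, n = nrow(M), rm_anova = rm_anova)
}

#' Exact / approximate Wilcoxon signed-rank test for paired scores
#'
#' Differences of zero are dropped; absolute differences are ranked with
#' average ranks for ties. For n <= \code{exact_limit} nonzero pairs the
#' two-sided p comes from the exact null distribution of the positive-rank
#' sum (computed by convolution over the doubled ranks, which keeps tied
#' average ranks integral); otherwise the normal approximation with
#' continuity and tie correction is used.
#'
#' @param x,y paired vectors (differences are \code{y - x}).
#' @param exact_limit largest n for the exact null (25).
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (positive differences predominate) or \code{"less"}.
#' @return list with \code{statistic} (positive-rank sum W+), \code{p},
#'   \code{n_nonzero}, \code{method} and \code{all_zero} flag.
#' @export
signed_rank_test <- function(x, y, exact_limit = 25,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  d <- y - x
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p = 1, n_nonzero = 0,
                method = "degenerate", all_zero = TRUE))
  }
  if (n < 5) warning("fewer than 5 nonzero pairs; exact test on tiny n",
                     call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    # exact distribution of W+ via generating-function convolution on 2r
    r2 <- as.integer(round(2 * r))
    coefs <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), utils::head(coefs, length(coefs) - ri))
      coefs <- coefs + shifted
    }
    probs <- coefs / 2^n
    support <- (seq_along(probs) - 1) / 2
    p_le <- sum(probs[support <= W + 1e-9])
    p_ge <- sum(probs[support >= W - 1e-9])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm((W - mu - 0.5) / sqrt(v),
                                       lower.tail = FALSE),
                less = stats::pnorm((W - mu + 0.5) / sqrt(v)))
    method <- "normal_approx"
  }
  list(statistic = W, p = p, n_nonzero = n, method = method,
       all_zero = FALSE)
}

#' Signed-rank post-hoc tests of each timepoint against 'pre'
#'
#' One paired Wilcoxon signed-rank test per timepoint versus the reference,
#' using participants with both observations available (follow-ups are
#' never imputed, so their tests are automatically available-case);
#' Benjamini-Hochberg correction across the tested timepoints.
#'
#' @param table outcome data.frame.
#' @param instrument instrument to test.
#' @param timepoints timepoints to compare against the reference.
#' @param reference reference timepoint ("pre").
#' @return data.frame: timepoint, n pairs, W statistic, raw and BH-adjusted
#'   p, method.
#' @export
signed_rank_posthoc <- function(table, instrument,
                                timepoints = c("GS1", "GS3", "GS5", "post",
                                               "FU6", "FU12"),
                                reference = "pre") {
  M <- outcome_matrix(table, instrument,
                      unique(c(reference, timepoints)))
  timepoints <- intersect(timepoints, colnames(M))
  rows <- lapply(timepoints, function(tp) {
    ok <- stats::complete.cases(M[, c(reference, tp)])
    tst <- signed_rank_test(M[ok, reference], M[ok, tp])
    data.frame(timepoint = tp, n = sum(ok), statistic = tst$statistic,
               p_raw = tst$p, method = tst$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Paired Cohen's d with noncentral-t confidence interval
#'
#' \code{d = mean(post - pre) / sd(post - pre)}; the 95% CI is obtained by
#' inverting the noncentral-t distribution of \code{t = d * sqrt(n)}, and
#' the companion p value comes from the paired t-test, so the CI excludes 0
#' exactly when p < 0.05.
#'
#' @param pre,post paired vectors.
#' @param conf confidence level (0.95).
#' @return list: \code{d}, \code{ci} (length 2), \code{p}, \code{n}.
#' @export
cohens_d_paired <- function(pre, post, conf = 0.95) {
  ok <- stats::complete.cases(pre, post)
  diffs <- post[ok] - pre[ok]
  n <- length(diffs)
  if (n < 2) stop_config("need >= 2 pairs")
  sdd <- stats::sd(diffs)
  if (sdd < 1e-12) stop_config("zero variance of difference scores; d undefined")
  d <- mean(diffs) / sdd
  tval <- d * sqrt(n)
  df <- n - 1
  alpha <- 1 - conf
  ncp_bound <- function(target_p) {
    # pt() warns about precision for extreme noncentrality; harmless here
    f <- function(ncp) suppressWarnings(stats::pt(tval, df, ncp)) - target_p
    lo <- tval - 10 * sqrt(n)
    hi <- tval + 10 * sqrt(n)
    stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  }
  ci <- c(ncp_bound(1 - alpha / 2), ncp_bound(alpha / 2)) / sqrt(n)
  p <- 2 * stats::pt(-abs(tval), df)
  list(d = d, ci = ci, p = p, n = n)
}

#' Normality-gated paired test
#'
#' Anderson-Darling normality test on the difference scores at alpha = 0.05
#' chooses between the paired t-test (normal) and the signed-rank test
#' (non-normal); the choice is recorded in the result. Below 8 pairs the
#' Anderson-Darling statistic is unavailable and the signed-rank branch is
#' taken.
#'
#' @param pre,post paired vectors (n >= 5).
#' @param alpha normality-test level.
#' @return list: \code{test} ("paired_t" or "signed_rank"),
#'   \code{statistic}, \code{p}, \code{ad_p}, \code{n}.
#' @export
paired_gate <- function(pre, post, alpha = 0.05) {
  ok <- stats::complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 5) stop_config("need >= 5 pairs, got %d", n)
  diffs <- post - pre
  ad_p <- if (n >= 8 && stats::sd(diffs) > 1e-12) {
    nortest::ad.test(diffs)$p.value
  } else 0  # too few / degenerate: fall through to the nonparametric branch
  if (ad_p > alpha) {
    tt <- stats::t.test(post, pre, paired = TRUE)
    list(test = "paired_t", statistic = unname(tt$statistic),
         p = tt$p.value, ad_p = ad_p, n = n)
  } else {
    sr <- signed_rank_test(pre, post)
    list(test = "signed_rank", statistic = sr$statistic, p = sr$p,
         ad_p = ad_p, n = n)
  }
}

#' Robust regression of primary change on secondary changes
#'
#' Robust linear regression (bisquare, c = 4.685) of the primary outcome
#' change score on all secondary change scores, controlling for
#' demographics. Numeric variables are z-scored across participants so
#' coefficients are standardized betas, labeled per the usual thresholds
#' (|beta| > 0.1 small, > 0.3 medium, > 0.5 large).
#'
#' @param primary_change numeric vector.
#' @param secondary_changes data.frame of numeric change scores.
#' @param demographics optional data.frame (numeric and/or factor columns).
#' @return list with a coefficient table (standardized beta, SE, p, label)
#'   and the overall Wald F and p over the secondary terms.
#' @export
change_regression <- function(primary_change, secondary_changes,
                              demographics = NULL) {
  df <- data.frame(.y = primary_change, secondary_changes,
                   check.names = FALSE)
  if (!is.null(demographics)) df <- data.frame(df, demographics,
                                               check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  sec_names <- names(secondary_changes)
  drop <- sec_names[vapply(sec_names, function(v)
    stats::sd(df[[v]]) < 1e-12, logical(1))]
  if (length(drop)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
    sec_names <- setdiff(sec_names, drop)
    df <- df[, setdiff(names(df), drop), drop = FALSE]
  }
  p_terms <- ncol(df) - 1
  if (n <= p_terms + 5) stop_config("need n > p + 5 complete cases (n=%d, p=%d)",
                                    n, p_terms)
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  for (v in num) df[[v]] <- (df[[v]] - mean(df[[v]])) / stats::sd(df[[v]])
  fit <- MASS::rlm(.y ~ ., data = df, psi = MASS::psi.bisquare, c = 4.685,
                   maxit = 100)
  sm <- summary(fit)
  co <- sm$coefficients
  df_res <- n - nrow(co)
  keep <- setdiff(rownames(co), "(Intercept)")
  label <- function(b) {
    a <- abs(b)
    if (a > 0.5) "large" else if (a > 0.3) "medium" else if (a > 0.1) "small"
    else "negligible"
  }
  tab <- data.frame(
    term = keep, beta = co[keep, "Value"], se = co[keep, "Std. Error"],
    p = 2 * stats::pt(-abs(co[keep, "t value"]), df_res),
    label = vapply(co[keep, "Value"], label, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  V <- sm$stddev^2 * sm$cov.unscaled
  sec_idx <- which(rownames(co) %in% sec_names)
  b <- co[sec_idx, "Value"]
  Fstat <- as.numeric(t(b) %*% solve(V[sec_idx, sec_idx]) %*% b) /
    length(sec_idx)
  list(coefficients = tab, F = Fstat,
       p_model = stats::pf(Fstat, length(sec_idx), df_res,
                           lower.tail = FALSE),
       n = n)
}

#' Baseline measures associated with remission
#'
#' Remission: post-intervention PHQ9 < 5. Each baseline measure is
#' contrasted between remitted and non-remitted participants: one-way ANOVA
#' for continuous measures, chi-square for categorical ones;
#' Benjamini-Hochberg correction across all measures. A logistic companion
#' controlling for baseline depression is reported per measure.
#'
#' @param table outcome data.frame containing PHQ9 pre and post scores.
#' @param baseline data.frame with \code{participant_id} plus baseline
#'   measure columns (numeric or factor/character).
#' @param remission_cutoff post PHQ9 below this = remitted (5).
#' @return list: per-measure results data.frame, remitted/responder ids and
#'   counts.
#' @export
remission_contrast <- function(table, baseline, remission_cutoff = 5) {
  M <- outcome_matrix(table, "PHQ9", c("pre", "post"))
  if (anyNA(M[, "post"])) stop_config("post PHQ9 missing for some participants")
  remitted <- M[, "post"] < remission_cutoff
  responder <- (M[, "post"] - M[, "pre"]) <= -0.5 * M[, "pre"]
  ids <- rownames(M)
  b <- baseline[match(ids, baseline$participant_id), , drop = FALSE]
  measures <- setdiff(names(b), "participant_id")
  phq_pre <- M[, "pre"]

  one <- function(v, name) {
    if (length(unique(remitted)) < 2) {
      return(data.frame(measure = name, test = "skipped", statistic = NA,
                        df = NA, p_raw = NA, p_logistic = NA,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    if (is.numeric(v)) {
      fit <- stats::aov(v ~ remitted)
      s <- summary(fit)[[1]]
      stat <- s["remitted", "F value"]
      df <- s["remitted", "Df"]
      p <- s["remitted", "Pr(>F)"]
      test <- "anova"
      gl <- stats::glm(remitted ~ v + phq_pre, family = stats::binomial)
      p_log <- summary(gl)$coefficients["v", "Pr(>|z|)"]
    } else {
      tb <- table(factor(v), remitted)
      ct <- suppressWarnings(stats::chisq.test(tb))
      stat <- unname(ct$statistic)
      df <- unname(ct$parameter)
      p <- ct$p.value
      test <- "chisq"
      p_log <- NA_real_
    }
    data.frame(measure = name, test = test, statistic = stat, df = df,
               p_raw = p, p_logistic = p_log, skipped = FALSE,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, lapply(measures, function(m) one(b[[m]], m)))
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = "BH")
  list(results = res,
       remitted = ids[remitted], n_remitted = sum(remitted),
       n_responder = sum(responder), n = length(ids))
}

#' Rank-based check of the intervention-domain covariate
#'
#' Kruskal-Wallis test of whether change scores differ by assigned
#' intervention domain (the rank-based analogue of adding the domain factor
#' to the repeated-measures model).
#'
#' @param change numeric change scores.
#' @param domain assigned domain per participant.
#' @return \code{kruskal.test} result components (statistic, df, p).
#' @export
domain_covariate_check <- function(change, domain) {
  kt <- stats::kruskal.test(change, factor(domain))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Cognitive task efficiency
#'
#' Efficiency = accuracy x processing speed (responses per second).
#'
#' @param accuracy proportion correct in [0, 1].
#' @param speed responses per second (> 0).
#' @return efficiency score.
#' @export
cognitive_efficiency <- function(accuracy, speed) {
  if (any(accuracy < 0 | accuracy > 1, na.rm = TRUE)) {
    stop_config("accuracy must lie in [0, 1]")
  }
  if (any(speed <= 0, na.rm = TRUE)) stop_config("speed must be > 0")
  accuracy * speed
}

#' Minimum detectable paired effect size
#'
#' Smallest Cohen's dz achieving the requested power for a paired t-test at
#' sample size n, solved by root-finding on the noncentral-t power
#' function.
#'
#' @param n number of pairs (>= 2).
#' @param alpha significance level.
#' @param power target power.
#' @param two_sided two-sided test (TRUE).
#' @return Cohen's dz.
#' @export
min_detectable_d <- function(n, alpha = 0.05, power = 0.8,
                             two_sided = TRUE) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  df <- n - 1
  pow <- function(d) {
    ncp <- d * sqrt(n)
    if (two_sided) {
      tc <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp) - power
    } else {
      tc <- stats::qt(1 - alpha, df)
      1 - stats::pt(tc, df, ncp) - power
    }
  }
  if (pow(1e-8) > 0 || pow(10) < 0) stop_config("no root in (0, 10)")
  stats::uniroot(pow, c(1e-8, 10), tol = 1e-10)$root
}
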