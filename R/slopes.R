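#' Representative lifestyle metric for one domain
#'
#' Orientation-corrected mean of the domain's EMA item z-scores per session:
#' each item is z-scored within participant (across the supplied sessions),
#' multiplied by its health orientation so that higher always means more of
#' the healthy behavior, and averaged over the domain's items available in
#' that session.
#'
#' @param sessions one participant's EMA data.frame (item columns present).
#' @param catalog a \code{feature_catalog}.
#' @param domain one of sleep / exercise / diet / social.
#' @return numeric vector, one value per session (NA where no item of the
#'   domain was probed).
#' @export
representative_metric <- function(sessions, catalog, domain) {
  entries <- catalog$entries[catalog$entries$source == "ema" &
                               catalog$entries$domain == domain, ]
  items <- intersect(entries$feature, names(sessions))
  if (length(items) == 0) {
    stop_config("no catalog items for domain '%s' present in the sessions",
                domain)
  }
  zmat <- vapply(items, function(it) {
    v <- sessions[[it]]
    mu <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    ori <- entries$orientation[entries$feature == it]
    if (!is.finite(s) || s < 1e-12) rep(NA_real_, length(v))
    else ori * (v - mu) / s
  }, numeric(nrow(sessions)))
  if (is.null(dim(zmat))) zmat <- matrix(zmat, nrow = nrow(sessions))
  out <- rowMeans(zmat, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Z-score a series against a phase-1 baseline
#'
#' \code{z = (x - mean(baseline)) / sd(baseline)}; expresses phase-2 values
#' in phase-1 standard-deviation units.
#'
#' @param x values to transform.
#' @param baseline phase-1 values of the same metric.
#' @param name metric name used in the zero-variance error message.
#' @return z-scored vector.
#' @export
phase_z <- function(x, baseline, name = "metric") {
  b <- baseline[!is.na(baseline)]
  if (length(b) < 2 || stats::sd(b) < 1e-12) {
    stop_config("zero phase-1 variance for '%s'; cannot z-score", name)
  }
  (x - mean(b)) / stats::sd(b)
}

#' OLS slope of a z-series against phase-2 session index
#'
#' @param z phase-2 z-scored values.
#' @param session 0-based session index (defaults to 0, 1, ...).
#' @return slope in z-units per session, or NA when fewer than 3 points.
#' @export
z_slope <- function(z, session = seq_along(z) - 1) {
  ok <- !is.na(z)
  if (sum(ok) < 3) return(NA_real_)
  x <- session[ok]
  y <- z[ok]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Per-participant phase-2 slopes for mood, target and off-target domains
#'
#' Computes representative metrics for the four lifestyle domains, z-scores
#' every series (mood included) against the participant's phase-1 baseline,
#' and fits linear slopes over phase-2 session index (0-based). The
#' off-target series is the mean of the three non-assigned domains' z
#' series. The mood slope is sign-flipped so that a participant whose raw
#' depressed-mood ratings fall across phase 2 gets a positive
#' \code{mood_slope} (alleviation is positive).
#'
#' @param ema one participant's validated EMA data.frame (both phases).
#' @param assigned_domain the participant's intervention target domain.
#' @param catalog a \code{feature_catalog}.
#' @param max_phase2_emas optional cutoff: use only the first m phase-2
#'   EMAs (early-window variant).
#' @return one-row data.frame: slopes, phase-2 means and the inclusion flag
#'   (participants with < 3 phase-2 EMAs are flagged excluded).
#' @export
participant_slopes <- function(ema, assigned_domain, catalog,
                               max_phase2_emas = NULL) {
  stopifnot(assigned_domain %in% LIFESTYLE_DOMAINS)
  p1 <- ema$phase == "monitoring"
  p2 <- which(ema$phase == "intervention")
  if (!is.null(max_phase2_emas)) p2 <- utils::head(p2, max_phase2_emas)

  zser <- function(series, name) {
    phase_z(series, series[p1], name)
  }
  dom_z <- vapply(LIFESTYLE_DOMAINS, function(d) {
    zser(representative_metric(ema, catalog, d), d)
  }, numeric(nrow(ema)))
  mood_z <- zser(ema$mood, "mood")
  off <- rowMeans(dom_z[, setdiff(LIFESTYLE_DOMAINS, assigned_domain),
                        drop = FALSE], na.rm = TRUE)
  off[is.nan(off)] <- NA_real_

  n2 <- length(p2)
  sess <- seq_len(n2) - 1
  data.frame(
    participant_id = ema$participant_id[1],
    mood_slope = -z_slope(mood_z[p2], sess),  # positive = alleviation
    target_slope = z_slope(dom_z[p2, assigned_domain], sess),
    offtarget_slope = z_slope(off[p2], sess),
    n_phase2_emas = n2,
    mean_z_mood = mean(mood_z[p2], na.rm = TRUE),
    mean_z_target = mean(dom_z[p2, assigned_domain], na.rm = TRUE),
    mean_z_offtarget = mean(off[p2], na.rm = TRUE),
    excluded = n2 < 3,
    stringsAsFactors = FALSE)
}

#' Slopes for a whole cohort
#'
#' @param ema validated multi-participant EMA data.frame.
#' @param assignments data.frame with \code{participant_id} and
#'   \code{assigned}.
#' @param catalog a \code{feature_catalog}.
#' @param max_phase2_emas optional early-window cutoff.
#' @return data.frame of per-participant slope sets.
#' @export
cohort_slopes <- function(ema, assignments, catalog,
                          max_phase2_emas = NULL) {
  out <- lapply(assignments$participant_id, function(id) {
    e <- ema[ema$participant_id == id, , drop = FALSE]
    d <- assignments$assigned[assignments$participant_id == id]
    participant_slopes(e, d, catalog, max_phase2_emas)
  })
  do.call(rbind, out)
}

#' Intervention-specificity regression
#'
#' Tests whether improvement in depressed mood is predicted specifically by
#' change in the targeted lifestyle domain: robust linear regression
#' (iteratively reweighted least squares, bisquare weights, tuning constant
#' 4.685) of mood slope on target and off-target slopes, all three
#' standardized across participants so the coefficients are standardized
#' betas.
#'
#' @param slopes data.frame from \code{\link{cohort_slopes}}; excluded rows
#'   and rows with missing slopes are dropped.
#' @param min_n minimum participants required (10).
#' @return list with standardized \code{beta_target} and
#'   \code{beta_offtarget} (each with SE and p), the overall model F and p,
#'   and \code{n}.
#' @export
specificity_regression <- function(slopes, min_n = 10) {
  s <- slopes[!slopes$excluded &
                stats::complete.cases(slopes[c("mood_slope", "target_slope",
                                               "offtarget_slope")]), ]
  n <- nrow(s)
  if (n < min_n) stop_config("need >= %d participants with valid slopes, got %d",
                             min_n, n)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  d <- data.frame(mood = zs(s$mood_slope), target = zs(s$target_slope),
                  offtarget = zs(s$offtarget_slope))
  if (abs(stats::cor(d$target, d$offtarget)) > 0.99) {
    stop_config("target and off-target slopes are collinear (|r| > 0.99)")
  }
  fit <- MASS::rlm(mood ~ target + offtarget, data = d,
                   psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  sm <- summary(fit)
  co <- sm$coefficients
  se <- co[, "Std. Error"]
  tv <- co[, "t value"]
  df_res <- n - 3
  pvals <- 2 * stats::pt(-abs(tv), df_res)
  # Wald F over the two slope coefficients
  V <- sm$stddev^2 * sm$cov.unscaled
  b <- stats::coef(fit)[c("target", "offtarget")]
  Fstat <- as.numeric(t(b) %*% solve(V[2:3, 2:3]) %*% b) / 2
  list(beta_target = unname(stats::coef(fit)["target"]),
       se_target = unname(se["target"]),
       p_target = unname(pvals["target"]),
       beta_offtarget = unname(stats::coef(fit)["offtarget"]),
       se_offtarget = unname(se["offtarget"]),
       p_offtarget = unname(pvals["offtarget"]),
       F = Fstat, p_model = stats::pf(Fstat, 2, df_res, lower.tail = FALSE),
       n = n)
}
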