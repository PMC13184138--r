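# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# a feature_table built directly from a matrix (bypasses the aligner)
make_table <- function(X, dv, id = "T01", phase = NULL) {
  n <- nrow(X)
  structure(list(
    participant_id = id,
    timestamp = as.POSIXct("2023-01-02", tz = "UTC") + (seq_len(n) - 1) * 14400,
    phase = phase %||% rep("monitoring", n),
    session = seq_len(n), dv = dv, X = X,
    catalog = feature_catalog()
  ), class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fitted_n1 wrapper around an arbitrary prediction function, with
# identity-ish preprocessing fitted on the table
fake_model <- function(table, predict_fun, id = table$participant_id) {
  prep <- suppressWarnings(idiomood::preproc_fit(table))
  full <- idiomood::preproc_apply(table, prep)
  structure(list(
    participant_id = id, family = "fake", params = data.frame(),
    fold_mape = rep(0, 5), mean_mape = 0, accuracy = 100,
    prep = prep, fit = list(predict = predict_fun),
    feature_names = colnames(full$X)
  ), class = "fitted_n1")
}

# a shap_report constructed directly from desired feature importances
fake_report <- function(mean_abs_phi, direction = NULL, k = 10,
                        id = "T01", catalog = feature_catalog()) {
  feats <- names(mean_abs_phi)
  stopifnot(all(feats %in% catalog$entries$feature))
  ord <- order(-mean_abs_phi, feats)
  rank <- integer(length(feats)); rank[ord] <- seq_along(feats)
  names(rank) <- feats
  direction <- direction %||% stats::setNames(rep(1, length(feats)), feats)
  k <- min(k, length(feats))
  structure(list(
    participant_id = id, base_value = 4,
    phi = matrix(0, 1, length(feats), dimnames = list(NULL, feats)),
    mean_abs_phi = mean_abs_phi, rank = rank, direction = direction,
    top_k = feats[ord][seq_len(k)], k = k, method = "fake",
    catalog = catalog, prediction = 4
  ), class = "shap_report")
}

# a synthetic report + neutral-ish context whose top features come from a
# planted domain (for decision-algorithm tests; emulates what a planted
# simulant's explanation looks like)
planted_case <- function(target, seed, catalog = feature_catalog()) {
  set.seed(seed)
  feats <- catalog$entries$feature
  domains <- idiomood::catalog_domain(catalog, feats, for_scoring = TRUE)
  imp <- stats::setNames(abs(stats::rnorm(length(feats), 0, 0.04)), feats)
  in_t <- which(domains == target & catalog$entries$source == "ema")
  imp[in_t] <- abs(stats::rnorm(length(in_t), 0.3, 0.08))
  rep <- fake_report(imp, id = sprintf("S%03d", seed))
  ctx <- idiomood::neutral_context(rep)
  corr <- stats::setNames(pmin(imp * 2 + stats::rnorm(length(imp), 0, 0.05),
                               0.95), feats)
  ctx$mood_correlation <- pmax(corr, -0.95)
  list(report = rep, context = ctx, target = target)
}

# small two-phase EMA frame built by hand for slope tests
toy_two_phase_ema <- function(id = "P1", n1 = 20, n2 = 15,
                              mood_fun, item_funs) {
  n <- n1 + n2
  tp <- rep(c("monitoring", "intervention"), c(n1, n2))
  df <- data.frame(
    participant_id = id,
    timestamp = format(as.POSIXct("2023-01-02", tz = "UTC") +
                         (seq_len(n) - 1) * 86400, "%Y-%m-%dT%H:%M:%S"),
    phase = tp, mood = mood_fun(seq_len(n), tp),
    stringsAsFactors = FALSE)
  for (nm in names(item_funs)) df[[nm]] <- item_funs[[nm]](seq_len(n), tp)
  df
}
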