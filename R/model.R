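#' Mean absolute percentage error
#'
#' \code{100/n * sum(|y_true - y_pred| / |y_true|)}. The depressed-mood
#' rating scale starts at 1, so a zero true value signals a mis-specified
#' scale and raises an error rather than producing a silent infinity.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 1.
#' @return MAPE, in percent.
#' @export
mape <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  if (any(y_true == 0)) {
    stop_config("MAPE undefined: y_true contains zero; shift the rating scale so it excludes 0")
  }
  100 * mean(abs(y_true - y_pred) / abs(y_true))
}

#' Model specification for one family
#'
#' @param family one of \code{"ridge"}, \code{"elastic_net"},
#'   \code{"random_forest"}, \code{"gradient_boosted_trees"}.
#' @param grid data.frame of candidate hyperparameter rows; defaults per
#'   family are small on purpose so a 60-session fit stays fast.
#' @param n_folds outer cross-validation folds (5).
#' @param scheme \code{"blocked_time_series"} (contiguous session blocks,
#'   the default since EMA data are autocorrelated) or \code{"shuffled"}.
#' @param seed RNG seed for any stochastic fit.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(family, grid = default_grid(family), n_folds = 5,
                       scheme = c("blocked_time_series", "shuffled"),
                       seed = 1L) {
  family <- match.arg(family, FAMILY_ORDER)
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1, n_folds >= 2)
  structure(list(family = family, grid = grid, n_folds = n_folds,
                 scheme = scheme, seed = as.integer(seed)),
            class = "model_spec")
}

# fixed simplicity order used to break MAPE ties between families
FAMILY_ORDER <- c("ridge", "elastic_net", "random_forest",
                  "gradient_boosted_trees")

#' Default hyperparameter grid per family
#' @param family family name.
#' @return data.frame of candidate hyperparameters.
#' @export
default_grid <- function(family) {
  switch(family,
    ridge = data.frame(lambda = 10^seq(-3, 2, length.out = 8)),
    elastic_net = expand.grid(alpha = 0.5,
                              lambda = 10^seq(-3, 1, length.out = 8)),
    random_forest = expand.grid(num_trees = 300, max_depth = 4,
                                min_node_size = c(3, 5)),
    gradient_boosted_trees = expand.grid(nrounds = 150, eta = c(0.03, 0.1),
                                         max_depth = c(2, 4)),
    stop_config("unknown family '%s'", family))
}

#' Default roster of model specifications (all four families)
#' @param seed seed shared by the specs.
#' @param n_folds outer folds.
#' @return list of \code{model_spec}s in simplicity order.
#' @export
default_model_specs <- function(seed = 1L, n_folds = 5) {
  lapply(FAMILY_ORDER, model_spec, n_folds = n_folds, seed = seed)
}

#' Cross-validation fold indices
#'
#' Blocked time-series folds are contiguous session blocks preserving
#' temporal order (100 rows, 5 folds -> sessions 1-20, 21-40, ..., 81-100);
#' shuffled folds permute rows with the given seed.
#'
#' @param n number of rows.
#' @param k number of folds (each fold must keep >= 3 rows).
#' @param scheme fold scheme.
#' @param seed seed for the shuffled scheme.
#' @return list of integer index vectors, one per fold.
#' @export
cv_folds <- function(n, k, scheme = "blocked_time_series", seed = 1L) {
  if (k < 2 || k > n / 4) {
    stop_config("n_folds must be >= 2 and <= n_sessions/4 (n=%d, k=%d)", n, k)
  }
  bounds <- floor(seq_len(k) * n / k)
  starts <- c(1, utils::head(bounds, -1) + 1)
  idx <- if (scheme == "shuffled") {
    set.seed(seed)
    sample.int(n)
  } else seq_len(n)
  folds <- lapply(seq_len(k), function(i) sort(idx[starts[i]:bounds[i]]))
  if (any(vapply(folds, length, 1L) < 3)) {
    stop_config("a fold has fewer than 3 rows (n=%d, k=%d)", n, k)
  }
  folds
}

# ---- family back-ends ------------------------------------------------------

fit_family <- function(family, X, y, params, seed) {
  switch(family,
    ridge = ,
    elastic_net = {
      alpha <- if (family == "ridge") 0 else params$alpha
      fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = params$lambda,
                            standardize = FALSE)
      list(predict = function(newX) {
        as.numeric(glmnet::predict.glmnet(fit, newX, s = params$lambda))
      })
    },
    random_forest = {
      df <- data.frame(y = y, X, check.names = FALSE)
      fit <- ranger::ranger(
        y ~ ., data = df, num.trees = params$num_trees,
        max.depth = params$max_depth, min.node.size = params$min_node_size,
        seed = seed, num.threads = 1, respect.unordered.factors = TRUE)
      list(predict = function(newX) {
        stats::predict(fit, data.frame(newX, check.names = FALSE),
                       num.threads = 1)$predictions
      })
    },
    gradient_boosted_trees = {
      fit <- xgboost::xgboost(
        x = X, y = y, nrounds = params$nrounds,
        learning_rate = params$eta, max_depth = params$max_depth,
        objective = "reg:squarederror", nthreads = 1, verbosity = 0,
        seed = seed)
      list(predict = function(newX) {
        stats::predict(fit, newX)
      })
    },
    stop_config("unknown family '%s'", family))
}

# grid search minimizing blocked-CV MAPE on the given rows (inner CV)
tune_params <- function(table, spec, rows, inner_folds = 3) {
  sub <- ft_rows(table, rows)
  n <- length(sub$dv)
  k <- min(inner_folds, floor(n / 4))
  if (k < 2) {  # too few rows to tune: take the first (most regularized) row
    return(spec$grid[1, , drop = FALSE])
  }
  folds <- cv_folds(n, k, spec$scheme, spec$seed)
  scores <- vapply(seq_len(nrow(spec$grid)), function(g) {
    params <- spec$grid[g, , drop = FALSE]
    mean(vapply(folds, function(test_idx) {
      train_idx <- setdiff(seq_len(n), test_idx)
      prep <- suppressWarnings(preproc_fit(sub, train_idx))
      tr <- preproc_apply(ft_rows(sub, train_idx), prep)
      te <- preproc_apply(ft_rows(sub, test_idx), prep)
      fit <- fit_family(spec$family, tr$X, tr$dv, params, spec$seed)
      mape(te$dv, fit$predict(te$X))
    }, numeric(1)))
  }, numeric(1))
  spec$grid[which.min(scores), , drop = FALSE]
}

#' Nested cross-validation for one model family
#'
#' Outer folds follow the spec's scheme; within each outer training block,
#' hyperparameters are chosen by an inner blocked CV, the model is refit on
#' the whole training block, and the held-out fold's MAPE is recorded.
#' Imputation and standardization statistics are computed on training rows
#' only.
#'
#' @param table a \code{feature_table} (raw; preprocessing happens inside).
#' @param spec a \code{model_spec}.
#' @return list with \code{fold_mape} (one value per outer fold) and the
#'   per-fold chosen hyperparameters.
#' @export
cross_validate <- function(table, spec) {
  n <- length(table$dv)
  folds <- cv_folds(n, spec$n_folds, spec$scheme, spec$seed)
  per_fold <- lapply(folds, function(test_idx) {
    train_idx <- setdiff(seq_len(n), test_idx)
    params <- tune_params(table, spec, train_idx)
    prep <- suppressWarnings(preproc_fit(table, train_idx))
    tr <- preproc_apply(ft_rows(table, train_idx), prep)
    te <- preproc_apply(ft_rows(table, test_idx), prep)
    fit <- fit_family(spec$family, tr$X, tr$dv, params, spec$seed)
    list(mape = mape(te$dv, fit$predict(te$X)), params = params)
  })
  list(fold_mape = vapply(per_fold, `[[`, numeric(1), "mape"),
       fold_params = lapply(per_fold, `[[`, "params"))
}

#' Fit the best N-of-1 model for one participant
#'
#' Runs nested cross-validation for every candidate family, selects the
#' family with the lowest mean outer-fold MAPE (ties broken toward the
#' simpler family: ridge < elastic net < random forest < gradient boosted
#' trees), re-tunes hyperparameters on all rows and refits the final
#' predictor on the full table. Accuracy is reported as 100 - mean MAPE.
#'
#' @param table a \code{feature_table} with >= 30 rows (a warning is issued
#'   below 60, the session count the protocol is designed around).
#' @param specs list of \code{model_spec}s (default: all four families).
#' @param tie_tol mean-MAPE differences below this (percentage points) are
#'   treated as ties, which the simpler family wins; 0.01 points is far
#'   below fold-to-fold variability at 60 sessions.
#' @return an object of class \code{fitted_n1} with fields \code{family},
#'   \code{params}, \code{fold_mape}, \code{mean_mape}, \code{accuracy},
#'   the fitted predictor and preprocessing.
#' @export
fit_n_of_1 <- function(table, specs = default_model_specs(),
                       tie_tol = 0.01) {
  n <- length(table$dv)
  if (n < 30) stop_config("need >= 30 sessions to fit an N-of-1 model, got %d", n)
  if (n < 60) warning(sprintf("only %d sessions; the design targets 60", n),
                      call. = FALSE)
  if (any(table$dv == 0)) {
    stop_config("DV contains 0; MAPE is undefined - shift the rating scale")
  }
  cvs <- lapply(specs, function(sp) cross_validate(table, sp))
  means <- vapply(cvs, function(cv) mean(cv$fold_mape), numeric(1))
  fams <- vapply(specs, `[[`, "", "family")
  tied <- which(means <= min(means) + tie_tol)
  best <- tied[order(match(fams[tied], FAMILY_ORDER))][1]
  spec <- specs[[best]]

  params <- tune_params(table, spec, seq_len(n))
  prep <- suppressWarnings(preproc_fit(table))
  full <- preproc_apply(table, prep)
  fit <- fit_family(spec$family, full$X, full$dv, params, spec$seed)

  structure(list(
    participant_id = table$participant_id,
    family = spec$family, params = params,
    fold_mape = cvs[[best]]$fold_mape,
    mean_mape = means[best], accuracy = 100 - means[best],
    all_family_mape = stats::setNames(means, fams),
    prep = prep, fit = fit, feature_names = colnames(full$X),
    spec = spec
  ), class = "fitted_n1")
}

#' @export
print.fitted_n1 <- function(x, ...) {
  cat(sprintf("<fitted_n1> %s: %s, accuracy %.1f%% (MAPE %.1f%%, %d folds)\n",
              x$participant_id, x$family, x$accuracy, x$mean_mape,
              length(x$fold_mape)))
  invisible(x)
}

#' Predict mood from a fitted N-of-1 model
#' @param object a \code{fitted_n1}.
#' @param table a raw \code{feature_table} over the same feature set.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fitted_n1 <- function(object, table, ...) {
  tab <- preproc_apply(table, object$prep)
  if (!identical(colnames(tab$X), object$feature_names)) {
    stop_config("feature-set mismatch between model and table")
  }
  object$fit$predict(tab$X)
}

# predict directly from an already-preprocessed feature matrix
predict_matrix <- function(object, X) {
  if (!identical(colnames(X), object$feature_names)) {
    stop_config("feature-set mismatch between model and matrix")
  }
  object$fit$predict(X)
}
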