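#' Align EMA and watch streams onto the mood sampling grid
#'
#' Builds the model-ready, DV-aligned feature table for one participant:
#' every independent variable is aggregated or extrapolated to the timestamps
#' at which the dependent variable (the depressed-mood EMA rating) was
#' sampled. Watch attributes are aggregated over the half-open interval
#' (previous mood timestamp, current timestamp] per the catalog rule (the
#' first session uses a 24 h lookback); \code{last_value} items use the
#' rating reported in the same session; \code{carry_forward} items use the
#' most recent report within a 36 h staleness horizon. No feature ever uses
#' information recorded after its session timestamp.
#'
#' @param ema validated EMA data.frame (see \code{\link{read_ema}}).
#' @param watch validated watch data.frame (may be empty).
#' @param catalog a \code{feature_catalog}.
#' @param participant_id participant to align; defaults to the single
#'   participant present in \code{ema}.
#' @param carry_forward_hours staleness horizon for carry-forward items.
#' @param lookback_hours window before the first session.
#' @return an object of class \code{feature_table}: \code{dv} vector,
#'   \code{X} numeric matrix (sessions x features, NA = missing),
#'   \code{timestamp}, \code{phase}, \code{session} index and the catalog.
#' @export
align_features <- function(ema, watch, catalog, participant_id = NULL,
                           carry_forward_hours = 36, lookback_hours = 24) {
  if (is.null(participant_id)) {
    ids <- unique(ema$participant_id)
    if (length(ids) != 1) {
      stop_config("ema contains %d participants; pass participant_id",
                  length(ids))
    }
    participant_id <- ids
  }
  ema$timestamp <- as_instant(ema$timestamp)
  watch$timestamp <- as_instant(watch$timestamp)
  e <- ema[ema$participant_id == participant_id, , drop = FALSE]
  if (nrow(e) < 2) stop_config("need at least 2 DV observations, got %d",
                               nrow(e))
  w <- watch[watch$participant_id == participant_id, , drop = FALSE]
  if (nrow(w) == 0 && any(catalog$entries$source == "watch")) {
    warning(sprintf("participant %s absent from watch stream; watch features all-missing",
                    participant_id), call. = FALSE)
  }
  t_dv <- as.numeric(e$timestamp)
  n <- length(t_dv)
  prev <- c(t_dv[1] - lookback_hours * 3600, t_dv[-n])
  tw <- as.numeric(w$timestamp)

  entries <- catalog$entries
  X <- matrix(NA_real_, n, nrow(entries),
              dimnames = list(NULL, entries$feature))
  for (j in seq_len(nrow(entries))) {
    feat <- entries$feature[j]
    agg <- entries$aggregation[j]
    if (entries$source[j] == "watch") {
      if (nrow(w) == 0 || !feat %in% names(w)) next
      v <- w[[feat]]
      fun <- if (agg == "sum_since_prev") sum else mean
      X[, j] <- vapply(seq_len(n), function(i) {
        in_win <- tw > prev[i] & tw <= t_dv[i]
        if (!any(in_win)) NA_real_ else fun(v[in_win], na.rm = TRUE)
      }, numeric(1))
    } else {
      if (!feat %in% names(e)) next
      v <- e[[feat]]
      if (agg == "carry_forward") {
        last_val <- NA_real_
        last_t <- -Inf
        out <- numeric(n)
        for (i in seq_len(n)) {
          if (!is.na(v[i])) {
            last_val <- v[i]
            last_t <- t_dv[i]
          }
          out[i] <- if (t_dv[i] - last_t <= carry_forward_hours * 3600) {
            last_val
          } else NA_real_
        }
        X[, j] <- out
      } else {
        X[, j] <- v
      }
    }
  }
  structure(list(participant_id = participant_id,
                 timestamp = e$timestamp, phase = e$phase,
                 session = seq_len(n), dv = e$mood, X = X,
                 catalog = catalog),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d sessions x %d features (%.1f%% missing)\n",
              x$participant_id, length(x$dv), ncol(x$X),
              100 * mean(is.na(x$X))))
  invisible(x)
}

#' Subset a feature table by row
#' @param table a \code{feature_table}.
#' @param rows integer row indices to keep.
#' @return a \code{feature_table}.
#' @export
ft_rows <- function(table, rows) {
  table$timestamp <- table$timestamp[rows]
  table$phase <- table$phase[rows]
  table$session <- table$session[rows]
  table$dv <- table$dv[rows]
  table$X <- table$X[rows, , drop = FALSE]
  table
}

#' Fit imputation / standardization statistics on a training split
#'
#' The fit/transform split exists so that, inside cross-validation,
#' imputation medians and z-scoring statistics come from the training fold
#' only and never leak from held-out rows. Features that are all-missing or
#' constant (after imputation) on the fitting rows are flagged for dropping.
#'
#' @param table a \code{feature_table}.
#' @param rows rows to fit on (default: all).
#' @return an object of class \code{ft_preproc} with per-feature medians,
#'   means, sds and the retained feature set.
#' @export
preproc_fit <- function(table, rows = seq_along(table$dv)) {
  X <- table$X[rows, , drop = FALSE]
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  all_missing <- !is.finite(med)
  Ximp <- X
  for (j in seq_len(ncol(X))) Ximp[is.na(Ximp[, j]), j] <- med[j]
  mu <- colMeans(Ximp)
  sdv <- apply(Ximp, 2, stats::sd)
  constant <- !all_missing & (is.na(sdv) | sdv < 1e-12)
  keep <- !all_missing & !constant
  if (any(all_missing)) {
    warning(sprintf("dropping all-missing feature(s): %s",
                    paste(colnames(X)[all_missing], collapse = ", ")),
            call. = FALSE)
  }
  if (any(constant)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(colnames(X)[constant], collapse = ", ")),
            call. = FALSE)
  }
  structure(list(median = med, mean = mu, sd = sdv, keep = keep),
            class = "ft_preproc")
}

#' Apply fitted preprocessing to a feature table
#'
#' @param table a \code{feature_table}.
#' @param prep an \code{ft_preproc} from \code{\link{preproc_fit}}.
#' @return the table with \code{X} imputed, z-scored and restricted to the
#'   retained features; the DV is left on its native scale.
#' @export
preproc_apply <- function(table, prep) {
  X <- table$X
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- prep$median[j]
  X <- sweep(X, 2, prep$mean, "-")
  X <- sweep(X, 2, ifelse(prep$sd < 1e-12, 1, prep$sd), "/")
  table$X <- X[, prep$keep, drop = FALSE]
  table
}

#' Impute and standardize a feature table in one step
#'
#' Convenience wrapper fitting the preprocessing on all rows and applying it;
#' use the \code{\link{preproc_fit}} / \code{\link{preproc_apply}} pair when
#' training-fold-only statistics are required.
#'
#' @param table a \code{feature_table} (nonempty).
#' @return a model-ready \code{feature_table}.
#' @export
impute_and_standardize <- function(table) {
  if (length(table$dv) == 0) stop_config("empty feature table")
  preproc_apply(table, preproc_fit(table))
}
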