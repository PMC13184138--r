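#' Shapley-value explanation of a fitted N-of-1 model
#'
#' Attributes each session's predicted depressed mood additively to the model
#' features. The value function replaces features outside the coalition with
#' a single reference point (the per-feature median of the preprocessed
#' table), so local accuracy -- base value + sum of attributions = model
#' prediction -- holds to machine precision for every model family:
#' \itemize{
#'   \item \code{exact}: exhaustive enumeration over all 2^p coalitions
#'     (used automatically when p <= \code{exact_limit});
#'   \item \code{sampling}: permutation sampling with at least
#'     \code{min_draws} coalition evaluations (fixed seed); each sampled
#'     permutation telescopes, so additivity is preserved exactly.
#' }
#' Feature direction is the sign of the correlation between feature values
#' and their per-session attributions (+1: larger values push predictions
#' toward higher depressed mood), set to 0 when |correlation| < 0.1. The
#' attributions record associations, not causal relationships.
#'
#' @param model a \code{fitted_n1}.
#' @param table the raw \code{feature_table} the model was fitted on.
#' @param k number of top features to report (10).
#' @param method \code{"auto"}, \code{"exact"} or \code{"sampling"}.
#' @param exact_limit largest p for the exhaustive explainer (12).
#' @param min_draws minimum coalition evaluations for sampling (2048).
#' @param seed seed for the sampled permutations.
#' @return an object of class \code{shap_report}: \code{base_value},
#'   \code{phi} (sessions x features), \code{mean_abs_phi}, \code{rank}
#'   (1 = most important; ties broken lexically), \code{direction},
#'   \code{top_k}.
#' @export
explain <- function(model, table, k = 10, method = c("auto", "exact",
                                                     "sampling"),
                    exact_limit = 12, min_draws = 2048, seed = 1L) {
  method <- match.arg(method)
  tab <- preproc_apply(table, model$prep)
  X <- tab$X
  if (!identical(colnames(X), model$feature_names)) {
    stop_config("feature-set mismatch between model and table")
  }
  p <- ncol(X)
  n <- nrow(X)
  if (method == "auto") method <- if (p <= exact_limit) "exact" else "sampling"
  ref <- apply(X, 2, stats::median)

  phi <- if (method == "exact") {
    .shap_exact(model, X, ref)
  } else {
    .shap_sampling(model, X, ref, min_draws, seed)
  }
  colnames(phi) <- colnames(X)
  base_value <- as.numeric(predict_matrix(model, matrix(
    ref, nrow = 1, dimnames = list(NULL, colnames(X)))))

  mean_abs <- colMeans(abs(phi))
  ord <- order(-mean_abs, colnames(X))
  rank <- integer(p)
  rank[ord] <- seq_len(p)
  direction <- vapply(seq_len(p), function(j) {
    if (stats::sd(X[, j]) < 1e-12 || stats::sd(phi[, j]) < 1e-12) return(0)
    r <- stats::cor(X[, j], phi[, j])
    if (!is.finite(r) || abs(r) < 0.1) 0 else sign(r)
  }, numeric(1))

  k <- min(k, p)
  structure(list(
    participant_id = model$participant_id,
    base_value = base_value, phi = phi,
    mean_abs_phi = stats::setNames(mean_abs, colnames(X)),
    rank = stats::setNames(rank, colnames(X)),
    direction = stats::setNames(direction, colnames(X)),
    top_k = colnames(X)[ord][seq_len(k)], k = k,
    method = method, catalog = table$catalog,
    prediction = as.numeric(predict_matrix(model, X))
  ), class = "shap_report")
}

# exhaustive Shapley over all 2^p coalitions, single-reference value function
.shap_exact <- function(model, X, ref) {
  p <- ncol(X)
  n <- nrow(X)
  n_coal <- 2^p
  masks <- matrix(FALSE, n_coal, p)
  for (j in seq_len(p)) {
    masks[, j] <- bitwAnd(seq_len(n_coal) - 1L, bitwShiftL(1L, j - 1L)) > 0
  }
  sizes <- rowSums(masks)
  # Shapley kernel weight for adding feature j to a coalition of size s
  w <- 1 / (p * choose(p - 1, 0:(p - 1)))

  phi <- matrix(0, n, p)
  refmat <- matrix(ref, n_coal, p, byrow = TRUE)
  for (i in seq_len(n)) {
    Z <- refmat
    xi <- matrix(X[i, ], n_coal, p, byrow = TRUE)
    Z[masks] <- xi[masks]
    colnames(Z) <- colnames(X)
    v <- model$fit$predict(Z)
    for (j in seq_len(p)) {
      without <- !masks[, j]
      with_j <- which(without) + bitwShiftL(1L, j - 1L)
      phi[i, j] <- sum(w[sizes[without] + 1] * (v[with_j] - v[without]))
    }
  }
  phi
}

# permutation-sampling Shapley; each permutation's marginal contributions
# telescope to v(full) - v(empty), so additivity is exact
.shap_sampling <- function(model, X, ref, min_draws, seed) {
  p <- ncol(X)
  n <- nrow(X)
  n_perm <- max(ceiling(min_draws / p), 2)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(p), simplify = FALSE)

  phi <- matrix(0, n, p)
  for (i in seq_len(n)) {
    # rows: for each permutation, the p+1 prefix coalitions
    Z <- matrix(ref, n_perm * (p + 1), p, byrow = TRUE)
    row0 <- 0
    for (m in seq_len(n_perm)) {
      pi_m <- perms[[m]]
      for (s in seq_len(p)) {
        rows <- row0 + (s + 1):(p + 1)
        Z[rows, pi_m[s]] <- X[i, pi_m[s]]
      }
      row0 <- row0 + p + 1
    }
    colnames(Z) <- colnames(X)
    v <- model$fit$predict(Z)
    row0 <- 0
    for (m in seq_len(n_perm)) {
      dv <- diff(v[row0 + seq_len(p + 1)])
      phi[i, perms[[m]]] <- phi[i, perms[[m]]] + dv
      row0 <- row0 + p + 1
    }
  }
  phi / n_perm
}

#' @export
print.shap_report <- function(x, ...) {
  cat(sprintf("<shap_report> %s (%s explainer): top %d of %d features\n",
              x$participant_id, x$method, x$k, length(x$rank)))
  print(utils::head(top_k_table(x), x$k))
  invisible(x)
}

#' Rebuild a minimal Shapley report from a serialized top-k table
#'
#' Downstream domain assignment only consumes the ranked top-k features,
#' their importances and directions, so a report serialized to
#' \code{shap/<id>.json} can be rehydrated into an object usable by
#' \code{\link{naive_da}} and \code{\link{build_llm_prompt}}.
#'
#' @param top data.frame with columns \code{feature}, \code{mean_abs_phi},
#'   \code{direction} ordered by rank (as written by the pipeline).
#' @param participant_id participant id.
#' @param catalog the \code{feature_catalog} the features refer to.
#' @param base_value optional model base value.
#' @return a \code{shap_report} restricted to the top-k features.
#' @export
as_shap_report <- function(top, participant_id, catalog,
                           base_value = NA_real_) {
  k <- nrow(top)
  feats <- top$feature
  structure(list(
    participant_id = participant_id, base_value = base_value,
    phi = matrix(0, 0, k, dimnames = list(NULL, feats)),
    mean_abs_phi = stats::setNames(top$mean_abs_phi, feats),
    rank = stats::setNames(seq_len(k), feats),
    direction = stats::setNames(top$direction, feats),
    top_k = feats, k = k, method = "rehydrated", catalog = catalog,
    prediction = numeric(0)
  ), class = "shap_report")
}

#' Ranked top-k feature table from a Shapley report
#'
#' @param report a \code{shap_report}.
#' @param k how many features (default: the report's k).
#' @return data.frame (feature, domain, mean_abs_phi, direction) ordered by
#'   rank, with attribute \code{captured_fraction}: the share of total mean
#'   |phi| captured by the top k.
#' @export
top_k_table <- function(report, k = report$k) {
  p <- length(report$rank)
  if (k > p) stop_config("k = %d exceeds the %d available features", k, p)
  feats <- names(sort(report$rank))[seq_len(k)]
  total <- sum(report$mean_abs_phi)
  frac <- if (k == 0) 0 else if (total < 1e-300) {
    if (k == p) 1 else 0
  } else sum(report$mean_abs_phi[feats]) / total
  out <- data.frame(
    feature = feats,
    domain = catalog_domain(report$catalog, feats),
    mean_abs_phi = unname(report$mean_abs_phi[feats]),
    direction = unname(report$direction[feats]),
    stringsAsFactors = FALSE)
  attr(out, "captured_fraction") <- frac
  out
}
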