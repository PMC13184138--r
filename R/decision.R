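#' Participant context for intervention-domain assignment
#'
#' The decision algorithm weighs, besides the Shapley ranking itself, the
#' contextual criteria a human coach considers: whether the top predictors
#' independently correlate with depressed mood, whether the participant is
#' dissatisfied with a lifestyle domain (low satisfaction favors targeting
#' it), and whether intervening in the domain is feasible at all (e.g. a
#' fixed work sleep schedule rules out a sleep plan).
#'
#' @param satisfaction named numeric over the four domains, on the rating
#'   scale (higher = more satisfied).
#' @param feasibility named logical over the four domains (FALSE =
#'   constrained, cannot be targeted).
#' @param mood_correlation named numeric in [-1, 1]: independent correlation
#'   of each feature with depressed mood.
#' @return an object of class \code{participant_context}.
#' @export
participant_context <- function(satisfaction, feasibility, mood_correlation) {
  stopifnot(all(LIFESTYLE_DOMAINS %in% names(satisfaction)),
            all(LIFESTYLE_DOMAINS %in% names(feasibility)))
  if (any(abs(mood_correlation) > 1, na.rm = TRUE)) {
    stop_config("mood correlations must lie in [-1, 1]")
  }
  structure(list(satisfaction = satisfaction[LIFESTYLE_DOMAINS],
                 feasibility = feasibility[LIFESTYLE_DOMAINS],
                 mood_correlation = mood_correlation),
            class = "participant_context")
}

#' Neutral context (all domains feasible, mid-scale satisfaction)
#' @param report a \code{shap_report}; correlations default to 0 for its
#'   features.
#' @param satisfaction_mid mid-scale satisfaction value.
#' @return a \code{participant_context}.
#' @export
neutral_context <- function(report, satisfaction_mid = 4) {
  participant_context(
    satisfaction = stats::setNames(rep(satisfaction_mid, 4),
                                   LIFESTYLE_DOMAINS),
    feasibility = stats::setNames(rep(TRUE, 4), LIFESTYLE_DOMAINS),
    mood_correlation = stats::setNames(rep(0, length(report$rank)),
                                       names(report$rank)))
}

#' Decision-algorithm weights
#'
#' @param w_count weight of the count of a domain's features in the top k.
#' @param w_rank weight of the rank-position credit
#'   \code{sum (k + 1 - rank) / k} over the domain's top-k features.
#' @param w_corr weight of the strongest independent mood correlation among
#'   the domain's top-k features.
#' @param w_satisfaction weight of reported dissatisfaction with the domain.
#' @param feasibility_mode \code{"hard_exclude"} (infeasible domains can
#'   never be assigned) or \code{"penalty"}.
#' @param penalty score penalty applied in penalty mode.
#' @return an object of class \code{da_weights}.
#' @export
da_weights <- function(w_count = 1, w_rank = 0.5, w_corr = 1,
                       w_satisfaction = 0.5,
                       feasibility_mode = c("hard_exclude", "penalty"),
                       penalty = 1) {
  w <- c(w_count = w_count, w_rank = w_rank, w_corr = w_corr,
         w_satisfaction = w_satisfaction)
  if (any(w < 0) || all(w == 0)) {
    stop_config("weights must be nonnegative with at least one > 0")
  }
  structure(list(w = w, feasibility_mode = match.arg(feasibility_mode),
                 penalty = penalty), class = "da_weights")
}

# per-domain score components: rows = domains, cols = count / rank / corr /
# satisfaction. The raw material of both the naive and fine-tuned DA.
da_components <- function(report, context, k = report$k,
                          satisfaction_scale_max = 7) {
  top <- top_k_table(report, k)
  top$score_domain <- catalog_domain(report$catalog, top$feature,
                                     for_scoring = TRUE)
  ranks <- seq_len(nrow(top))
  C <- matrix(0, 4, 4, dimnames = list(LIFESTYLE_DOMAINS,
                                       c("count", "rank", "corr",
                                         "satisfaction")))
  for (d in LIFESTYLE_DOMAINS) {
    in_d <- which(!is.na(top$score_domain) & top$score_domain == d)
    C[d, "count"] <- length(in_d)
    if (length(in_d)) {
      C[d, "rank"] <- sum((k + 1 - ranks[in_d]) / k)
      corr <- abs(context$mood_correlation[top$feature[in_d]])
      C[d, "corr"] <- if (all(is.na(corr))) 0 else max(corr, na.rm = TRUE)
    }
    C[d, "satisfaction"] <-
      (satisfaction_scale_max - context$satisfaction[[d]]) /
      satisfaction_scale_max
  }
  C
}

# rank domains by score, breaking exact ties by the fixed order
# social > exercise > sleep > diet (a tie triggers a warning)
.rank_domains <- function(score, warn = TRUE) {
  ord <- order(-score, match(names(score), DOMAIN_TIEBREAK_ORDER))
  ranked <- names(score)[ord]
  if (warn && length(ranked) > 1 &&
      abs(score[ranked[1]] - score[ranked[2]]) < 1e-12) {
    warning(sprintf("domain scores tied at machine precision; fixed order picked '%s'",
                    ranked[1]), call. = FALSE)
  }
  ranked
}

#' Naive decision algorithm: Shapley ranking + context -> assigned domain
#'
#' Scores each lifestyle domain as a weighted sum of (i) how many of the
#' participant's top-k predictive features belong to it, (ii) how highly
#' those features rank, (iii) the strongest independent mood correlation
#' among them, and (iv) reported dissatisfaction with the domain; infeasible
#' domains are excluded (or penalized). Watch features count toward the
#' exercise domain. The assigned domain is the top-scoring feasible domain;
#' exact ties fall back to the fixed order social > exercise > sleep > diet.
#'
#' @param report a \code{shap_report} with at least one top-k feature.
#' @param context a \code{participant_context}.
#' @param weights a \code{da_weights}.
#' @param k number of top features considered (the report's k).
#' @param satisfaction_scale_max top of the satisfaction rating scale.
#' @return an object of class \code{domain_assignment}: per-domain
#'   \code{score}, \code{ranking}, \code{assigned} and a \code{rationale}
#'   matrix of the score components.
#' @export
naive_da <- function(report, context, weights = da_weights(),
                     k = report$k, satisfaction_scale_max = 7) {
  if (report$k < 1) stop_config("report has no top-k features")
  C <- da_components(report, context, k, satisfaction_scale_max)
  score <- as.numeric(C %*% weights$w)
  names(score) <- rownames(C)
  feasible <- vapply(LIFESTYLE_DOMAINS, function(d)
    isTRUE(context$feasibility[[d]]), logical(1))
  if (weights$feasibility_mode == "penalty") {
    score[!feasible] <- score[!feasible] - weights$penalty
    feasible[] <- TRUE
  }
  if (!any(feasible)) {
    stop_config("all domains infeasible; manual review required")
  }
  ranking <- .rank_domains(score)
  assigned <- ranking[ranking %in% names(score)[feasible]][1]
  structure(list(participant_id = report$participant_id, score = score,
                 ranking = ranking, assigned = assigned, rationale = C,
                 weights = weights), class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat(sprintf("<domain_assignment> %s -> %s (%s)\n", x$participant_id,
              x$assigned,
              paste(sprintf("%s %.2f", names(sort(-x$score)),
                            sort(x$score, decreasing = TRUE)),
                    collapse = ", ")))
  invisible(x)
}

#' Fine-tune the decision-algorithm weights against coach labels
#'
#' Exhaustive search over the declared weight grid maximizing agreement with
#' the coach-assigned domains; ties prefer the smallest weights (by sum,
#' then lexicographically), a mild regularization. Reports the in-sample
#' match rate and a leave-one-out match rate; the in-sample rate is overfit
#' to the labeled sample and flagged as optimistic.
#'
#' @param training list of cases, each a list with elements \code{report}
#'   (\code{shap_report}), \code{context} (\code{participant_context}) and
#'   \code{label} (coach-assigned domain). At least 10 cases.
#' @param weight_grid named list of candidate values for \code{w_count},
#'   \code{w_rank}, \code{w_corr}, \code{w_satisfaction}.
#' @param feasibility_mode passed to the resulting \code{da_weights}.
#' @param satisfaction_scale_max top of the satisfaction scale.
#' @return list with \code{weights} (a \code{da_weights}),
#'   \code{match_rate}, \code{loo_match_rate} and \code{n}.
#' @export
fine_tune_da <- function(training,
                         weight_grid = list(
                           w_count = c(0, 0.5, 1, 2),
                           w_rank = c(0, 0.5, 1, 2),
                           w_corr = c(0, 0.5, 1, 2),
                           w_satisfaction = c(0, 0.5, 1, 2)),
                         feasibility_mode = "hard_exclude",
                         satisfaction_scale_max = 7) {
  n <- length(training)
  if (n < 10) stop_config("need at least 10 labeled cases, got %d", n)
  G <- as.matrix(expand.grid(weight_grid))
  G <- G[rowSums(G) > 0, , drop = FALSE]
  if (nrow(G) == 1) {
    warning("degenerate single-point weight grid", call. = FALSE)
  }
  labels <- vapply(training, `[[`, "", "label")

  # precompute per-case components and feasibility, then sweep the grid
  assigned <- matrix("", n, nrow(G))
  for (i in seq_len(n)) {
    case <- training[[i]]
    C <- da_components(case$report, case$context,
                       satisfaction_scale_max = satisfaction_scale_max)
    feas <- vapply(LIFESTYLE_DOMAINS, function(d)
      isTRUE(case$context$feasibility[[d]]), logical(1))
    S <- C %*% t(G)  # 4 domains x grid points
    if (feasibility_mode == "hard_exclude") {
      if (!any(feas)) stop_config("all domains infeasible for case %d", i)
      S[!feas, ] <- -Inf
    }
    tb <- match(LIFESTYLE_DOMAINS, DOMAIN_TIEBREAK_ORDER)
    assigned[i, ] <- apply(S, 2, function(s) {
      LIFESTYLE_DOMAINS[order(-s, tb)][1]
    })
  }
  match_mat <- assigned == labels

  pick_best <- function(rows) {
    rate <- colMeans(match_mat[rows, , drop = FALSE])
    best <- which(rate == max(rate))
    best[order(rowSums(G[best, , drop = FALSE]),
               G[best, 1], G[best, 2], G[best, 3], G[best, 4])][1]
  }
  best <- pick_best(seq_len(n))
  loo <- vapply(seq_len(n), function(i) {
    match_mat[i, pick_best(setdiff(seq_len(n), i))]
  }, logical(1))

  w <- G[best, ]
  list(weights = da_weights(w[["w_count"]], w[["w_rank"]], w[["w_corr"]],
                            w[["w_satisfaction"]],
                            feasibility_mode = feasibility_mode),
       match_rate = mean(match_mat[, best]),
       loo_match_rate = mean(loo), n = n,
       note = "in-sample match rate is optimistic (weights overfit to the labeled sample)")
}

#' Agreement between two sets of domain assignments
#'
#' @param assignments_a,assignments_b data.frames with columns
#'   \code{participant_id} and \code{assigned} over the same participants.
#' @return list with \code{percent} (100 * matches / n), \code{matches},
#'   \code{n} and a 4 x 4 \code{confusion} table (a rows x b columns).
#' @export
agreement <- function(assignments_a, assignments_b) {
  a <- assignments_a[order(assignments_a$participant_id), ]
  b <- assignments_b[order(assignments_b$participant_id), ]
  if (!identical(a$participant_id, b$participant_id)) {
    stop_config("assignment sets cover different participants")
  }
  fa <- factor(a$assigned, levels = LIFESTYLE_DOMAINS)
  fb <- factor(b$assigned, levels = LIFESTYLE_DOMAINS)
  m <- sum(fa == fb)
  list(percent = 100 * m / nrow(a), matches = m, n = nrow(a),
       confusion = table(a = fa, b = fb))
}

#' Build a deterministic LLM prompt for domain assignment
#'
#' Embeds the participant's top-k Shapley table, satisfaction and
#' feasibility context and the four-domain taxonomy into an instruction
#' asking for exactly one domain plus a rationale. Pure text construction;
#' no network call is made.
#'
#' @param report a \code{shap_report}.
#' @param context a \code{participant_context}.
#' @param satisfaction_scale_max top of the satisfaction scale.
#' @return a single prompt string.
#' @export
build_llm_prompt <- function(report, context, satisfaction_scale_max = 7) {
  top <- top_k_table(report)
  feat_lines <- sprintf("%d. %s | domain=%s | importance=%.6f | direction=%+d",
                        seq_len(nrow(top)), top$feature, top$domain,
                        top$mean_abs_phi, as.integer(top$direction))
  sat_lines <- sprintf("- %s: satisfaction %s/%d, feasible: %s",
                       LIFESTYLE_DOMAINS,
                       vapply(LIFESTYLE_DOMAINS, function(d)
                         format(context$satisfaction[[d]]), ""),
                       satisfaction_scale_max,
                       vapply(LIFESTYLE_DOMAINS, function(d)
                         ifelse(isTRUE(context$feasibility[[d]]), "yes",
                                "no"), ""))
  paste(c(
    "You are assisting a behavioral health coach.",
    sprintf("Participant %s completed a mood and lifestyle monitoring phase.",
            report$participant_id),
    "An individualized model ranked the features most predictive of this participant's depressed mood (Shapley importance; direction +1 means larger values predict worse mood, -1 better mood, 0 unclear).",
    "",
    "TOP PREDICTIVE FEATURES:",
    feat_lines,
    "",
    "PARTICIPANT CONTEXT:",
    sat_lines,
    "",
    "The four candidate intervention domains are: sleep, exercise, diet, social.",
    "Choose the single lifestyle domain whose targeted intervention is most likely to improve this participant's mood, considering feature importance, independent correlations with mood, satisfaction, and feasibility.",
    "Answer with exactly one domain name from the taxonomy on the first line, followed by a short rationale."
  ), collapse = "\n")
}

#' Parse the feature table back out of a generated prompt
#'
#' Round-trip extractor for \code{\link{build_llm_prompt}}; recovers the
#' embedded top-k table (used to verify prompts are lossless).
#'
#' @param prompt prompt string.
#' @return data.frame (feature, domain, mean_abs_phi, direction).
#' @export
parse_llm_prompt <- function(prompt) {
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  rows <- grep("^\\d+\\. .* \\| domain=", lines, value = TRUE)
  parts <- regmatches(rows, regexec(
    "^\\d+\\. (.*) \\| domain=(.*) \\| importance=([-0-9.e+]+) \\| direction=([+-]\\d+)$",
    rows))
  data.frame(
    feature = vapply(parts, `[[`, "", 2),
    domain = vapply(parts, `[[`, "", 3),
    mean_abs_phi = as.numeric(vapply(parts, `[[`, "", 4)),
    direction = as.numeric(vapply(parts, `[[`, "", 5)),
    stringsAsFactors = FALSE)
}
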