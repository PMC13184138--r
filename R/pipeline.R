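PIPELINE_STAGES <- c("simulate", "features", "fit", "explain", "assign",
                     "slopes", "outcomes")

# dependency of each stage on in-memory products of earlier stages
.stage_needs <- list(
  simulate = character(0),
  features = "simulate",
  fit = "features",
  explain = "fit",
  assign = "explain",
  slopes = c("simulate", "assign"),
  outcomes = c("simulate", "assign")
)

config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(obj), f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> features -> fit -> explain -> assign -> slopes
#' -> outcomes, writing each stage's artifacts under \code{out_dir} and a
#' run manifest (config hash, seed, per-stage outputs). The master seed
#' fans out deterministically to per-participant sub-seeds, so results do
#' not depend on processing order, and rerunning with the same seed
#' reproduces identical artifacts. Requesting a stage whose in-memory
#' dependency was not produced in the same call raises a named error before
#' any work is done.
#'
#' @param out_dir output directory.
#' @param n_participants cohort size (40).
#' @param scenario a \code{sim_scenario}.
#' @param seed master seed.
#' @param stages ordered subset of the seven stages.
#' @param specs model specifications for the fit stage.
#' @param catalog a \code{feature_catalog}.
#' @param weights \code{da_weights} for the assignment stage.
#' @param k top-k features for the explanation stage.
#' @return the run manifest (invisibly), with per-stage summaries.
#' @export
run_pipeline <- function(out_dir, n_participants = 40,
                         scenario = sim_scenario(), seed = 1L,
                         stages = PIPELINE_STAGES,
                         specs = NULL, catalog = feature_catalog(),
                         weights = da_weights(), k = 10) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  for (st in stages) {
    unmet <- setdiff(.stage_needs[[st]], stages)
    if (length(unmet)) {
      stop_config("stage '%s' requires stage(s) %s in the same run", st,
                  paste(sprintf("'%s'", unmet), collapse = ", "))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(n_participants = n_participants,
              scenario = unclass(scenario), seed = seed, stages = stages,
              k = k)
  hash <- config_hash(cfg)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(config_hash = unname(hash), seed = seed, stages = list())

  env <- new.env()
  timing <- c()
  for (st in stages) {
    t0 <- Sys.time()
    out_files <- switch(st,
      simulate = {
        env$cohort <- simulate_cohort(n_participants, scenario,
                                      master_seed = seed, catalog = catalog)
        write_cohort(env$cohort, out_dir)
        c("ema.csv", "watch.csv", "outcomes.csv", "truth.json")
      },
      features = {
        ids <- unique(env$cohort$ema$participant_id)
        p1 <- env$cohort$ema[env$cohort$ema$phase == "monitoring", ]
        env$tables <- lapply(ids, function(id) {
          align_features(p1, env$cohort$watch, catalog, id)
        })
        names(env$tables) <- ids
        dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
        for (id in ids) {
          tab <- env$tables[[id]]
          utils::write.csv(
            data.frame(session = tab$session, dv = tab$dv, tab$X,
                       check.names = FALSE),
            file.path(out_dir, "features", paste0(id, ".csv")),
            row.names = FALSE)
        }
        file.path("features", paste0(ids, ".csv"))
      },
      fit = {
        sp <- specs %||% default_model_specs(seed = seed)
        env$models <- lapply(env$tables, function(tab) {
          suppressWarnings(fit_n_of_1(tab, sp))
        })
        mdf <- do.call(rbind, lapply(env$models, function(m) {
          data.frame(participant_id = m$participant_id, family = m$family,
                     mean_mape = m$mean_mape, accuracy = m$accuracy,
                     stringsAsFactors = FALSE)
        }))
        utils::write.csv(mdf, file.path(out_dir, "models.csv"),
                         row.names = FALSE)
        "models.csv"
      },
      explain = {
        env$reports <- lapply(names(env$models), function(id) {
          explain(env$models[[id]], env$tables[[id]], k = k,
                  seed = split_seed(seed, match(id, names(env$models))))
        })
        names(env$reports) <- names(env$models)
        dir.create(file.path(out_dir, "shap"), showWarnings = FALSE)
        for (id in names(env$reports)) {
          rep <- env$reports[[id]]
          top <- top_k_table(rep)
          jsonlite::write_json(
            list(participant_id = id, base_value = rep$base_value,
                 method = rep$method,
                 captured_fraction = attr(top, "captured_fraction"),
                 top_k = top),
            file.path(out_dir, "shap", paste0(id, ".json")),
            dataframe = "rows", auto_unbox = TRUE, digits = NA)
        }
        file.path("shap", paste0(names(env$reports), ".json"))
      },
      assign = {
        env$assignments <- do.call(rbind, lapply(names(env$reports),
                                                 function(id) {
          rep <- env$reports[[id]]
          tab <- preproc_apply(env$tables[[id]], env$models[[id]]$prep)
          corr <- vapply(seq_len(ncol(tab$X)), function(j) {
            if (stats::sd(tab$X[, j]) < 1e-12) return(0)
            stats::cor(tab$X[, j], tab$dv)
          }, numeric(1))
          names(corr) <- colnames(tab$X)
          ctx <- neutral_context(rep)
          ctx$mood_correlation <- corr
          da <- suppressWarnings(naive_da(rep, ctx, weights))
          data.frame(participant_id = id, assigned = da$assigned,
                     t(da$score), stringsAsFactors = FALSE)
        }))
        names(env$assignments)[3:6] <- paste0("score_", LIFESTYLE_DOMAINS)
        utils::write.csv(env$assignments,
                         file.path(out_dir, "assignments.csv"),
                         row.names = FALSE)
        "assignments.csv"
      },
      slopes = {
        env$slopes <- cohort_slopes(env$cohort$ema, env$assignments,
                                    catalog)
        utils::write.csv(env$slopes, file.path(out_dir, "slopes.csv"),
                         row.names = FALSE)
        spec_res <- tryCatch(specificity_regression(env$slopes),
                             error = function(e) list(error = conditionMessage(e)))
        jsonlite::write_json(spec_res, file.path(out_dir,
                                                 "specificity.json"),
                             auto_unbox = TRUE, digits = NA)
        env$specificity <- spec_res
        c("slopes.csv", "specificity.json")
      },
      outcomes = {
        oc <- env$cohort$outcomes
        oc$timepoint <- factor(oc$timepoint, levels = OUTCOME_TIMEPOINTS,
                               ordered = TRUE)
        oc <- interpolate_missing(oc, "PHQ9")
        stats_out <- outcome_report(oc, env$assignments)
        jsonlite::write_json(stats_out,
                             file.path(out_dir, "outcome_stats.json"),
                             auto_unbox = TRUE, digits = NA)
        env$outcome_stats <- stats_out
        "outcome_stats.json"
      })
    timing[st] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[st]] <- list(outputs = as.list(out_files),
                                  seconds = round(timing[[st]], 2))
  }
  manifest$versions <- list(
    package = as.character(utils::packageVersion("idiomood")),
    r = R.version.string)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(manifest, list(env = env)))
}

#' Standard outcome analysis report for a cohort
#'
#' Runs the outcome battery: Friedman repeated-measures test (with the
#' parametric companion) on PHQ9 across screening-to-post, signed-rank
#' post-hocs against pre, paired effect sizes for every instrument, the
#' normality-gated paired test for pre/post-only instruments, and the
#' rank-based intervention-domain covariate check.
#'
#' @param outcomes outcome data.frame (PHQ9 interior timepoints imputed).
#' @param assignments data.frame with participant_id and assigned domain.
#' @return nested list of results.
#' @export
outcome_report <- function(outcomes, assignments = NULL) {
  phq_tp <- c("screening", "pre", "GS1", "GS3", "GS5", "post")
  res <- list()
  res$phq9_friedman <- friedman_rm(outcomes, "PHQ9", phq_tp)
  res$phq9_posthoc <- signed_rank_posthoc(outcomes, "PHQ9")
  M <- outcome_matrix(outcomes, "PHQ9", c("pre", "post"))
  res$phq9_d <- cohens_d_paired(M[, "pre"], M[, "post"])
  for (instr in c("GAD7", "HDRS", "MCS12", "MAAS")) {
    Mi <- outcome_matrix(outcomes, instr, c("pre", "post"))
    ok <- stats::complete.cases(Mi)
    if (sum(ok) >= 5) {
      res[[paste0(tolower(instr), "_d")]] <-
        cohens_d_paired(Mi[ok, "pre"], Mi[ok, "post"])
      res[[paste0(tolower(instr), "_gate")]] <-
        suppressWarnings(paired_gate(Mi[ok, "pre"], Mi[ok, "post"]))
    }
  }
  if (!is.null(assignments)) {
    ids <- intersect(rownames(M), assignments$participant_id)
    change <- M[ids, "post"] - M[ids, "pre"]
    dom <- assignments$assigned[match(ids, assignments$participant_id)]
    res$domain_covariate <- domain_covariate_check(change, dom)
  }
  res
}
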