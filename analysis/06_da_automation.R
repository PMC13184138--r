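#!/usr/bin/env Rscript
# Stage 6: automating the intervention-domain assignment.
#
# The naive decision algorithm is a transparent scoring equation over the
# Shapley top-10 (feature counts, rank credit, independent mood
# correlations, satisfaction, feasibility). Here its weights are
# empirically fine-tuned against "coach" labels (the naive assignments
# with 10% label noise standing in for human judgment variability), and a
# deterministic LLM prompt is built per participant for an external
# assistant; no network call is made.

library(idiomood)

seed <- 20260919
catalog <- feature_catalog()
assignments <- read.csv("results/assignments.csv")
ids <- assignments$participant_id

cases <- lapply(seq_along(ids), function(i) {
  j <- jsonlite::read_json(sprintf("results/shap/%s.json", ids[i]),
                           simplifyVector = TRUE)
  rep <- as_shap_report(j$top_k, ids[i], catalog, j$base_value)
  ctx <- neutral_context(rep)
  list(report = rep, context = ctx,
       label = assignments$assigned[i])
})

set.seed(split_seed(seed, 6))
flip <- sample(length(cases), round(0.1 * length(cases)))
for (i in flip) {
  cases[[i]]$label <- sample(setdiff(c("sleep", "exercise", "diet",
                                       "social"), cases[[i]]$label), 1)
}
naive_match <- mean(vapply(cases, function(cs) {
  suppressWarnings(naive_da(cs$report, cs$context,
                            da_weights()))$assigned == cs$label
}, logical(1)))
ft <- fine_tune_da(cases)

dir.create("results/prompts", showWarnings = FALSE)
for (cs in cases[1:4]) {
  writeLines(build_llm_prompt(cs$report, cs$context),
             sprintf("results/prompts/prompt_%s.txt",
                     cs$report$participant_id))
}

cat(sprintf("Naive DA match with noisy coach labels: %.1f%% (%d of %d)\n",
            100 * naive_match, round(naive_match * length(cases)),
            length(cases)))
cat(sprintf("Fine-tuned DA: in-sample %.1f%%, leave-one-out %.1f%% (%s)\n",
            100 * ft$match_rate, 100 * ft$loo_match_rate, ft$note))
cat(sprintf("Fine-tuned weights: count %.2f, rank %.2f, corr %.2f, satisfaction %.2f\n",
            ft$weights$w["w_count"], ft$weights$w["w_rank"],
            ft$weights$w["w_corr"], ft$weights$w["w_satisfaction"]))
cat("Example prompts written to results/prompts\n")
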