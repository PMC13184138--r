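#!/usr/bin/env Rscript
# Stage 5: clinical, behavioral and cognitive outcome statistics.
#
# PHQ9 interior missing timepoints are linearly interpolated per
# participant (follow-ups are never imputed); change from screening to
# post-intervention is tested with Friedman's repeated-measures test (plus
# the parametric companion with Mauchly / Greenhouse-Geisser), signed-rank
# post-hocs against pre with BH-FDR, paired Cohen's d with noncentral-t
# CIs for every instrument, the normality-gated paired test for
# pre/post-only instruments, robust regression of primary change on
# secondary changes, and baseline remission contrasts.

library(idiomood)

outcomes <- read_outcomes("results/cohort/outcomes.csv")
assignments <- read.csv("results/assignments.csv")

outcomes <- interpolate_missing(outcomes, "PHQ9")
report <- outcome_report(outcomes, assignments)
jsonlite::write_json(report, "results/outcome_stats.json",
                     auto_unbox = TRUE, digits = NA)

fr <- report$phq9_friedman
cat(sprintf("PHQ9 Friedman chi2(df = %d) = %.1f, p = %.2g (n = %d)\n",
            fr$df, fr$chisq, fr$p, fr$n))
cat(sprintf("  parametric companion: F = %.1f, GG-corrected p = %.2g (epsilon %.2f, Mauchly p = %.2g)\n",
            fr$rm_anova$F, fr$rm_anova$p_gg, fr$rm_anova$gg_epsilon,
            fr$rm_anova$mauchly_p))
cat(sprintf("PHQ9 pre->post: d = %.2f, 95%% CI [%.2f, %.2f], p = %.2g\n",
            report$phq9_d$d, report$phq9_d$ci[1], report$phq9_d$ci[2],
            report$phq9_d$p))
for (instr in c("gad7", "hdrs", "mcs12", "maas")) {
  es <- report[[paste0(instr, "_d")]]
  gate <- report[[paste0(instr, "_gate")]]
  if (!is.null(es)) {
    cat(sprintf("%s: d = %.2f CI [%.2f, %.2f]; gate chose %s (p = %.2g)\n",
                toupper(instr), es$d, es$ci[1], es$ci[2], gate$test,
                gate$p))
  }
}
cat(sprintf("Domain covariate (Kruskal-Wallis on PHQ9 change): p = %.2f\n",
            report$domain_covariate$p))

# remission contrasts against baseline measures
M_pre <- outcomes[outcomes$instrument == "GAD7" &
                    outcomes$timepoint == "pre", ]
baseline <- data.frame(participant_id = M_pre$participant_id,
                       GAD7 = M_pre$score)
rc <- remission_contrast(outcomes, baseline)
cat(sprintf("Remission (post PHQ9 < 5): %d of %d (%.0f%%); responders: %d\n",
            rc$n_remitted, rc$n, 100 * rc$n_remitted / rc$n,
            rc$n_responder))

cat(sprintf("A priori minimum detectable paired effect at n = 40: d = %.2f\n",
            min_detectable_d(40)))
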