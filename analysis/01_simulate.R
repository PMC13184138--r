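#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# 40 participants complete the two-phase protocol: a digital monitoring
# phase (60 EMAs at up to 4/day, 2 h refractory gap, over 2-4 weeks, plus
# continuous smartwatch sampling) followed by a 6-week intervention phase
# with once-daily EMAs. Each participant has one planted dominant
# lifestyle-mood coupling; the planted domain is the ground truth that the
# rest of the analysis chain tries to recover.

library(idiomood)

seed <- 20260919
coh <- simulate_cohort(40, scenario = sim_scenario(), master_seed = seed)
write_cohort(coh, "results/cohort")

cat("Cohort written to results/cohort\n")
cat(sprintf("  EMA rows: %d (%d monitoring / %d intervention)\n",
            nrow(coh$ema), sum(coh$ema$phase == "monitoring"),
            sum(coh$ema$phase == "intervention")))
cat(sprintf("  watch rows: %d; outcome rows: %d\n",
            nrow(coh$watch), nrow(coh$outcomes)))
cat("  planted target domains:\n")
print(table(coh$truth$target_domain))
p2 <- table(coh$ema$participant_id[coh$ema$phase == "intervention"])
cat(sprintf("  phase-2 EMAs per participant: %.1f +/- %.1f of 42\n",
            mean(p2), sd(p2)))
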