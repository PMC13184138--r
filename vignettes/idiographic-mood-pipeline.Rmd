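---
title: "Idiographic mood modeling and personalized lifestyle intervention analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Idiographic mood modeling and personalized lifestyle intervention analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Lifestyle factors — sleep, exercise, diet, social connection — are coupled
to depressed mood, but *which* factor matters most differs sharply across
individuals. A nomothetic (population-pooled) model averages those couplings
away. The idiographic alternative models each person separately: collect a
dense per-person time series of momentary mood and lifestyle reports
(ecological momentary assessment, EMA) plus passive smartwatch data, fit an
N-of-1 predictive model of depressed mood, read the dominant predictors off
a Shapley decomposition, and target the behavioral intervention at the
lifestyle domain those predictors implicate. `idiomood` implements that full
chain — simulation, ingestion, feature alignment, N-of-1 model selection,
Shapley ranking, domain assignment, phase-2 slope specificity analysis, and
the repeated-measures outcome statistics — as composable, tested R
functions, with numbered drivers under `analysis/` reproducing the workflow
end to end.

Because no participant-level dataset ships with the package, the first-class
entry point is a synthetic cohort generator with *planted ground truth*:
every downstream stage can therefore be scored against a known answer.

## The synthetic cohort: what it emulates

`simulate_cohort()` reproduces the two-phase study design:

* **Phase 1 (monitoring).** Notifications at 08:00/12:00/16:00/20:00; each
  is answered with probability 0.85 (the protocol fixes 4 notifications/day
  and a 60-session quota; perfect compliance would always finish in exactly
  15 days, so a response probability is the minimal mechanism that spreads
  completion over the realistic 2–4-week range). Responses jitter ±45 min
  around the notification; the jitter is bounded so the app's 2 h
  refractory rule can never be violated, and the generator refuses
  schedules for which that cannot be guaranteed.
* **Latent behavior.** Each lifestyle domain has a latent z-scored behavior
  series following a stationary AR(1) with ρ = 0.5 across sessions — enough
  autocorrelation that blocked cross-validation genuinely matters, without
  long-memory structure.
* **Mood model.** The depressed-mood rating is
  `clip(round(baseline + Σ_d coupling_d · z_d + ε))` on a 1–7 integer scale,
  ε ~ N(0, noise_sd). By default the planted target domain has coupling
  −(1.2–1.8) (healthier behavior → less depressed mood) and off-target
  domains ±0.25; `noise_sd = 0.4`. Exactly one domain carries the maximum
  absolute coupling by construction. Clipping and rounding attenuate
  regression estimates slightly; the generator exposes
  `round_ratings = FALSE` for exact-identity checks.
* **EMA items.** Sixteen items (four per domain) are noisy oriented
  reflections of their domain's latent z. Momentary items are probed at
  every session; `sleep_duration` is a morning question probed once per
  day and carried forward by the aligner (36 h horizon). An early design
  probed *all* sleep items daily; that systematically starved sleep-planted
  participants of model credit because a once-a-day item cannot express the
  session-level latent it is coupled to, so only the genuinely daily
  quantity retains daily probing.
* **Phase 2 (intervention).** Once-daily EMAs for 42 days, skipped with
  probability 0.35 (matching roughly two-thirds completion of daily EMAs
  over six weeks). The target domain's latent mean drifts upward by
  0.03 z per phase-2 day; off-target domains do not drift. Clinical outcome
  trajectories (PHQ9, GAD7, HDRS, MCS12, MAAS, cognitive efficiencies) are
  baseline + improvement proportional to the cumulative target-domain
  change + noise, with 6/12-week follow-ups missing at 30%/45%.
* **Watch stream.** Heart rate and step attributes on a 30-min grid, with
  step intensity coupled to the day's exercise z — a plausibility
  surrogate, not a sensor model.

What the generator does **not** emulate: nonstationary baselines, weekday
structure, measurement reactivity, item-specific response styles, floor
effects in severely depressed ranges, or sensor artifacts. Passing tests on
this cohort show the *machinery* is correct and calibrated; they do not
certify performance on real data.

## N-of-1 model selection

Four families compete per participant: ridge, elastic net, random forest,
gradient-boosted trees. Hyperparameter grids are deliberately tiny (λ
log-grids; ≤ 300 trees, depth ≤ 4, learning rate {0.03, 0.1}) so a
60-session fit stays in seconds. The harness is nested cross-validation
with **blocked time-series folds** (contiguous session blocks; EMA data are
autocorrelated, and shuffled folds would leak temporal structure — a
shuffled scheme remains available for comparison). Imputation medians and
z-scoring statistics are computed on training folds only, via an explicit
fit/transform pair (`preproc_fit()` / `preproc_apply()`).

Accuracy is reported as `100 − MAPE`. MAPE requires a DV bounded away from
zero; the default 1–7 rating scale guarantees that, and a scale including 0
aborts with guidance rather than returning infinities. The best family is
the lowest mean outer-fold MAPE; mean MAPEs within 0.01 percentage points
are treated as tied and resolved toward the simpler family (fixed order
ridge < elastic net < random forest < gradient-boosted trees). Without that
tolerance the choice between near-identical fits (e.g. ridge vs elastic net
on an exactly-linear DV) is decided by ~0.001-point CV noise, which is not
a meaningful model preference.

## Shapley explanation

The explainer attributes each session's prediction additively to features
against a single reference point (the per-feature median of the
preprocessed table): `v(S)` evaluates the model with coalition features at
their observed values and the rest at the reference. Two routes are
provided:

* **exact** — exhaustive enumeration over all `2^p` coalitions (used
  automatically for p ≤ 12);
* **sampling** — permutation sampling with at least 2048 coalition
  evaluations under a fixed seed. Each sampled permutation's marginal
  contributions telescope to `v(full) − v(empty)`, so the local-accuracy
  identity `base + Σφ = prediction` holds to machine precision for *both*
  routes and every model family.

Feature *direction* is the sign of the correlation between feature values
and per-session attributions (set to 0 below |r| = 0.1) — the scalar
analogue of reading a dot plot's color gradient. Ranks break ties
lexicographically so reports are deterministic. The attributions are
associations, not causal effects.

## Domain assignment

`naive_da()` scores each domain as

```
score(d) = w_count · |top-k features of d|
         + w_rank  · Σ_{f ∈ d ∩ top-k} (k + 1 − rank_f) / k
         + w_corr  · max_{f ∈ d ∩ top-k} |cor(f, mood)|
         + w_sat   · (scale_max − satisfaction_d) / scale_max
```

with defaults `w_count = 1, w_rank = 0.5, w_corr = 1, w_sat = 0.5`, hard
exclusion of infeasible domains, and watch features counting toward
exercise. The correlation term uses the *maximum* over the domain's top-k
features so that one strong independent predictor suffices. Exact score
ties fall back to the fixed order social > exercise > sleep > diet (the
observed assignment-frequency order) with a logged warning. All weights are
configuration, not constants: the equation is structurally faithful to how
coaches describe their criteria, and `fine_tune_da()` grid-searches the
weights against labeled assignments, preferring smaller weights on ties and
reporting both in-sample and leave-one-out match rates — the in-sample rate
is flagged as optimistic by construction. `build_llm_prompt()` renders the
same evidence as a deterministic prompt (no network call); a round-trip
parser guarantees the embedded table is lossless.

## Slope specificity

Phase-2 change is quantified in phase-1 z-units: each domain's
representative metric is the orientation-corrected mean of its item
z-scores per session, every series is z-scored against the participant's
monitoring-phase mean and SD, and an OLS slope over phase-2 *session index*
(not calendar time — phase-2 EMAs are nominally daily with gaps) summarizes
each participant. The mood slope is sign-flipped so alleviation is
positive. Participants with fewer than 3 phase-2 EMAs are flagged excluded.
Specificity across participants is a robust regression (IRLS, bisquare,
c = 4.685 — fixed for reproducibility) of mood slope on target and
off-target slopes, all standardized, with an early-window variant using
only the first 10 phase-2 EMAs.

**Two different nulls.** With zero phase-2 drift but lifestyle–mood
couplings intact, the slope-on-slope regression *correctly* rejects in
nearly every replicate: random AR(1) excursions of the target behavior
still move mood through the coupling, so slope correlation is a true
association, not a false positive. Type-I calibration of the regression
machinery is therefore assessed under the *association null* — no drift
and (numerically) no coupling — where the false-positive rate sits at the
nominal 5%. The distinction matters when interpreting the statistic on
real data: a significant target beta evidences association between change
trajectories, not intervention causality.

## Outcome statistics

* **Interpolation.** Interior missing timepoints on the
  screening→post grid are linearly interpolated per participant;
  leading/trailing gaps stay missing with a warning; follow-ups are never
  imputed (follow-up tests are available-case by construction).
* **Repeated measures.** Friedman's χ² (df = k − 1, average ranks for
  ties) is the primary test; a parametric RM-ANOVA companion with
  Mauchly's sphericity test and Greenhouse–Geisser-corrected p is emitted
  alongside, since both framings are in common use and neither is silently
  preferred. For small matrices an exact permutation p is computed by
  dynamic programming over column rank-sum vectors; the test suite checks
  it against literal enumeration of all within-row rank permutations.
* **Post-hocs.** Wilcoxon signed-rank of each timepoint vs pre: zero
  differences dropped, exact null (convolution over doubled average ranks,
  so ties stay integral) for n ≤ 25, otherwise normal approximation with
  continuity and tie corrections; BH-FDR across timepoints.
* **Effect sizes.** Paired Cohen's d = mean(Δ)/sd(Δ) with 95% CI by
  noncentral-t inversion, so the CI excludes zero exactly when the paired
  t-test rejects at 0.05.
* **Gated tests.** Anderson–Darling normality of the difference scores at
  α = 0.05 selects paired-t vs signed-rank; below 8 pairs the statistic is
  unavailable and the nonparametric branch is taken.
* **Change regression and remission.** Robust (bisquare) regression of
  primary change on secondary changes with standardized betas labeled
  small/medium/large at 0.1/0.3/0.5; remission = post PHQ9 < 5, responder
  = ≥ 50% reduction; one-way ANOVA / χ² baseline contrasts with BH-FDR and
  a logistic companion controlling baseline severity. The intervention
  domain covariate is checked with a Kruskal–Wallis test on change scores,
  the rank-based analogue of adding the factor to the repeated-measures
  model.
* **Power.** `min_detectable_d()` solves the noncentral-t power function
  by root-finding; at n = 40, α = 0.05, power 0.8 the two-sided paired
  design resolves d ≈ 0.45.

## Problem sizes and numerical choices

The shipped analyses use a 40-participant cohort (60 monitoring sessions,
42 phase-2 days), 100 seed replicates for specificity power and 200 for
type-I calibration — sizes at which every property of interest is stable
while a full run stays in minutes. Degenerate inputs have defined behavior
throughout: all-tied Friedman matrices report χ² = 0, p = 1; all-zero
signed-rank differences report p = 1 with a flag; constant features are
dropped with a warning before modeling; zero phase-1 variance aborts
z-scoring with the metric named; an all-infeasible assignment errors toward
manual review rather than guessing.

## Known limitations

* The feature catalog, DA weights and representative-metric construction
  are documented defaults, overridable by configuration; they are the
  package's design choices, not published constants.
* The empirical quantities reported by published trials of this design
  (model accuracy near 75%, specificity beta near 0.4, remission near 55%)
  depend on participant data that is not distributable; synthetic results
  are comparable in *structure* and serve as plausibility bands only.
* No causal identification: every reported association — Shapley ranks,
  slope specificity, change regressions — is correlational.
* The fine-tuned DA weights overfit whatever labeled sample they are given;
  the leave-one-out rate is the honest generalization summary, and full
  automation without human review is not supported by these analyses.
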