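---
title: "Methods: the 1-back Stroop workload paradigm and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 1-back Stroop workload paradigm and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bstask)
```

## The paradigm

The BS task crosses a spatial 1-back judgement (does the stimulus occupy the
same cell of a 3×3 grid as the previous trial?) with a colour–word Stroop
judgement (does the word's meaning match its ink colour?). The cross defines
four conditions — both consistent (1), both inconsistent (2), 1-back
consistent only (3), Stroop congruent only (4) — and the response key is the
XNOR of the two judgements: one key when the judgements agree (conditions
1–2), the other when they disagree (3–4), with the key assignment
counterbalanced across participants. Because a 1-back judgement is undefined
without a predecessor, every sequence is preceded by one unscored lead-in
trial: the full task is 121 trials, 120 scored, 30 per condition.

`realize_trials()` guarantees faithfulness by construction: a
back-consistent trial copies the previous grid cell, a back-inconsistent
trial draws uniformly from the other 8 cells (implemented as a uniform
offset 1–8 modulo 9, which makes the recurrence vectorisable); a congruent
trial's word equals its ink, an incongruent trial's word draws uniformly
from the other 3 colours. `rescore_conditions()` inverts the construction
from the raw stimuli and is used throughout the tests as an independent
oracle.

### Pseudo-randomness

"Pseudo-random" presentation is implemented as a uniformly random
permutation of the per-condition counts, rejected until no run of identical
conditions exceeds `max_run_length` (default 4, configurable). The bounded
run is our reading of balanced pseudo-randomness — the source protocol does
not state an explicit constraint — and rejection sampling (capped at 10,000
tries, then an explicit infeasibility error) keeps the distribution uniform
over admissible sequences.

## Time-pressure calibration

Required time (RT) is the mean reaction time measured with no response
deadline; the available time (deadline) is `AT = 1.25 × RT`, so that
`RT/AT = 0.8`, the ratio at which responders feel time pressure. Before
averaging, RTs pass a two-level screen, one pass per level (no iteration):

1. incorrect trials are dropped per participant;
2. within each participant × condition group, trials outside mean ± 3 SD of
   that group's pre-removal statistics are dropped (sample SD, n − 1;
   singleton groups are kept with a warning);
3. per-participant condition means outside the group's mean ± 3 SD for that
   condition exclude the whole participant (the screen reports participant
   counts, so exclusion is participant-wise rather than cell-wise).

The product is rounded **half-up to the nearest 100 ms**. The rounding rule
is inferred: all four published (mean RT, deadline) pairs —
2269.5 → 2300, 2992.7 → 3000, 2638.1 → 2600, 2814.3 → 2800 — are consistent
with nearest-100 rounding and inconsistent with ceiling or floor. The
quantum and the 1.25 factor are both arguments.

A deliberately unresolved ambiguity: the trial-level screen could pool SDs
per condition across participants rather than within participant. We screen
within participant × condition because the screen is described as operating
"for each participant within each condition"; the pooled variant can be
obtained by pre-grouping the observations differently.

## The session engine

The engine runs on a virtual clock — a 30-minute session executes in
milliseconds — and drives any *responder*: an object answering vectorised
callbacks for task trials, PVT trials and scale prompts. A display
front-end would adapt a human to the same interface; the engine itself never
renders anything.

Per scored trial: the responder's latency is compared with the trial's
deadline. Within the deadline, the key is scored (check or cross feedback);
past it, the trial is a no-response (dash feedback, latency and key
recorded as missing). The clock advances by `min(latency, deadline)` plus
the 500 ms feedback interval. No-response trials count as errors for
accuracy by default; `count_no_response_as_error = FALSE` scores answered
trials only — which reading of "accuracy" applies is not stated in the
source protocol, so both are exposed.

Numerical conventions the protocol leaves open, fixed here:

* **Lead-in clock charge.** A deadline-pressured lead-in displays for the
  rounded mean of the block's deadlines plus the feedback interval; in
  unlimited (calibration) mode it is free. Some display duration is
  physically necessary; the mean deadline is a neutral choice and only
  shifts the block clock by one trial-equivalent.
* **Time-on-task block filling.** The 30-minute protocol fixes 6 blocks of
  5 minutes but not trials per block. Blocks are filled with pseudo-random
  *balanced batches* of four (one trial per condition) until the block
  clock expires; a batch begun before expiry completes. This preserves the
  1:1:1:1 ratio exactly within blocks and yields variable per-block trial
  counts (~155–160 with the default simulated participant), matching the
  variable published correct-trial counts rather than a fixed count.
  The 1-back referent chains across batches within a block; each block
  starts with its own lead-in.
* **PVT intervals.** Stimuli are scheduled at uniform 2–10 s intervals; the
  drawn interval *includes* the 1 s feedback display that follows each key
  press (the source's parenthetical reading), so a trial consumes its
  interval plus the reaction time. Validity ≥ 100 ms and lapse ≥ 500 ms are
  flagged per trial.
* **Scale administrations** are instantaneous on the task clock (no
  duration is specified; rest during the scale is forbidden anyway).
* The **practice gate** repeats 16-trial blocks until accuracy reaches 0.90
  (configurable) or an attempt cap flags failure.

## The simulated participant

The simulated responder exists so every protocol and the full analysis
pipeline can be exercised and property-tested at desk scale. It is a
generative emulation of group-level published behaviour, not a cognitive
model and not a fit to any human data.

* **Task RTs**: lognormal kernels per condition, moment-matched to target
  mean/SD. Deadline-pressured defaults (1200/1550/1350/1450 ms) are chosen
  so block trial counts and accuracies land on the scale of the published
  block summaries; deadline-free defaults (1815/2395/2110/2250 ms) sit at
  the published condition means.
* **Fatigue drift**: RT means scale by `1 + d_rt·b` and accuracies drop by
  `d_acc·b` with 0-based block index `b` (defaults 0.01 and 0.006 per
  block), chosen to produce first-to-last-block declines of roughly 6% in
  correct trials and 3 points in accuracy. Linear-in-block drift is the
  simplest shape consistent with a monotone decline.
* **PVT**: a lapse mixture — with a per-trial lapse probability (default
  0.005, multiplied by 3.5 after the task) the RT is 500 ms plus an
  exponential tail; otherwise the base kernel (mean 272 ms) truncated at
  100 ms.
* **Subjective scales**: the reported mean at block `b` is
  `baseline + asymptote·(1 − e^{−rate·b})` plus Gaussian noise, clamped to
  0–100 and rounded to the scale unit. The saturating-exponential mirrors
  the diminishing block-to-block increments that fatigue self-reports show;
  per-item defaults put the fatigue item near 60 by block 6 with the
  largest jump in block 1.
* **Cohorts** draw per-participant parameters (multiplicative lognormal
  jitter on RT means, Gaussian jitter on accuracies, asymptotes and PVT
  means) around the preset; the spread is a free choice targeting the
  published between-participant SDs, since no individual-level variance
  decomposition is available.

What passing tests on this responder do **not** show: anything about human
RT distributions beyond scale, sequential dependencies (the model is
conditionally independent across trials), strategic speed–accuracy
trade-offs, or real time-pressure physiology. They do show that the engine,
file formats and statistics are internally consistent and that the analysis
recovers planted effects with the advertised power and type-I error.

## The analysis pipeline

Scale scoring is the unweighted six-dimension sum (0–120). Block metrics
count check-feedback trials over scored trials. First-to-last-block decline
is `100 (first − last)/first`, reported to two decimals.

Repeated-measures comparisons are routed on normality: Shapiro–Wilk for
paired two-sample comparisons, and by default the Lilliefors-corrected
Kolmogorov–Smirnov test for block-wise matrices (the plain KS test is wrong
when moments are estimated from the sample; both are exposed). Normal data
go to the paired t-test (Cohen's d = mean difference / SD of differences)
or the one-way repeated-measures ANOVA; non-normal data go to the Wilcoxon
signed-rank test (matched-pairs rank-biserial `r = (W⁺ − W⁻)/(W⁺ + W⁻)`)
or the Friedman test.

The RM-ANOVA (`rm_anova_gg()`) delegates the fit to `car::Anova` on an
intercept-only multivariate model, tests sphericity with Mauchly's test
(`stats::mauchly.test`), and when sphericity is rejected at 0.05 multiplies
both degrees of freedom by the Greenhouse–Geisser epsilon, computed from
the eigenvalues of the covariance projected onto an orthonormal contrast
basis (bounded in `[1/(k−1), 1]`; with two conditions epsilon is exactly 1
and no test is run). Partial eta squared is `SS_effect/(SS_effect +
SS_error)`. The test suite cross-checks F, partial eta squared and epsilon
against explicit sums-of-squares and covariance-formula implementations.

The Friedman test delegates to `stats::friedman.test` (average ranks for
ties) and reports Kendall's W through the identity `W = χ²/(n(k − 1))`;
Bonferroni-corrected pairwise signed-rank post hocs are available. The
fatigue item is analysed over 7 timepoints (baseline + 6 blocks), the other
subjective items and the behavioural metrics over 6 — the timepoint set is
an explicit argument (`include_baseline`) rather than a guess, since
published block tables differ in whether a baseline column exists.

Spearman matrices use tie-corrected average ranks with asymptotic p-values;
constant columns yield flagged `NA`s, never a silent zero.

Cohen's d for paired data is mean difference over SD of differences; with
summary-level inputs this formula cannot reproduce every published paired-d
value (those depend on the raw pairings), which is why cohort-level
reproduction of inferential statistics is explicitly out of scope.

## Problem sizes and tolerances

The test suite exercises: structural invariants of the generator over 100
seeds; oracle equivalence of all statistics on random 5×4 to 10×6 matrices
at |Δ| < 1e-10; Monte-Carlo recovery of responder moments at 1000–20,000
draws against 3-standard-error bands; saturating-curve parameter recovery
from 200 simulated trajectories within 10%; and a power/type-I study of the
full pipeline — 100 replicate 72-participant time-on-task cohorts with the
drifting preset (expecting Friedman p < 0.001 in at least 95%) and 200
driftless cohorts (expecting a rejection rate of 0.05 ± 0.02 at α = 0.05).
These sizes were chosen as the smallest that make the binomial bands
meaningful.

## Known limitations

* The engine models time, not displays: no render latency, keyboard debounce
  or monitor calibration.
* The simulated participant is stationary within block and has no
  sequential structure (no post-error slowing, no streaks).
* Single-pass outlier screening is order-dependent by design (re-running the
  screen could expose new outliers; the published procedure is one-shot).
* The 2-back comparison task is implemented to its stated pacing (0.5 s
  letter + 2 s blank, no feedback) but its analysis surface is limited to
  what the workload comparison needs.
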