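# bstask

A headless, fully testable R implementation of a **1-back Stroop (BS)
dual-task paradigm** for inducing high mental workload (HMW) and — combined
with a 30-minute time-on-task protocol — mental fatigue, together with the
complete analysis pipeline used to validate such protocols.

## Who this is for

Researchers building or evaluating cognitive fatigue-induction protocols who
need (a) a reference implementation of the paradigm's combinatorics, timing
and calibration rules, (b) a virtual-clock session engine that any display
front-end or simulated participant can drive, and (c) the repeated-measures
statistics that the field reports (Greenhouse–Geisser-corrected RM-ANOVA,
Friedman tests with Kendall's W, normality-routed paired tests, Spearman
matrices).

## The paradigm

Each trial shows a colour word (one of red/yellow/blue/green, rendered as a
Chinese character by a front-end) in a cell of a 3×3 grid. The participant
makes two simultaneous judgements:

* **1-back consistency** `B` — does the grid cell match the previous trial's?
* **Stroop congruency** `S` — does the word's meaning match its ink colour?

These define four conditions — 1: `B ∧ S`, 2: `¬B ∧ ¬S`, 3: `B ∧ ¬S`,
4: `¬B ∧ S` — and the required key is a function of `B XNOR S`: one key for
conditions 1–2, the other for 3–4 (counterbalanced across participants).

**Time pressure** is calibrated from deadline-free sessions. With RT the mean
reaction time per condition and AT the response deadline, a ratio
RT/AT = 0.8 produces felt time pressure, so

```
AT = 1.25 × RT,  rounded half-up to 100 ms
```

after a two-level preprocessing pass (incorrect trials removed, then ±3 SD
trial-level outliers within each participant × condition, then participants
with any ±3 SD condition mean at the group level). Feeding the published
per-condition mean RTs (1815.63, 2394.17, 2110.47, 2251.46 ms) through this
rule gives the paradigm's deadlines of **2300, 3000, 2600, 2800 ms**.

The fatigue-induction protocol runs six 5-minute blocks of the
deadline-pressured task (conditions balanced 1:1:1:1 in pseudo-random
batches), a 0–100 visual-analogue scale (mental fatigue / effort / stress /
boredom) at baseline and after every block, and a 3-minute psychomotor
vigilance test (valid response ≥ 100 ms, attention lapse ≥ 500 ms) before
and after the task.

## Worked example

```r
library(bstask)

# deadlines from the published condition means
compute_available_time(c(1815.63, 2394.17, 2110.47, 2251.46))
#> [1] 2300 3000 2600 2800

# one simulated 30-minute fatigue-induction session
log <- run_tot_protocol(sim_responder(), seed = 7)
block_metrics(log)
#>   block_index n_scored correct_count  accuracy mean_rt_ms
#> 1           1      160           152 0.9500000   1379.988
#> 2           2      160           146 0.9125000   1381.808
#> 3           3      160           145 0.9062500   1374.811
#> 4           4      156           142 0.9102564   1434.020
#> 5           5      156           146 0.9358974   1451.099
#> 6           6      156           143 0.9166667   1432.872

# a 72-participant cohort and the full published-style analysis
logs <- generate_cohort(72, "tot", seed = 1)
rep <- tot_report(logs)
rep$tests$mental_fatigue   # Friedman chi-square + Kendall's W (k = 7, incl. baseline)
rep$declines               # block-1 -> block-6 percent declines
rep$pvt$tests$mean_rt_ms   # pre/post PVT paired comparison
```

Each block holds roughly 155–160 scored trials; accuracy starts in the
mid-90s and declines by a few percentage points over the six blocks, the
fatigue score rises with strictly diminishing increments, and the post-task
PVT shows more lapses — the qualitative signatures the protocol is designed
to induce.

A command-line front-end wraps the same functions:

```sh
Rscript inst/cli/bstask.R generate --task bs --seed 7 --out trials.csv
Rscript inst/cli/bstask.R simulate --protocol tot --n 12 --seed 7 --out-dir logs/
Rscript inst/cli/bstask.R analyze --logs logs/ --out-dir results/
```

## Scope

The package is a paradigm engine, not a stimulus presenter: rendering (grid,
progress bar, feedback glyph display) and millisecond keyboard timing are a
front-end's job, against the engine's timing contracts. Simulated
participants emulate the scale and direction of published group-level
behaviour for testing; they are not fits to any human data set.
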