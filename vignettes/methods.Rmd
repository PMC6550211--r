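---
title: "Methods: simulating and phenotyping daily-life stress physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and phenotyping daily-life stress physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ambulatory stress-monitoring studies pair multi-day wearable physiology —
an ECG-derived R-peak series, skin conductance (SC), skin temperature (ST)
and 3-axis accelerometry (ACC) — with ecological momentary assessment (EMA):
smartphone prompts, up to 12 per day and at least 30 minutes apart, on which
subjects rate the maximal stress of the past hour on a 5-point Likert scale.
The analysis question is twofold: do physiological features differ across
self-reported stress states, and how well can a population model predict a
held-out subject's momentary stress from physiology alone? The second
question turns out to be the more interesting one, because subjects differ
enormously in how strongly their physiology tracks their self-reports —
which is itself a subject-level trait, a *digital phenotype*.

`wearstress` implements that full chain. Because raw recordings of this
kind are not publicly distributable, the package ships a synthetic cohort
generator with a known ground truth, so that every downstream stage is
testable: the generator plants a latent stress-reactivity phenotype in each
subject (*responsive* vs *blunted*) and the pipeline's job is to recover it.

# The synthetic cohort

Each subject carries a latent, piecewise-constant stress level (Likert 1-5,
30-minute blocks) over the recording horizon. Nights (00:00-06:00) are
forced to level 1; daytime blocks draw independently from a distribution
skewed towards "no stress" — by default `c(0.504, 0.353, 0.100, 0.040,
0.003)`, chosen so that level 1 carries 50.4% of reports, the merged top
three levels 14.3%, and the extreme level 0.3%, matching the self-report
imbalance typical of healthy working populations. The split between levels
3 and 4 inside the merged mass is not separately constrained; it is a free
configuration choice.

The latent level drives all four channels:

* **Beats.** Instantaneous heart rate = subject baseline (population
  N(70, 5) bpm) + a phenotype-scaled stress effect + a nocturnal dip
  (default −10 bpm, matching the usual day/night difference of ~10 bpm) + a
  slow wander (SD 2 bpm). Beat times come from inverting the cumulative
  rate; RR intervals are then modulated by 0.1 Hz and 0.3 Hz sinusoids
  (relative amplitudes 0.03 and 0.025) plus 10 ms white noise, so LF and HF
  band features have realistic targets.
* **Skin conductance** (default 8 Hz; the device contract is 256 Hz but all
  rules are rate-parameterized and 8 Hz keeps multi-day simulations
  desk-sized). Tonic level = baseline (~1.7 µS) + 1.1 µS at night + slow
  wander. Skin conductance responses (SCRs) arrive as an inhomogeneous
  Poisson process — 1/min at rest, plus a phenotype-scaled stress increment —
  each a 1-s linear rise with 4-s exponential decay and log-normal amplitude
  (median 0.3 µS).
* **Skin temperature** (1 Hz): baseline ~31.4 °C, +1.7 °C at night, a small
  stress-related decrease, slow wander and 0.05 °C noise.
* **Accelerometer magnitude** (32 Hz around 1 g): noise SD 0.015 g at rest
  and 0.08 g during high-intensity bouts (3 bouts/day, 20-40 min), placing
  rest and activity clearly below and above the 0.04 windowed-SD activity
  threshold.

The phenotype is encoded purely as effect size: responsive subjects draw
their maximal-stress effects from disjointly higher ranges than blunted
subjects on every channel (HR +8 to +12 vs +1 to +3 bpm; SCR rate +2.4 to
+3.6 vs +0.3 to +0.8 events/min; ST −1.0 to −0.6 vs −0.25 to −0.05 °C). At
the windowed-feature level the responsive HR effect is several
within-subject SDs, the blunted effect well under one — the contrast the
phenotyping stage must recover. Blunted subjects also draw worse
psychological baseline scores (higher PSS, DASS, PSQI), encoding the
association between blunted reactivity and poorer self-reported health that
the group comparisons should rediscover.

EMA reports equal the latent level at the prompt time, with a symmetric
±1-step misreport probability (default 0.1). Prompts are placed uniformly
in the 08:00-22:00 waking window conditional on the 30-minute minimum gap.
Prompt hours are not part of the device contract and the waking window is a
package choice.

What the generator does **not** emulate: ECG waveform morphology (it emits
beats directly, since every downstream computation consumes beat times),
respiration coupling, weekday/weekend structure, context streams, and any
correlation between activity and stress. Passing tests therefore
demonstrate the pipeline's correctness and its ability to recover planted
effects — not field performance on real recordings.

# Signal quality

Three rule-based indicators, each a pure function of its segment:

* **ECG (10-s segments).** Bad if mean HR is outside 40-180 bpm, any
  inter-beat gap exceeds 3 s, or max(RR)/min(RR) ≥ 2.2 ("less than 2.2" is
  the pass condition, so exactly 2.2 fails). Segments passing all three
  rules face an adaptive template match. The template is the mean resampled
  RR profile (length 10) of the last 5 accepted segments, seeded by the
  first rule-passing segment. The match statistic is a normalized RMS
  distance, `1 − RMS(profile − template)/mean(template)`, thresholded at
  0.66. A correlation statistic was considered and rejected: clean ambulatory
  RR profiles are flat-plus-noise, for which a Pearson correlation against a
  near-flat template is numerically degenerate (r ≈ 0) and would flag
  virtually all clean segments bad. The distance statistic passes clean data
  comfortably (match ≈ 0.97) while rejecting gross rate mismatches.
  Fewer than two beats in a segment is bad by definition. Whole-recording
  masks additionally mark every segment overlapped by a series-level gap
  > 3 s as bad, since a gap spanning a segment boundary is invisible to
  within-segment differences.
* **SC (5-s windows).** Bad if more than 90% of samples are below the
  0.001 µS "lost" threshold, or if between adjacent 1-s aggregates the
  signal rises more than 20% or falls more than 10%. The comparator for the
  slew rule (previous 1-s mean) is a package decision; the rule's source
  does not define it.
* **ST (per sample).** Good iff within 20-40 °C inclusive (the range is
  stated as "between 20 and 40"; inclusivity is a package decision, fixed by
  test). Non-finite samples are bad.

Final partial segments are discarded (bad) — conservative. Window-level
quality is the time-weighted good fraction; the downstream inclusion rule
is strictly `quality > 0.8` (the source material states both "≥80%" and
"> 0.8"; the strict form is adopted and tested).

# Feature extraction

Windows are 5 minutes with 4 minutes overlap (60-s hop), aligned to the
recording start — one feature row per interior minute. No clock-minute
snapping is applied; alignment to the recording origin is the simplest
reproducible convention.

Eighteen features: 6 ECG (mean HR = 60000/mean(RR ms); RMSSD; SDNN; LF
0.04-0.15 Hz; HF 0.15-0.40 Hz; LF/HF), 8 SC (tonic mean, phasic power,
summed SCR area, SCR count, mean |Δ| and |Δ²| of the raw signal, tonic
slope, SD), 4 ST (mean, median, slope, SD), plus the ACC-magnitude SD.
Only six of the eighteen identities are fixed by the source material (mean
HR, RMSSD, LF, HF, LF/HF, SC phasic/area/diff2, ST median/slope/SD among
them); the remainder — SDNN as the sixth ECG feature, the exact SC
difference features, ST mean — are reconstructions chosen from standard
practice and documented as such.

Numerical choices:

* Tachogram spectra: cubic-spline interpolation of the RR series to 4 Hz,
  linear detrend, Hann window, single-segment periodogram normalized so the
  full-band integral matches the signal variance (checked by a
  Parseval-style test). No estimator is prescribed by the source; this is
  the simplest spectrally calibrated choice for 5-minute windows.
* SC decomposition: tonic = zero-phase 2nd-order Butterworth low-pass at
  0.05 Hz; phasic = residual, so tonic + phasic reconstructs the input
  exactly. Reflective padding (3 cutoff periods) suppresses the filter's
  edge transients, which otherwise dominate the phasic residual. SCR
  detection runs on a 0.5-s moving-average of the phasic trace:
  trough-to-peak rises ≥ 0.01 µS completed within 5 s (common EDA practice;
  both configurable). Event area integrates the detection trace above the
  onset level until recovery, capped at 60 s past the peak.
* In `extract_features()` the decomposition runs once per recording and is
  sliced per window — standard EDA practice and linear instead of quadratic
  in recording length. The per-window `sc_decompose()` remains the public
  single-window API.
* Missing-feature policy: a window failing one channel's quality gate gets
  missing values for that channel's features only; rows are never dropped at
  extraction time. ECG features are also missing when fewer than two beats
  fall in a window, and LF/HF when HF = 0.

# Dataset assembly

EMA labels propagate backwards onto the 60 one-minute rows preceding each
prompt. Where two prompts' lookback hours overlap (possible at the 30-min
minimum gap), the later prompt wins — the source is silent; this keeps every
row's label the most recent available report. Rows in [00:00, 06:00) are
state N regardless of labels; day is [06:00, 24:00).

Inclusion: overall window quality (minimum across the three channel
fractions) strictly above 0.8 and ACC SD ≤ 0.04 (stated both as < and ≤ in
different places; ≤ adopted). EMA hours whose surviving rows span fewer
than 10 minutes are dropped entirely, and subjects whose surviving daytime
labels contain a single state are discarded. Filtering is idempotent.

Features are then z-normalized per subject over the retained rows
(zero-variance features map to 0 rather than dropping the subject), and
redundant features are pruned greedily on the pooled normalized rows:
visiting features in the documented canonical order, a feature is kept only
if its |Spearman r| with every kept feature is ≤ 0.7. Pruning after
normalization (rather than before) is a package decision; it makes the
correlation matrix scale-free across subjects.

Location handling is planar: stay locations are maximal contiguous runs
within 1 km of the running centroid lasting over 60 min; everything else is
commuting. Anonymization is one random rigid transform (rotation +
translation) per subject, which preserves all pairwise distances.

# Phenotype modeling

Stress states are the merged Likert levels (1→S1, 2→S2, 3-5→S3).
Classification is leave-one-subject-out: for each fold, a univariate
one-way ANOVA F-test per feature with Benjamini-Hochberg selection at
α = 0.05 runs on the training rows only (falling back to all features if
nothing survives), missing values are imputed by training-fold medians
(per-subject median for training rows, global training median for test
rows — the test subject's own statistics are never used), and a random
forest is fit.

Forest defaults: 100 trees, ⌊√p⌋ variables per split, no depth cap, fixed
seed per fold. One hundred trees is deliberate: with ≤ ~10 surviving
features, forest predictions stabilize well below 100 trees, while
multi-day cohorts make each additional tree expensive; the tree count is an
explicit argument for users who want more.

The per-subject score is macro-averaged F1 over the classes present in that
subject's true labels, with 2PR/(P+R) per class and a zero convention when
P+R = 0. The F1 description in the source ("a weighted average between
precision and recall") describes the harmonic mean inside each class, not
the cross-class averaging, which is unstated; macro is adopted because it is
the convention under which a uniform-random classifier on three balanced
classes scores 1/3 — exactly the "performance as good as random" anchor used
for the 0.33 group threshold. Support-weighted averaging is available via
`average = "weighted"`.

Groups: F1 < 0.33 low, F1 > 0.66 high, everything else (boundaries
included — the stated intervals are open on both sides, leaving the
boundaries unassigned) medium. The dynamic range of a feature for a subject
is mean(S3 rows) − mean(S1 rows); group values average over subjects having
both states, excluding (not zeroing) subjects that lack one. Group
comparisons use Kruskal-Wallis across the three groups, Wilcoxon rank-sum
low-vs-high with BH correction across the questionnaire battery, and
chi-square for gender.

# Statistical reporting

The state matrix reports, per feature, population medians of the normalized
rows per state and the six signed median differences N-S1, N-S2, N-S3,
S1-S2, S2-S3, S1-S3, each with a Wilcoxon rank-sum p-value BH-adjusted
across the full feature-by-pair family and a significance tier (\*
p < 0.05, \*\* p < 0.005, \*\*\* p < 0.0005 on adjusted values). Population
summaries report per-state means with central 95% intervals taken as
2.5th-97.5th percentiles of the pooled distribution: reported intervals of
this type in the field are far wider than standard errors of the mean, so
they are interpreted as population spread, not mean uncertainty.

BH adjustment wraps `stats::p.adjust(method = "BH")` and is verified in the
tests against a brute-force step-up enumeration; Spearman correlation wraps
`stats::cor` and is verified against a midrank oracle.

# Problem sizes and determinism

The package-level end-to-end demonstration uses a 30-subject, 2-day cohort
at 50% responsive fraction — large enough for a stable
responsive-vs-blunted F1 contrast and feature-wise dynamic-range dominance,
small enough to run in minutes on one CPU. All randomness flows from a
single integer seed through per-subject, per-channel derived sub-seeds, so
cohorts are bitwise reproducible and subjects can be simulated streamingly
(generate, extract, discard) without changing the result.

# Known limitations

* The simulator's independence assumptions (stress level independent of
  activity, consumption and location) remove real-world confounds by
  construction; the pipeline's activity filter is exercised, but its value
  against correlated confounding cannot be demonstrated synthetically.
* The ECG quality indicator operates on beat series, not waveforms, so its
  template stage captures rate-pattern consistency rather than QRS
  morphology.
* Blunted subjects still carry non-zero effects; with very short recordings
  (1 day) the responsive/blunted F1 contrast is noisy. Two or more days are
  recommended for phenotype-recovery experiments.
* Group comparisons on synthetic questionnaires merely confirm the planted
  associations; they say nothing about real psychometrics.
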