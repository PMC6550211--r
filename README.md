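# wearstress

Digital stress phenotyping from wearable physiology and momentary
self-reports.

`wearstress` is an R package for ambulatory stress-monitoring studies in
which subjects wear physiological sensors for several days — an ECG-derived
R-peak beat series, skin conductance (SC), skin temperature (ST) and
3-axis accelerometry (ACC) — while answering ecological momentary
assessment (EMA) prompts: up to 12 per day, at least 30 minutes apart,
rating the maximal stress of the past hour on a 5-point Likert scale. It is
aimed at researchers in psychophysiology and digital health who want a
tested, reproducible implementation of the full analysis chain, plus a
synthetic cohort generator with planted ground truth for validating every
stage without access to sensitive raw recordings.

## What it computes

**Signal quality.** Rule-based per-channel indicators: ECG 10-s segments
are bad if mean HR ∉ [40, 180] bpm, any R-R gap > 3 s, or
max(RR)/min(RR) ≥ 2.2, with an adaptive template match on top; SC 5-s
windows are bad if > 90% of samples are "lost" (< 0.001 µS) or the signal
slews more than +20%/−10% per second; ST samples must lie in 20–40 °C.

**Features.** On 5-minute windows with 4-minute overlap (one row per
minute): 6 ECG features (mean HR, RMSSD, SDNN, LF and HF band power of the
interpolated RR tachogram over 0.04–0.15 / 0.15–0.40 Hz, LF/HF), 8 SC
features from a tonic/phasic decomposition (tonic mean, phasic power,
summed SCR area, SCR count, first/second differences, tonic slope, SD),
4 ST features (mean, median, slope, SD), and the ACC-magnitude SD as an
activity index.

**Dataset assembly.** EMA labels propagate onto the 60 rows of the hour
preceding each prompt; stress levels merge 1→S1, 2→S2, 3–5→S3; nights
(00:00–06:00) form the baseline state N. Rows need window quality > 0.8 and
ACC SD ≤ 0.04; EMA hours with under 10 surviving minutes and single-state
subjects are dropped. Features are z-normalized per subject and pruned at
|Spearman r| > 0.7.

**Phenotyping.** Leave-one-subject-out random-forest classification of
S1/S2/S3 with per-fold FDR-supervised feature selection
(Benjamini–Hochberg, α = 0.05), per-subject macro F1 with a majority-class
baseline, performance groups at F1 < 0.33 / > 0.66, per-group physiological
dynamic range (mean S3 − mean S1 per feature), and group comparisons of
questionnaire baselines (PSS, DASS, PSQI) with Kruskal–Wallis, Wilcoxon and
chi-square tests under BH correction.

**Reporting.** State-wise median-difference matrices (N–S1, N–S2, N–S3,
S1–S2, S2–S3, S1–S3 per feature) with BH-adjusted Wilcoxon p-values and
significance tiers, plus per-state population summaries.

## Worked example

```r
library(wearstress)

rep <- run_stress_pipeline(n_subjects = 6, responsive_fraction = 0.5,
                           days = 1, seed = 42)
rep$loso$per_subject
#>   subject_id    f1 baseline_f1 n_rows
#> 1       S001 0.373       0.197    507
#> 2       S002 0.383       0.263    600
#> 3       S003 0.324       0.207    544
#> 4       S004 0.546       0.425    591
#> 5       S005 0.278       0.168    583
#> 6       S006 0.319       0.256    577

rep$dataset$features
#> [1] "ecg_mean_hr" "ecg_lfhf" "sc_phasic" "sc_scr_count" "sc_diff2"
#> [6] "sc_slope" "st_slope" "st_sd"

subset(rep$state_matrix, feature == "ecg_mean_hr")
#>       feature  pair     diff         p     p_adj sig
#> 1 ecg_mean_hr  N-S1 -1.92250  0.00e+00  0.00e+00 ***
#> 2 ecg_mean_hr  N-S2 -1.91714  0.00e+00  0.00e+00 ***
#> 3 ecg_mean_hr  N-S3 -2.04148 1.18e-189 1.89e-188 ***
#> 4 ecg_mean_hr S1-S2  0.00536  9.74e-02  1.23e-01
#> 5 ecg_mean_hr S2-S3 -0.12434  1.01e-04  2.02e-04 ***
#> 6 ecg_mean_hr S1-S3 -0.11898  9.49e-07  2.40e-06 ***
```

Each subject contributes one row per minute of good-quality, low-activity,
EMA-labeled recording (`n_rows`), is scored by LOSO macro F1 against the
majority-class baseline, and the state matrix shows the expected
physiology: mean heart rate is ~2 within-subject SDs lower at night than in
any daytime stress state, and rises from no stress (S1) to high stress (S3)
by ~0.12 SD. The correlation pruning keeps 8 of the 18 features (e.g.,
RMSSD and SDNN track mean HR almost perfectly and are dropped).

At this toy scale (6 subjects, 1 day) per-subject F1 is noisy and the
responsive/blunted contrast is not yet resolved; the package-level
demonstration uses 30 subjects over 2 days, where responsive subjects score
a clearly higher mean LOSO F1 than blunted ones and the high-F1 group
dominates the dynamic range on most features (see the acceptance script and
`tests/testthat/test-acceptance.R`).

## Package layout

- `R/synthetic-cohort.R` — cohort generator: profiles, latent stress
  schedules, beats/SC/ST/ACC simulation, EMA, artifact injection, CSV
  writers.
- `R/signal-quality.R` — ECG/SC/ST quality indicators, masks, window-level
  aggregation.
- `R/feature-extraction.R` — sliding windows, HRV features, SC
  decomposition and features, ST features, the per-subject feature table.
- `R/cohort-assembly.R` — label propagation, day/night states, inclusion
  rules, per-subject normalization, correlation pruning, stay locations.
- `R/phenotype-modeling.R` — F1 scores, FDR feature selection, LOSO random
  forest, performance groups, dynamic range, group comparisons.
- `R/stats-report.R` — BH adjustment, state median matrix, population
  summaries, Spearman correlation.
- `vignettes/methods.Rmd` — the model, parameter and design documentation.
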