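# voicecog

Voice-based cognitive-status screening, end to end and fully
reproducible without clinical data.

Screening for cognitive impairment from voice rests on a simple
physiological premise: declining neuromuscular control degrades the
stability of phonation. `voicecog` implements the complete analysis
pipeline of such a study — speech tasks → acoustic features → cohort
grouping → classification → attribution — together with a synthetic
voice and cohort generator, so that every stage is testable against
known ground truth. It is aimed at researchers in clinical voice
analysis and biomedical machine learning who want an auditable,
seed-deterministic reference pipeline.

## The science in brief

**Features.** From each of 8 speech tasks (sustained /a/, /i/, /u/,
prolonged /a/, and the DDK tasks /puh/, /tuh/, /kuh/, /puh-tuh-kuh/) 23
acoustic features are extracted — 184 indicators per subject. The core
perturbation measures over the per-cycle periods *P*ᵢ and amplitudes
*A*ᵢ are

    jitter_local  = mean |P_i − P_{i−1}| / P̄ × 100        (%)
    shimmer_local = mean |A_i − A_{i−1}| / Ā × 100        (%)
    HNR           = 10 · log10(E_harmonic / E_noise)      (dB)

plus their standard families (RAP, PPQ5, DDP; local-dB, APQ3/5/11,
DDA), F0 statistics, LPC formant statistics F1–F4, and duration.

**Cohort.** Subjects are grouped by K-MMSE score: 0–19 severe, 20–23
mild, 24–30 normal; demographics are compared with Kruskal–Wallis,
chi-square, and Bonferroni-corrected pairwise Mann–Whitney tests.

**Classification.** Three binary tasks (severe vs normal, mild vs
normal, combined vs normal) over four model families (regularized
logistic, random forest, gradient boosting, feedforward net), tuned by
seeded random search with 5-fold cross-validated PR-AUC on an 8:2
stratified split. The chance level of PR-AUC is the prevalence

    PR-AUC_base = n_positive / n_total

and models are reported as relative improvement over it.

**Attribution.** Shapley values φᵢ with an interventional value
function (coalition features pinned to the instance, the rest drawn
from a background sample): exact enumeration up to 15 features, seeded
permutation sampling with standard errors beyond, and a top-20 ranking
with a value–attribution correlation as direction readout.

## Worked example

```r
library(voicecog)

# a 2-second vowel with 1% jitter, 3% shimmer, 25 dB SNR
w <- synthesize_vowel(voice_params(f0_hz = 110, duration_s = 2,
                                   jitter_pct = 1, shimmer_pct = 3,
                                   noise_snr_db = 25), seed = 42)
cycles <- detect_periods(w)
round(c(jitter  = compute_jitter(cycles, "local"),
        shimmer = compute_shimmer(cycles, "local"),
        hnr     = compute_hnr(w)), 2)
#>  jitter shimmer     hnr
#>    1.01    4.80   11.22
```

Detected jitter (1.01%) recovers the injected 1% from the 218 detected
cycles. Shimmer reads above the injected 3% and HNR well below the
injected 25 dB SNR because jitter and additive noise both contribute
real aperiodicity: noise perturbs the measured cycle peaks, and a
jittered voice genuinely has lower harmonicity (period variation smears
energy out of the harmonics). On a jitter-free vowel at 20 dB SNR the
same estimator reads 20.1 dB; the clean-signal recovery bands (jitter
and shimmer within 10% relative, HNR within ±3 dB over 0-30 dB SNR)
are asserted in the test suite.

```r
# a synthetic cohort with the study's group sizes and a known effect
cohort <- generate_cohort(cohort_params(
  group_sizes = c(severe = 72, mild = 54, normal = 97),
  effect_map  = list(i__shimmer_dda = c(severe = 1.5, mild = 0.8)),
  seed = 1))
tasks <- make_tasks(cohort$roster)
baseline_pr_auc(tasks$severe_vs_normal$counts)
#> [1] 0.426

rep <- demographic_report(cohort$roster)
round(rep$sex_test$statistic, 2)   # chi-square on the sex-by-group table
#> [1] 2.22
```

`0.426` is the severe-vs-normal prevalence baseline (72 of 169) — the
number any useful model must beat.

Full pipeline from one config file (writes roster, features,
demographics, classification results, SHAP rankings and a digest
manifest):

```sh
Rscript exec/voicecog run --config study.toml
```

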