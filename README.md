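# jwavesst

Automatic detection of the **J wave** — a small bump on the descending
slope of the terminal QRS complex of the ECG, associated with malignant
arrhythmia and sudden cardiac death — from single-lead recordings, using
the **synchrosqueezed wavelet transform (SST)** and a **random forest**.

The package is aimed at biomedical-signal researchers who want a complete,
reproducible reference pipeline: synthetic labelled ECG in, beat-level
detection metrics out, with every stage exposed as an ordinary R function.

## Method

Each beat contributes one 120-sample window after its R peak (0.24 s at
500 Hz — the terminal QRS / ST region where J waves live). The window is
decomposed by the SST chain:

* CWT with an analytic Morlet basis (centre frequency 35 Hz),
  `W_f(a,b) = a^{-1/2} ∫ f(t) ψ*((t−b)/a) dt`;
* instantaneous frequency `w_f(a,b) = Im[∂_b W_f / W_f]`;
* synchrosqueezing: each coefficient's mass `W_f(a_k,b) a_k^{-3/2} Δa_k/Δw`
  is reassigned to the frequency bin nearest `w_f(a_k,b)`, producing a
  sharply concentrated time–frequency plane;
* K = 5 maximum-energy ridges `φ'_k(b)` by dynamic programming, and
  narrow-band inverse SST
  `f_k(t) = 2 Re[R_ψ^{-1} Σ_{|w_l−φ'_k|≤bw} T_f(w_l,t) Δw]`
  giving five intrinsic-mode series per beat.

Features per beat: a 20-value band-energy/centroid summary of the SST
plane, plus Renyi (order 3), approximate and sample entropy of each mode
(m = 2, r = 0.2·SD) — 35 values, fed to a 150-tree random forest. Records
are split into train/test *by record*; scoring is beat-level sensitivity,
specificity, accuracy, Matthews correlation coefficient and rank-based
AUC, with per-feature Welch t-tests and importance rankings.

Clinical J-wave datasets are private, so validation is property-based on a
built-in synthetic cohort generator (Gaussian-wave beats, optional J bump,
baseline wander + powerline + white noise, record-level morphology
variability, record-level labels). See
`vignettes/jwave-detection-methods.Rmd` for the model, every tunable, and
what synthetic validation does and does not show.

## Worked example

```r
library(jwavesst)

cfg <- pipeline_config(n_negative = 4, n_positive = 4,
                       beats_per_record = 40, seed = 5)
res <- run_pipeline(cfg)
print(res$metrics)
#> Se 100.0%  Sp 92.5%  Acc 96.2%  MCC 0.928  AUC 0.999
#> confusion: TP 80 FN 0 TN 74 FP 6
head(res$feature_report[, c("feature", "importance", "t", "p")], 3)
#>      feature importance         t            p
#> 11    tf_c01 0.24098614  4.958495 3.590497e-06
#> 23     re_m3 0.08470072 -6.432761 2.019770e-09
#> 31 sampen_m1 0.08457800 -1.746753 8.382873e-02
```

Eight synthetic records (four J-positive) of 40 beats are generated,
denoised, segmented at detected R peaks, decomposed and classified; the
metrics are beat-level on the two held-out records per class: all 80
J-positive test beats and 74 of 80 J-negative test beats are correctly
classified (sensitivity 100%, specificity 92.5%, accuracy 96.2%), with
record-split AUC 0.999. The feature report shows the time-of-energy
feature in the lowest SST band (`tf_c01`) and the mode-3 Renyi entropy
(`re_m3`) leading the importance ranking, both with strongly significant
class separation (p < 1e-5) — the J bump shifts low-frequency energy
later into the window and changes mode complexity.

Lower-level entry points: `generate_dataset()` / `generate_record()`,
`denoise()`, `detect_r_peaks()`, `segment_beats()`, `cwt()`,
`synchrosqueeze()`, `extract_ridges()`, `reconstruct_modes()`,
`extract_features()`, `train_rf()`, `evaluate_model()`. A thin CLI over
the same functions lives at `inst/cli/jwave.R`
(`simulate` / `preprocess` / `features` / `run` subcommands).

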