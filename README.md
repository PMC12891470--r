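# gaitstab

Trunk-accelerometry gait stability metrics and a two-step, interpretable
machine-learning pipeline for stroke-vs-control gait analysis.

People recovering from stroke walk less stably, and the difference shows in
the acceleration of the trunk: larger sway (RMS), less periodic waveforms
(harmonic ratio, recurrence), more irregularity (sample entropy) and poorer
local dynamic stability (short-term maximum Lyapunov exponent). `gaitstab`
is for movement scientists and rehabilitation researchers who record lumbar
(L3) triaxial accelerometer signals during walking and want a tested,
reproducible path from raw cycles to interpretable models:

* **Signal layer** — gait-event detection from shank AP acceleration,
  transient-stride trimming, extraction of ten consecutive cycles, and the
  18 stability indicators (RMS, HR, SampEn, %REC, %DET, sLE × AP/ML/VT),
  plus EMG co-contraction indices and cycle-normalized joint angles.
* **Step 1 (classification)** — IQR/power/z-score normalization fitted on
  training splits only, Boruta ∩ LASSO consensus feature selection,
  training-split-only augmentation (SMOTE / lightweight GAN / conditional
  Gaussian), six classifiers with inner 5-fold grid search over repeated
  stratified splits, and sparse PLS-DA with per-component AUC and VIP
  scores.
* **Step 2 (regression)** — six regressors predicting uneven-surface
  stability and gait speed from even-surface parameters, with odds ratios,
  partial dependence, exactly additive permutation-Shapley attributions,
  and locators that read breakpoints, plateaus and U-shapes off PDP curves.
* **Synthetic cohort** — a ground-truth generator (imbalanced 71/39 cohort,
  d = 0.7 effects, a 0.8 m/s speed breakpoint, an ankle-angle U-shape, a
  harmonic-ratio plateau at 1.5) so the entire pipeline is testable without
  participant data.

Key metric definitions (demeaned window `x`, gait speed `v`):

* `RMS = sqrt(mean(x^2)) / v^2`
* `HR_AP = Σ A(2k f_stride) / Σ A((2k−1) f_stride)` over 20 harmonics
  (inverted for ML)
* `SampEn = −ln(A/B)`, Chebyshev matches of length m+1 vs m, r = 0.2 SD
* `%REC`, `%DET` from a 5-dim, delay-10 embedding, radius 0.4 SD √dim
* `sLE` = least-squares slope of the Rosenstein mean log-divergence over the
  first half stride, on 100-samples/stride normalized data, in nats/stride

## Worked example

```r
library(gaitstab)

# a stroke-like subject walking on an uneven surface
spec <- cohort_spec()
rec  <- simulate_subject_record("S001", "PwS", "uneven", spec, seed = 7)

ev <- detect_gait_events(rec$shank_ap, spec$fs)
ev <- trim_transient_strides(ev)          # drop 3 + 3 transient cycles
st <- extract_cycles(rec$trunk_signal, ev, n_cycles = 10)
compute_stability_features(st, speed = rec$speed)[c("RMS_VT", "HR_AP", "SampEn_AP")]
#>     RMS_VT    HR_AP SampEn_AP
#> 1 2.548235 2.534115  1.893935
```

A slow stroke-like walker (here ~0.60 m/s) shows a large speed-normalized
vertical RMS, a modest AP harmonic ratio and high AP sample entropy. The
same subject simulated with control-like parameters gives a lower `RMS_VT`
and higher `HR_AP` — the direction the classifier exploits.

```r
# Step 1 on the full synthetic cohort
coh  <- simulate_classification_cohort(spec, seed = 1)
tab  <- coh$features[c("group", stability_feature_names())]
plan <- experiment_plan(n_repeats = 10, task = "classification")
rep  <- run_classification(tab, plan)
head(rep$summary[c("model", "augmenter", "auc_mean", "auc_sd")], 3)
#>      model        augmenter  auc_mean     auc_sd
#> 1      svc             none 0.7982143 0.07601822
#> 2 logistic             none 0.7767857 0.04454354
#> 3 logistic smote_balance100 0.7723214 0.04358875
```

Mean test AUC around 0.80 is what the designed cohort supports: five
features shifted by d = 0.7 put the Bayes-optimal AUC near 0.87, and a
110-subject cohort fits models a few points below that ceiling. The
per-repeat values, grid choices and all artifacts are in `rep$raw`.

```r
# Step 2: read the embedded breakpoint off a random-forest PDP
reg <- simulate_regression_cohort(spec, n = 200, seed = 1)
pdp_locate_breakpoint(reg$features, "uneven_speed", "even_speed",
                      predictors = c("even_speed", "Ang_IC_ankle", "even_HR_AP",
                                     "even_RMS_VT", "even_SampEn_AP",
                                     "CI_TA_SOL_stance", "age"))
#> [1] 0.8904726
```

The locator recovers the 0.8 m/s breakpoint the generator embedded to
within a tenth of a m/s — the same analysis that, on real cohorts, flags
slow walkers as the group whose stability degrades most on uneven ground.

An end-to-end orchestration (`pipeline_simulate()` → `pipeline_extract()` →
`pipeline_classify()` → `pipeline_regress()` → `pipeline_interpret()` →
`pipeline_report()`) writes every artifact (feature CSVs, selection report,
tidy per-repeat metrics, odds ratios, sPLS-DA scores/loadings/VIP, PDP and
Shapley exports) with run manifests for reproducibility.

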