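# fallrisk

Wearable-sensor fall-risk assessment for stroke survivors: simulation,
signal segmentation, feature extraction, and classification in one tested
R pipeline.

## The problem

Stroke survivors fall often, and clinicians want to know *who* is at high
risk before the fall happens. One assessment protocol instruments each
subject with eight inertial sensors (both feet, shanks and thighs, pelvis,
thorax; 60 Hz; 3-axis segment angle, angular velocity and linear
acceleration each) while they perform a ten-task battery: quiet standing
with eyes open and closed, the Timed Up and Go (TUG), a 10 m walk, and a
five-repetition sit-to-stand (STS) — each once normally and once with a
concurrent cognitive (counting-backward) task, because dual-task
interference is where fall risk shows most clearly.

From those recordings this package:

1. **detects events** — heel strikes and toe-offs from shank resultant
   acceleration, the five TUG phases from thorax angular velocity, and STS
   cycles from thigh angular velocity;
2. **extracts a fixed 92-feature pool** — 42 motion features (postural
   sway, spatiotemporal gait, transition times), the same 42 on the
   dual-task trials (`Dual_` prefix), and 8 clinical/demographic features
   (including the short FES-I fear-of-falling score);
3. **classifies fallers vs non-fallers** with greedy forward feature
   selection wrapped around leave-one-subject-out (LOSO) cross-validation,
   using random forest, linear SVM, or ridge logistic backends; and
4. **searches reduced designs** — ablations (no motion features, no
   dual-task features) and an exhaustive search over sensor subsets ×
   test-battery subsets, for deployments with fewer sensors or less
   clinic time.

Clinical recordings cannot ship with a package, so a synthetic-data module
generates cohorts with the same structure, configurable faller/non-faller
effect sizes, and exact ground-truth annotations; every downstream stage is
validated against that truth. See `vignette("fallrisk-methods")` for the
generator's motifs, the segmentation heuristics, and the modeling
protocol (including why pooled-mode selection accuracy is optimistically
biased and when to use nested mode instead).

## Quick start

```r
library(fallrisk)

cohort <- generate_cohort(cohort_spec(n_fallers = 4, n_nonfallers = 4, seed = 42))
cohort
#> <fall_cohort> 4 fallers + 4 non-fallers, 80 trials @ 60 Hz

features <- assemble_feature_table(cohort)
features[, c(1, 2, 45, 94)]
#> # A tibble: 8 × 4
#>   subject_id `Balance_Thorax Linear Acc 1` Dual_Balance_Thorax Linear Ac…¹ label
#>   <chr>                              <dbl>                           <dbl> <int>
#> 1 S01                               0.0463                          0.0549     1
#> 2 S02                               0.0661                          0.0525     1
#> 3 S03                               0.0653                          0.0563     1
#> 4 S04                               0.0579                          0.0500     1
#> 5 S05                               0.0411                          0.0275     0
#> 6 S06                               0.0461                          0.0466     0
#> 7 S07                               0.0382                          0.0338     0
#> 8 S08                               0.0415                          0.0441     0
#> # ℹ abbreviated name: ¹​`Dual_Balance_Thorax Linear Acc 2`

fit <- forward_select(features, model_spec("logistic", seed = 1))
fit
#> <fall_eval> logistic, pooled mode: accuracy 1.00, sensitivity 1.00, specificity 1.00
#> selected: CE_Balance_Thorax Linear Acc 4

glance(fit)
#> # A tibble: 1 × 7
#>   classifier selection_mode accuracy sensitivity specificity n_features
#>   <chr>      <chr>             <dbl>       <dbl>       <dbl>      <int>
#> 1 logistic   pooled                1           1           1          1
#> # ℹ 1 more variable: n_subjects <int>
```

`tidy(fit)` gives the per-subject LOSO predictions and `autoplot(fit)` the
feature-addition accuracy trajectory. Note the perfect pooled-mode accuracy
above is descriptive, not an out-of-sample estimate — selection saw every
subject; use `model_spec(selection_mode = "nested")` for an honest
generalization figure.

Segmentation works directly on signals too:

```r
trial <- cohort$trials[["S01_STS_single"]]
thigh <- lowpass(abs(trial$sensors$thigh_L$angular_velocity[, "a2"]), filter_spec())
detect_sts_cycles(thigh, trial$fs_hz)
#> <sts_cycles> 5 cycles
```

Other entry points: `segment_tug()` and `detect_gait_events()` for the
remaining tasks; `run_ablation()` for reduced feature pools;
`search_configurations()` for the sensor × test-battery search;
`run_pipeline(pipeline_config(...))` for the whole chain from a YAML-round-
trippable config, with on-disk artifacts when `out_dir` is set; and
`write_cohort()` / `read_trial()` / `write_feature_table()` for the
documented CSV + JSON file layout, which external real data can follow.

## Testing

The suite uses testthat (3rd edition) and runs against the installed
package:

```r
testthat::test_dir("tests/testthat", package = "fallrisk",
                   load_package = "installed")
```

All fixtures are generated in code; there are no binary data files.
`tests/testthat/test-acceptance.R` holds one test per headline claim
(catalogue bookkeeping, battery structure, event-recovery accuracy,
feature-vs-truth agreement, metric identities, selection-oracle
equivalence, null-effect calibration, planted-effect recovery, filter
frequency response).

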