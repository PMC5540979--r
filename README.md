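# eegboost

Automated detection of driver fatigue from EEG signals: entropy features
over 1-second epochs, classified with a from-scratch AdaBoost ensemble of
depth-limited decision trees.

## What it does, and for whom

Fatigue changes the complexity of the electroencephalogram: a drowsy
brain produces more regular, alpha-dominated activity than an alert one.
This package is for researchers who want to turn that observation into a
reproducible two-state classifier. It takes multichannel recordings
labelled *normal* or *fatigue*, band-pass filters them to 0.15–45 Hz
(zero-phase Butterworth), windows every channel into non-overlapping 1-s
epochs (the atomic "unit"), and reduces each unit to up to four entropy
statistics:

- **FE** — fuzzy entropy: match-frequency ratio between embedding
  dimensions m and m+1 with the continuous membership `exp(−dⁿ/s)` on
  baseline-centred, SD-standardised templates;
- **SE** — sample entropy: `ln(B/A)` of hard template-match counts,
  self-matches excluded;
- **AE** — approximate entropy: the same idea with self-matches
  included, `φᵐ − φᵐ⁺¹`;
- **PE** — spectral entropy: Shannon entropy `Σ yᵢ ln(1/yᵢ)` of the
  normalised periodogram.

Defaults are `m = 2`, `s = 0.2·SD` per epoch, `n = 4`. Features are
min-max scaled to [−1, 1] per subject and channel, then classified by
discrete AdaBoost: each round trains a weighted-Gini decision tree
`D_m`, computes the weighted error `e_m`, sets
`α_m = ½ ln((1−e_m)/e_m)`, reweights
`W ← W·exp(−α_m y D_m(x))/Z_m`, and the ensemble decides by
`sign(Σ lr·α_m·D_m(x))`. The evaluation battery covers ERR, Precision,
Recall, F1, MCC, ROC/AUC (trapezoidal = Mann–Whitney), stratified
k-fold cross-validation over repeated runs, paired t-tests, and sweep
runners for tree depth, learning rate, test-set ratio and cohort size.
SVM (RBF) and Gaussian Naive Bayes comparators are available behind the
same adapter interface.

Because real fatigue EEG is rarely shareable, the package includes a
synthetic generator (two-state cohorts whose fatigue state mixes in a
variance-preserving 8–13 Hz oscillation controlled by an effect size δ,
with an exact null at δ = 0) and the `MIX(p)` sine–noise benchmark for
validating the entropy estimators.

## Worked example

```r
library(eegboost)

cfg <- synth_config(n_subjects = 4, n_channels = 2, fs = 128,
                    minutes_per_state = 0.5, effect_size = 1.5, seed = 42)
cohort   <- synth_cohort(cfg)                      # 8 recordings
epochs   <- assemble_dataset(cohort)               # 480 one-second units
features <- scale_features(extract_features(epochs, "FE"))

fit <- cross_validate(features,
                      baseline_classifier("adaboost", M = 50, max_depth = 3),
                      k = 10, n_runs = 5, seed = 42)
fit
#> <eb_eval> adaboost, 10-fold CV x 5 run(s): ERR 0.1087 +/- 0.0061, AUC 0.9616
glance(fit)
#> # A tibble: 1 x 8
#>     err precision recall    f1   mcc   auc  err_sd  auc_sd
#>   <dbl>     <dbl>  <dbl> <dbl> <dbl> <dbl>   <dbl>   <dbl>
#> 1 0.109     0.888  0.895 0.892 0.783 0.962 0.00614 0.00153
```

At effect size 1.5, fuzzy entropy alone separates the two states well:
about 11% of the 480 held-out units are misclassified and the mean ROC
area is 0.96 (an AUC of 0.5 is chance; at `effect_size = 0` the same
pipeline sits at chance by construction). `autoplot(fit)` draws the
mean ROC curve; `tidy(fit)` returns the per-run metrics. A fitted
ensemble itself is inspectable the same way:

```r
model <- adaboost_fit(as.matrix(features["FE"]),
                      ifelse(features$state == "normal", 1, -1),
                      M = 50, max_depth = 3)
head(tidy(model), 3)
#> # A tibble: 3 x 4
#>   round alpha  error depth
#>   <int> <dbl>  <dbl> <int>
#> 1     1 1.35  0.0625     3
#> 2     2 0.751 0.182      3
#> 3     3 0.391 0.314      3
```

Disk-based runs (`cmd_simulate()`, `cmd_extract()`, `cmd_evaluate()`,
or the wrapper script `inst/scripts/eegboost-cli.R`) write a manifest,
a feature CSV and a JSON report, all reproducible byte-for-byte from
the logged configuration and seed.

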