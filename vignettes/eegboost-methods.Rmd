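---
title: "Entropy features and AdaBoost for two-state EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy features and AdaBoost for two-state EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegboost)
```

## The problem

Sustained monotonous driving induces fatigue, and fatigue changes the
character of the electroencephalogram: the signal becomes more regular
and less "complex", with a relative rise of slow and alpha-band (8–13 Hz)
activity. eegboost implements an automated two-state (normal vs fatigue)
detector built on that observation. The unit of classification is a
single-channel, 1-second EEG window (an *epoch*); each epoch is reduced
to a small vector of entropy statistics and classified by a boosted
ensemble of shallow decision trees. Labels are encoded `normal = +1`,
`fatigue = −1` throughout, and "positive" always means normal.

## Signal handling

Recordings are matrices of channels × timepoints at a sampling rate
`fs`. They are band-pass filtered to 0.15–45 Hz with a 4th-order
Butterworth filter applied forward and backward (`signal::filtfilt`), so
the filter is zero-phase: entropy statistics are sensitive to waveform
shape, and a phase-distorting filter would alter them asymmetrically.
Filtered channels are then cut into non-overlapping windows of
`round(fs × window_s)` samples (default 1 s); a trailing partial window
is discarded. A 5-minute channel therefore yields exactly 300 epochs,
and a 28-subject × 2-state × 30-channel × 5-minute study yields 504,000
units, 252,000 per state — these counts depend only on durations, never
on `fs`.

## The four entropy features

All four statistics use the natural logarithm and share parameters
`m = 2` (embedding dimension), `s = 0.2 × SD` of the epoch (tolerance)
and `n = 4` (fuzzy gradient). The tolerance is computed from each
epoch's own SD, treating each 1-s window as locally stationary.

**Spectral entropy (PE)** is the Shannon entropy of the normalised
one-sided periodogram of the mean-removed window:
`PE = Σ yᵢ ln(1/yᵢ)` with `yᵢ = Yᵢ / Σ Yᵢ`. Zero-power bins contribute
nothing; a constant window returns 0 with a degenerate flag. The value
is reported in nats without dividing by `ln(n_bins)`; a `normalize`
option maps it to [0, 1]. The spectrum is taken over the full
post-filter band.

**Approximate entropy (AE)** compares the log-frequency of template
matches (Chebyshev distance ≤ s) between dimensions m and m+1:
`AE = φᵐ − φᵐ⁺¹` with `φᵐ = mean ln(Sᵢ / (L−m+1))`. Self-matches are
*included*, so every count is at least 1 and the logarithm is always
defined — the classic estimator's bias, accepted deliberately; a
`strict` toggle excludes them for study.

**Sample entropy (SE)** excludes self-matches and uses the same number
of templates (`L − m`) at both orders: `SE = ln(B/A)` where `B` and `A`
are total match counts at m and m+1. It is non-negative whenever
defined; when *no* pair matches at m+1 the statistic is undefined and
the epoch is flagged with an `NA` sentinel, excluded by
`extract_features()` and counted in `attr(, "n_excluded")` — exclusion,
not imputation, so downstream averages are never contaminated.

**Fuzzy entropy (FE)** replaces the hard indicator by the continuous
membership `D = exp(−dⁿ/s)` on baseline-centred templates (each
template has its own mean removed), making the statistic smooth in the
data and always finite. Because the exponent acts on the distance, the
printed membership applied to raw amplitudes would scale as
`c^(n−1)` under an amplitude gain `c`; eegboost therefore evaluates the
membership on the epoch standardised to unit SD with width
`s_coef = 0.2`. This is equivalent to the same formula on the
normalised series, and it restores the amplitude invariance a
gain-dependent feature must have (an EEG amplifier setting should not
move an entropy estimate). FE is likewise invariant to additive
offsets via the per-template centring.

A known asymmetry of the classical definitions — AE uses `L − m + 1`
templates at order m while SE and FE use `L − m` at both orders — is
kept as is; the estimators are validated against independently coded
brute-force oracles rather than against each other.

Summation order in all accumulations is fixed (ascending template
index) and everything is double precision, so results are bit
reproducible.

### Feature scaling

Features are min-max scaled to [−1, 1] separately within each
(subject, channel) group, fitting the map on all units by default —
the protocol that matches per-subject normalisation done before any
splitting. A `train_only` mode fits the ranges on training units and
applies them to test units (clipping out-of-range values by default)
for users who want strictly leak-free scaling; constant groups map to
0 with a warning.

## AdaBoost over depth-limited trees

The classifier is classic discrete AdaBoost, written from scratch
because the weak-learner contract matters: weights enter the *tree
induction* (weighted Gini impurity), not a resampling step, so training
is deterministic. Weak learners are binary axis-aligned trees whose
split candidates are midpoints between consecutive distinct sorted
feature values; ties are broken toward the smallest threshold, then the
lowest feature index, and leaves predict the weighted class majority
(ties → +1). Each boosting round computes the weighted
misclassification rate `e_m`, sets `α_m = ½ ln((1−e_m)/e_m)`,
reweights `W ← W·exp(−α_m y D_m(x))/Z_m` and accumulates the margin
`f_m = f_{m−1} + lr·α_m·D_m`. Degenerate rounds are handled explicitly:
`e_m = 0` clamps the error to 1e-10, keeps the (perfect) learner and
stops; `e_m ≥ 0.5` discards the learner and stops with a warning. The
continuous margin feeds the ROC sweep; its sign is the decision, with
an exactly-zero margin predicting normal (documented, configurable).
The recommended operating point for fatigue EEG features is
`max_depth = 9`, `lr = 1`, `M = 500`; tests and examples use smaller
ensembles purely for speed, which the boosting mathematics does not
depend on.

Comparator classifiers (RBF-kernel SVM and Gaussian Naive Bayes via
e1071, plus the bare depth-9 tree) sit behind a uniform fit/score
adapter so the evaluation harness treats all of them identically; a
small cross-validated grid-search hook covers hyperparameter tuning.

## Evaluation battery

With normal as the positive class: ERR = (FP+FN)/total,
Precision = TP/(TP+FP), Recall = TP/(TP+FN), F1 their harmonic mean,
and the Matthews correlation coefficient. Degenerate denominators
return 0 with a flag rather than NaN so parameter sweeps never lose
rows. The ROC sweeps thresholds over unique scores (ties grouped into
single steps) and AUC is trapezoidal — exactly the Mann–Whitney
pair-ordering probability, which the tests verify by exhaustive pair
counting.

Cross-validation is stratified k-fold (fold sizes within one unit,
class counts per fold within one unit), re-randomised across
`n_runs` independent rounds with seeds derived from one base seed;
fold assignment follows canonical unit keys, so results are invariant
to row order. Reported scalars are means over rounds with SDs. The
mean ROC across rounds is obtained by vertical averaging of the step
curves on a fixed FPR grid of 0.01 — the paired t-test between two
classifiers' per-round metrics is two-sided with n−1 degrees of
freedom.

Four sweep runners reproduce the usual robustness analyses: weak
learner depth, learning rate, test-sample ratio (stratified random
holdout, `train = round((1−ratio)·N)`, degenerate splits skipped with
a warning), and number of subjects (random subject subsets pooled and
cross-validated, 20 repeats by default).

## The synthetic generator

Real fatigue EEG is not redistributable, so the package ships a
generator whose default configuration mirrors the reference design —
28 subjects × 30 channels × 2 states × 5 minutes — at a default
`fs` of 250 Hz (1 kHz available by configuration; all unit counts are
fs-invariant). The normal state is 1/f-shaped broadband noise built by
spectral shaping of white noise. The fatigue state mixes the same
noise with a sinusoid at a per-channel random frequency in 8–13 Hz
(random phase, per-subject log-normal gain with σ = 0.2) and rescales
by `1/√(1 + a²/2)` so the variance is state-invariant; the effect size
δ multiplies the oscillation amplitude and at δ = 0 the two states are
draws from the same process, giving an exact null for calibration
tests.

Two generator choices deserve a note. First, the spectral exponent
defaults to 0.5 rather than the steeper 1/f often quoted for EEG:
after the mandatory 0.15–45 Hz zero-phase band-pass, a 1/f background
is already so smooth that *adding* an alpha oscillation would raise
FuzzyEn/SampEn, inverting the physiological premise that fatigue makes
the signal more regular; with exponent 0.5 (or 0) the entropy deltas
are negative and monotone in δ at both 128 and 250 Hz. Second, the mix
is variance-preserving so that the tolerance `s = 0.2·SD` is comparable
across states and the classifier cannot cheat off a trivial amplitude
difference.

The generator emulates stationary background activity plus a state
marker. It does *not* contain eye blinks, muscle artifacts,
non-stationary drifts, inter-channel correlation structure, or
volume-conduction topography — so passing tests demonstrate that the
estimators and the classifier behave as specified, not that the
pipeline is robust to the artifact content of real recordings.

The `MIX(p)` process — `(1−z_j)·√2·sin(2πj/12) + z_j·V_j` with
`z_j ~ Bernoulli(p)`, `V_j ~ U(−√3, √3)` — interpolates between a
deterministic sinusoid and unit-variance uniform noise and is the
standard family for validating that complexity estimators order
signals correctly: mean AE, SE and FE are strictly increasing in p.

## Numerical and design choices

- All seeds are explicit; every derived seed stays below 2³¹.
- Tie-breaks (split threshold, feature index, zero margin, weighted
  majority) are all documented and deterministic.
- The undefined-SampEn sentinel is exclusion + count, never imputation.
- Model persistence is versioned JSON (thresholds, leaves, alphas, lr),
  round-trippable to the last bit of the double representation.
- Problem sizes in the test-suite and acceptance script: the design
  counts use the full 28 × 30 × 2 × 5-minute cohort at `fs` = 100 Hz;
  end-to-end classification checks use 8 subjects × 1 channel ×
  1 minute per state at 128 Hz (960 units) with `M` = 60, depth-3
  trees, 10-fold cross-validation — sizes chosen so that the whole
  battery runs on a laptop in minutes while keeping every qualitative
  contract testable.

## Limitations

- EDF support covers continuous 16-bit EDF as written by the package
  (sufficient for round-tripping cohorts); EDF+ annotations and
  discontinuous records are out of scope.
- The evaluation harness assumes binary states; multiclass boosting
  (SAMME-style) is not implemented.
- Channel selection, artifact rejection, re-referencing and other
  preprocessing beyond the band-pass are out of scope.
- Entropy parameters are not auto-tuned; sensitivity to `m`, `s`, `n`
  should be explored with the provided sweep helpers when moving to a
  new recording setup.
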