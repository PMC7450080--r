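---
title: "Methods: medication-state classification from clinical EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: medication-state classification from clinical EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegmedstate)
```

## The problem

Clinical EEG archives pair multichannel recordings with free-text
physician reports that list, among other things, the medications a
patient was taking. `eegmedstate` implements a pipeline that asks whether
the EEG alone carries a detectable signature of anticonvulsant medication
state — phenytoin (Dilantin), levetiracetam (Keppra), or no medications —
separately within normal-EEG and abnormal-EEG strata, and whether a given
classifier's accuracy is distinguishable from chance by a random-label
control.

Real clinical corpora of this kind are access-controlled, so the package
ships a synthetic cohort generator that emulates the relevant data
properties end to end: multichannel recordings with controllable
class-dependent band-power structure, and report text with medication and
impression lines. Every downstream stage — labeling, preprocessing,
feature extraction, model fitting, and the significance protocol — is
exercised against this generator.

## Synthetic cohorts

Each recording holds the 19 canonical 10–20 channels (optionally plus A1,
A2 and EKG distractors, or with one canonical channel deliberately
missing). Per channel the signal is Gaussian noise shaped in the Fourier
domain: inside 0.5–50 Hz the power profile is $1/f$-like over the six
classical bands ($\delta$ 1–4, $\theta$ 4–8, $\alpha$ 8–12, $\mu$ 12–16,
$\beta$ 16–25, $\gamma$ 25–40 Hz) plus a flat broadband floor, and the
power inside each band is multiplied by that class's planted factor. A
common source is mixed into every scalp channel with weight 0.3 so that
common-average referencing is non-trivial. The band shaping is an ideal
(brick-wall) Fourier-domain mask — the fixed, documented filter choice for
the generator; only band structure matters downstream, and the mask makes
the planted power factors exact in expectation. Signals are scaled so a
neutral recording has an RMS of a few tens of microvolts.

The planted effect size is a free parameter of the generator. There is no
empirical anchor for how strongly an anticonvulsant shifts band power, so
the property checks in this package use an alpha-power factor of 0.5 — a
strong, unambiguous planted effect — and verify detection, not effect-size
realism. Passing these checks shows the machinery is correct and
calibrated (type-I error at the nominal level on null cohorts); it does
not show that real medication effects are detectable, which requires the
real corpus. The generator also does not emulate artifacts (blinks, EMG),
seizure morphology, or longitudinal structure within subjects; reports
follow a fixed minimal grammar (`MEDICATIONS:` / `IMPRESSION:` / `AGE:` /
`SEX:` lines) rather than real report formats.

Determinism: every recording is reproducible from `(seed, class, subject
index)`; all downstream seeded steps derive their streams from a master
seed, so a cohort → features → accuracies run is bit-reproducible.

## Report labeling

Labeling is a deliberate keyword stand-in for a validated report
classifier: the medication list is read from the `MEDICATIONS:` line with
case-insensitive brand/generic canonicalization
(Dilantin ↔ phenytoin, Keppra ↔ levetiracetam); two or more medications,
or one unrecognized medication, exclude the recording (drug-interaction
confounds); the pathology stratum comes from `abnormal`/`normal` keywords
in the `IMPRESSION:` line, with an `unknown` fallback. Negation is not
handled. Each recording is labeled independently; reconciling
within-subject disagreements across sessions is out of scope.

## Preprocessing

Every usable recording becomes a 19 × 30,000 segment at 100 Hz:

1. **Channel selection** into the fixed order Fp1, Fp2, F3, F4, C3, C4,
   P3, P4, O1, O2, F7, F8, T3, T4, T5, T6, Fz, Cz, Pz. Label matching
   strips an `EEG ` prefix and `-REF`/`-LE` suffix and ignores case. Any
   missing canonical channel rejects the whole recording.
2. **Cropping** to seconds [60, 360): the first minute is discarded,
   exactly five minutes retained (half-open sample windows, 0-based
   offsets at the native rate). Recordings shorter than 360 s are
   rejected.
3. **Down-sampling** to 100 Hz by polyphase resampling at the rational
   ratio (256 Hz resolves as 25/64). Rates below 100 Hz are an error —
   up-sampling is not part of the procedure.
4. **Filtering and referencing**: a 4th-order Butterworth high-pass at
   0.5 Hz applied forward–backward (zero-phase) per channel, then common
   average referencing. The nominal band-pass is 0.5–50 Hz; at 100 Hz the
   upper edge coincides with Nyquist, so the low-pass branch is an
   identity and only the high-pass branch is realizable. The filter
   family, order, and phase handling are not dictated by the procedure's
   description; the choice here (Butterworth 4, `filtfilt`-style with
   odd-reflection padding) is recorded in each segment's provenance so it
   can be varied. Step order is crop → resample → filter → reference,
   following the narrative order of the source procedure.

Rejection is total: `preprocess_recording()` returns either a canonical
segment or an `omitted_recording` carrying the reason — never an
exception for data-dependent conditions.

## The 570-feature battery

Thirty features per channel × 19 channels. Spectral features come from
the one-sided rectangular-window periodogram of the full 30,000-sample
segment, scaled so total power equals the signal's mean square: six
absolute band powers (sum of PSD bins with $lo \le f < hi$), six relative
band powers (absolute / total), and two Shannon entropies — of the raw
periodogram values and of the periodogram normalized to a probability
distribution (natural log, $0\log 0 := 0$). The normalized/raw pair is
the only reading that keeps the two entropies distinct; z-scoring the
signal instead would make them equal, so that interpretation was
rejected.

Time-domain features: amplitude-histogram entropy of the z-scored signal
(100 bins on $[-5, 5]$), mean-thresholded Lempel–Ziv complexity (LZ76
exhaustive-history phrase count of $1\{x \ge \bar x\}$, reported raw — the
battery says mean-thresholded, not normalized), curve length
$\sum|x_n - x_{n-1}|$, energy $\sum x^2$, Teager non-linear energy
$\sum (x_n^2 - x_{n-1}x_{n+1})$, sixth power $\sum x^6$, min, max,
median, variance and standard deviation (denominator $n$), skew and
non-excess kurtosis, the integral $\sum x / f_s$, and Hjorth mobility
$\sqrt{\operatorname{var}(\Delta x)/\operatorname{var}(x)}$ and
complexity (mobility of $\Delta x$ over mobility of $x$). Degenerate
constant signals return 0 for entropy, mobility, complexity, skew and
kurtosis.

The classical battery enumerates 31 names but the advertised total is 30
per channel. The redundant member is `sum`: at fixed sampling rate it is
an exact scalar multiple of `integral`, so the default registry drops it
(`feature_vector(..., include_sum = TRUE)` restores the 31-feature
variant). Spectral features use the full one-sided grid to Nyquist rather
than being clipped to the filter passband. `feature_registry()` emits the
formula of every feature.

The LZ76 count is computed by suffix-array LZ factorization
(linear-time), which on 30,000-sample segments is two orders of magnitude
faster than the textbook quadratic scan; tests verify exact agreement
with the exhaustive-history scan on random sequences, including the
classic worked 16-symbol example (6 phrases).

## Feature transforms

Max normalization is fitted on training rows only: per feature,
$t(x) = (x - \mu_{train}) / M_{train}$ where $M$ is the maximum of the
*raw* training values (the literal reading of the transform's
description); a zero maximum maps to 0. Note the consequence: training
values of a non-negative feature land in $(-1, 1]$, not $[0, 1]$ — the
often-quoted $[0,1]$ range holds only approximately, and the formula wins
here. Reduction is PCA (top-$k$ components on the max-normalized training
matrix, centered, not re-standardized) or K-best (largest one-way ANOVA F
between the two classes). Fit functions never receive test rows; the
leakage-freedom is enforced by interface and asserted by tests.

## Classifiers

**SVMs.** Linear SVM and RBF-kernel SVM (libsvm via `e1071`, no internal
scaling) tuned by grid search over reduction ∈ {PCA, K-best}, retained
dimensions ∈ {60, 120, 210, 390, 570}, C ∈ {1, 10, 100, 1000} and, for
the RBF kernel, γ ∈ {0.1, 0.01, 0.001} — 120 kernel-SVM configurations,
40 linear. Scoring is an inner 10-fold cross-validation on the training
partition with max normalization and reduction re-fitted inside every
inner fold (the leakage-safe reading; whether the original procedure
re-fitted inside inner folds is not stated). Ties break toward smaller
k, then smaller C, then larger γ — prefer simpler models; the winning
configuration is refitted on the full training partition.

**Random forest.** Fixed configuration, no search: 100 trees, minimum 2
samples to split, minimum 1 per leaf, no depth cap, Gini impurity
(`randomForest`, seeded).

**Networks.** Four feed-forward architectures on the raw 19 × 30,000
input (channels × time, canonical order), implemented on an in-package
engine (dense, temporal/spatial/depthwise/separable convolutions, batch
norm, ELU, square/log, mean pooling, dropout, softmax cross-entropy,
Adam) with analytically derived backward passes, gradient-checked in
tests:

* **LNN** — flatten → dense softmax, no bias: 1,140,000 weights
  (2 × 19 × 30,000).
* **SCNN** — temporal conv (40 filters, length 25, with bias) → spatial
  conv across the 19 channels (40 filters, no bias) → batch norm → square
  → mean pool (length 360) → log → dropout 0.5 → dense softmax (with
  bias): 38,162 weights. The square/mean-pool/log stage is the
  log-variance analogue of filter-bank common spatial patterns; the
  temporal-then-spatial factorization is the FBCSP-inspired split.
* **DCNN** — the same split first stage (25 filters, temporal length 16)
  then three further conv–pool pairs (50, 100, 200 filters, length 10;
  ELU; batch norm; dropout 0.5; mean pools 3, 9, 9, 10) → dense softmax
  (with bias): 279,927 weights.
* **EEGNet** — temporal conv (8 filters, length 50, same-padding) →
  depthwise spatial conv (depth 2) → separable conv (depthwise length 16
  then pointwise), ELU, batch norm, dropout 0.25, mean pools 8 and 10 →
  flatten → dense softmax with no bias ("softmax applied directly to the
  flattened features"): 13,296 weights.

The published totals pin down an accounting that the architecture
sketches alone underdetermine. The accounting that reproduces all four
printed numbers simultaneously — and is therefore adopted — counts
batch-norm affine pairs, omits convolution biases wherever batch norm
follows, and gives a classifier bias to SCNN/DCNN but not to LNN/EEGNet.
Kernel and pool lengths not legible from the sketches (the DCNN temporal
length 16 and pools 9/9/10, the SCNN pool 360, EEGNet's pools 8/10) were
chosen to reproduce those totals; `network_registry()` records the full
per-layer resolution. Builders accept overrides so scaled-down shapes can
be trained in tests.

**Two-run training.** Run 1 trains exactly 35 epochs (Adam, learning rate
1e-3, batch size 64, cross-entropy — conventional defaults where
unstated), recording per-epoch training accuracy and loss; the best epoch
is the highest training accuracy (ties → earliest). Run 2 restarts from
*fresh* initialization and stops at the first epoch whose training loss
reaches run 1's loss at the best epoch, capped at the same budget with a
warning. The restart semantics are ambiguous in the source description
(warm start vs fresh restart with a loss target); the criterion is called
a stopping condition on a specified training loss, which motivates the
fresh-restart default, and `restart = "warm"` selects the other reading.
A 10% validation split is carved from the training partition for
monitoring only and never overlaps test data; run 2 reuses the same
carve-out.

## Evaluation and significance

Tasks are balanced by down-sampling the majority class (seeded, without
replacement) to the minority count inside one pathology stratum. The
balancing unit is the recording: the published task sizes equal twice the
minimum of the published per-class *recording* counts (e.g. 2 × 320 =
640 with test sets of floor(0.1 · 640) = 64), which is what fixes this
choice; subject-level grouping is not modeled. The protocol draws ten
independent seeded random 90/10 splits — the procedure's own description
of its "10-fold cross-validation", as repeated random splits rather than
a partitioned 10-fold — stratified per class, with test size
floor(0.1 · n). For each split all transforms and tuning are fitted on
the training partition only. The random-label null repeats the identical
protocol with training labels shuffled once per split (seeded from the
master seed and split index); test labels are never touched. The null is
re-tuned with the same search as the correct-label run (the conservative
reading), which a restricted `grid` argument can relax.

Significance: the in-package Kruskal–Wallis statistic on the two
ten-accuracy vectors — joint mid-rank ranking,
$H = \frac{12}{N(N+1)} \sum R_i^2/n_i - 3(N+1)$ divided by the tie
correction $1 - \sum (t^3 - t)/(N^3 - N)$, with $p$ from $\chi^2_1$ (two
groups; the standard large-sample approximation). Tiers: `*` for
$p < .01$, `**` for $p < .001$, `ns` otherwise, thresholds honored
exactly. `compare_cv_results()` provides the analogous pairwise contrasts
across tasks or methods. With ten discrete accuracies per arm the
chi-square approximation is conservative under heavy ties, which is the
desirable direction for the null-calibration guarantee.

## Problem sizes used by the checks

The package's property checks run the full generate → label → preprocess
→ featurize → evaluate chain at sizes chosen to make the suite a
practical single-CPU run while keeping every statistical claim testable:

* planted-null calibration: 50 independent cohorts of 40 recordings
  (20 per class), random forest, ten-split protocol with its
  random-label null; asserted: chance-level mean accuracy and a
  false-significance rate ≤ 5% at the .01 threshold;
* planted-effect power: 20 independent cohorts of 100 recordings
  (50 per class) with the alpha factor 0.5, kernel SVM at the most
  common tuned configuration (K-best, 210 dimensions, C = 10, γ = 0.1)
  rather than the 120-point grid search per run — the search itself is
  validated separately at small scale; asserted: mean accuracy > 0.6 and
  a significant tier in ≥ 80% of runs;
* feature correctness: all 30 features against independent naive-loop
  oracles (direct-DFT periodogram, explicit-loop statistics,
  exhaustive-history LZ76 scan) on 50 random 512-sample signals at 1e-9;
* statistic correctness: the Kruskal–Wallis implementation against a
  counting-based rank oracle and `stats::kruskal.test` on 100 random
  tied inputs at 1e-9;
* network training at reduced input shapes with gradient checks per
  architecture; the canonical-shape builds are verified by weight count.

The headline accuracies of the motivating study (all ≤ 73.46%) are not
reproduction targets: they require the access-controlled clinical corpus
and GPU-scale training. What this package reproduces exactly are the
structural numbers — 570 features, 120 grid points, the four weight
totals, the balanced task sizes — and the behavioral guarantees above.

## Known limitations

* The synthetic generator's effects are stationary band-power shifts;
  detectability of real pharmacological signatures is not addressed.
* The network engine is plain R: correct and gradient-checked, but meant
  for scaled-down experiments, not full-cohort training.
* The chi-square Kruskal–Wallis $p$ is an approximation for n = 10 + 10;
  an exact permutation variant is a natural extension.
* EDF support covers continuous 16-bit files with one rate across
  channels (the emulated corpus style), not discontinuous EDF+ records.
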