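---
title: "Methods: EEG microstate segmentation, features, and task-performance classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG microstate segmentation, features, and task-performance classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The model

Spontaneous EEG topographies do not drift continuously: the scalp potential
field remains quasi-stable for roughly 60–120 ms and then switches abruptly
to a new configuration. These quasi-stable periods are *microstates*, and in
the four-class archetype taxonomy they are labelled A (left–right dominant
orientation), B (right–left), C (anterior–posterior), and D (a
fronto-central focal maximum). `microstatr` implements the full analysis
chain for a two-group (good/poor performer), two-condition (rest/task)
cognitive-task design:

1. **Preprocessing** — 2–20 Hz zero-phase band-pass, common-average
   re-reference, 2-s epoching, threshold artifact rejection;
2. **Segmentation** — polarity-invariant modified k-means on GFP-peak maps,
   best of 20 re-runs by global explained variance (GEV), archetype
   labeling, sample-wise backfitting;
3. **Features** — 36 per-epoch features: 18 microstate features (duration,
   occurrence, coverage, mean GFP per class, plus mean duration and mean
   occurrence), 12 ordered transition percentages, 6 directional
   predominances with a run-shuffling permutation test;
4. **Statistics** — Mann–Whitney contrasts between the four state groups
   (PR, PT, GR, GT) with Bonferroni–Holm correction, and one-sample tests of
   predominance against zero;
5. **Classification** — balanced downsampling, recursive feature
   elimination (RFE) with repeated cross-validation, eight classifiers
   (LR, linear/polynomial/RBF SVM, kNN-2/5/10, random forest), and
   accuracy/AUC/sensitivity/specificity reporting.

Every stage is testable without external data because the package ships a
synthetic generator with known ground truth (module 0, below).

### Global field power and global explained variance

The per-sample field strength is the reference-free root-mean-square
deviation across the $N$ electrodes,

$$\mathrm{GFP}(t) = \sqrt{\frac{1}{N}\sum_{i=1}^{N}
  \bigl(V_i(t) - \bar V(t)\bigr)^2},$$

and topographic shape is compared by the spatial (channel-wise Pearson)
correlation between average-referenced vectors. The clustering objective is
the GFP-weighted squared correlation between each sample and its assigned
template,

$$\mathrm{GEV} = \frac{\sum_t \mathrm{GFP}(t)^2\,
  \mathrm{corr}\bigl(V(t), m_{\ell(t)}\bigr)^2}{\sum_t \mathrm{GFP}(t)^2}
  \in [0, 1].$$

### Modified k-means

Clustering operates on the maps at GFP local maxima only (where
signal-to-noise is best); backfitting then labels every sample. The
"modification" relative to ordinary k-means is polarity invariance:
assignment maximizes the *squared* spatial correlation, and each template is
updated as the first principal direction of its assigned maps, so the sign
of any map is irrelevant in both steps. Iteration stops when the relative
GEV change falls below `1e-6` or after 1000 iterations; 20 random restarts
are run and the restart with maximal GEV kept. GEV is non-decreasing within
a run (both steps are coordinate ascent on it), which the test suite
asserts, and on small instances (≤ 8 maps, k = 2) the result equals an
exhaustive enumeration over all bipartitions with the analytic per-part
template.

Defaults follow standard practice for this family of analyses: k = 4,
20 re-runs, threshold 1e-6, 1000 iterations, random GFP-peak maps as seeds,
ties everywhere broken toward the lowest archetype index, no temporal
smoothing and no minimum-segment rejection (both deliberately absent rather
than hidden defaults: the feature definitions below assume the raw labels).

### Archetype labeling

The four fitted maps are matched to built-in canonical orientation
templates — smooth dipolar fields over the 2-D 10–20 electrode positions —
by maximizing the summed absolute correlation over all 24 permutations.
The canonical A/B axes are tilted 30° off the left–right electrode axis
(left–right dominant with a frontal component): a pure 45° diagonal would
make the left–right and anterior–posterior projections exactly tie, and the
tilt makes the A/B versus C distinction well defined. Type D is a focal
fronto-central Gaussian, following the methods convention for this
taxonomy (descriptions of D as occipital exist in the literature for the
same label; the fronto-central convention is implemented).

## Module 0: the synthetic generator

The generator emulates exactly the properties the downstream statistics
measure, with every law configurable:

* **Topographies** — the four canonical templates plus a seeded smooth
  perturbation, re-centered and unit-normalized; pairwise |corr| < 0.95.
* **State sequence** — a first-order Markov chain over the four classes with
  a row-stochastic, zero-diagonal transition matrix (default uniform
  off-diagonal) and truncated-geometric dwell lengths in samples (minimum
  1 sample), mean 80 ms per class by default — inside the 60–120 ms
  quasi-stability range. Geometric dwell is the memoryless law consistent
  with the Markov surrogate and has a single controllable mean.
* **Amplitude** — each segment gets a random sign (p = 1/2, which is what
  forces polarity invariance to matter), a uniform(0.7, 1.3) scale, and a
  half-sine within-segment envelope with floor 0.25, normalized to unit
  mean, so GFP peaks fall inside segments and the mean noiseless GFP equals
  `gfp_mean_uv` (default 5 µV).
* **Noise** — spatially correlated Gaussian noise (squared-exponential
  covariance over electrode distances, length scale 0.6), scaled so
  signal-RMS/noise-RMS equals `snr` (default 5). White noise would make
  GFP-peak extraction unrealistically easy; spatially smooth noise produces
  plausible spurious topographies.
* **Cohort** — 26 good and 10 poor performers by default, one 3-min rest and
  one 1-min task recording each at 500 Hz, with group-by-condition effects
  injected as per-class dwell multipliers (e.g. `list(GT = c(1,1,1,1.2))`
  raises class-D dwell by 20% in the good-performer task state only).

What the generator does **not** emulate: biophysical sources, eye/muscle
artifacts, 1/f background spectra, inter-subject topography variability, or
within-subject nonstationarity. Passing recovery tests therefore shows the
algorithms are correct on data satisfying the model's own assumptions — not
that real recordings satisfy them.

One interaction deserves note: the 2–20 Hz band-pass is part of the real
pipeline, but applied to the generator's piecewise-constant signal it smears
energy across segment boundaries, so sample-wise label agreement against
the generating sequence is measured on unfiltered (re-referenced) data,
while map recovery — which is unaffected (|corr| ≈ 0.997 either way) — is
measured through the full chain.

## Feature definitions and boundary policy

For one epoch, with runs obtained by run-length encoding the label sequence:

* `duration_k` — mean run length (ms) of class *k* over runs **not**
  truncated by the epoch boundary (the first and last runs extend past the
  window, so including them biases durations downward);
* `occurrence_k` — runs of *k* starting in the epoch per second (the first
  run counts as a start), in Hz;
* `coverage_k` — percentage of samples labelled *k*; the four coverages sum
  to 100 by construction;
* `gfp_k` — mean GFP over samples labelled *k* (µV);
* `mean_duration`, `mean_occurrence` — the same quantities across classes;
  `mean_occurrence` equals the sum of the four occurrences exactly.

A class absent from interior runs has undefined duration; it is imputed
with 0 in the assembled 36-vector and the name recorded in the `imputed`
attribute. The identity `coverage ≈ occurrence × duration / 10` (%, Hz, ms)
is exact only when truncated runs are excluded from all three features
symmetrically (`boundary = "symmetric"`); under the default policy it holds
asymptotically in epoch length and is noisy on 2-s epochs, where a class has
only a handful of runs.

Transitions are counted at run boundaries: 12 ordered percentages (summing
to 100 whenever a boundary exists) and 6 directional predominances
$P(X{\to}Y) - P(Y{\to}X)$ in the fixed order (A,B), (A,C), (A,D), (B,C),
(B,D), (C,D). Time-reversing a sequence negates every predominance and
leaves the 18 microstate features unchanged — a property test.

### The asymmetry permutation test

The null is built by uniformly shuffling the order of the runs (lengths
stay attached to their classes) and recomputing the asymmetry each shuffle,
with the two-sided add-one estimator
$p = (1 + \#\{|T_{\mathrm{null}}| \ge |T_{\mathrm{obs}}|\})/(B + 1)$.
The permuted statistic is the studentized count difference

$$T = \frac{N_{XY} - N_{YX}}{\sqrt{N_{XY} + N_{YX}}},$$

not the raw percentage difference. The reason is calibration: a shuffled
run sequence contains adjacent equal classes that merge, so its boundary
total differs systematically from the observed (no-repeat) sequence, and
the percentage-normalized difference is not pivotal across that change —
measured on symmetric-chain sequences it rejects at ≈ 0.02 instead of 0.05
(and the unnormalized count difference at ≈ 0.13). The studentized form is
the binomial-style direction z — given the pair total, the direction split
behaves binomially in both the sequence law and the shuffle null — and
calibrates correctly. The reported effect size remains the percentage
predominance. The analytic independence expectation of the asymmetry under
the shuffle null is zero by symmetry; the realized null mean is returned
alongside for comparison.

## Statistical comparisons

Contrasts (PR vs PT, GR vs GT, PT vs GT) use the Mann–Whitney rank-sum
test at the **epoch** level, mirroring the source design (epochs from the
same subject are dependent; this deliberately matches the reference
analysis design, and
subject-level aggregation is available by pre-averaging the feature table).
p-values are exact (null U distribution) for tie-free samples with both
n < 50 and otherwise use the tie-corrected, continuity-corrected normal
approximation; z is always the signed normal-approximation statistic
(positive = first sample stochastically larger). Bonferroni–Holm correction
is applied within each contrast and feature block — the 18 microstate
features, the 12 transitions, the 6 predominances — the narrowest
defensible family. The vs-zero test for predominance is a sign-flip
permutation test of the mean (10,000 flips, add-one, two-sided), with a
Wilcoxon signed-rank alternative.

## Classification harness

The cohort is unbalanced, so classification starts from a uniform random
subsample of 250 epochs per group. RFE ranks features within each training
fold only (|coefficient| for LR and linear SVM after z-scoring;
permutation importance — training-accuracy drop under column shuffling —
for the kernel SVMs, kNN, and the forest), drops the lowest-ranked feature,
and records held-out accuracy at every feature count; the curve is averaged
over 5 folds and repeated splits (100 repetitions by default, each
optionally re-drawing the subsample). Standardization parameters come from
the training fold only; a label-shuffle null keeps the whole harness honest
(accuracy ≈ 0.5 at every count). Defaults: SVM cost 1, RBF width by the
median pairwise-distance heuristic, 500 trees, stratified folds under a
recorded seed. AUC uses the rank formula (ties half-counted) and is checked
against an exhaustive pairwise oracle; per-fold ROC points are exported.

## Numerical choices and degenerate inputs

* Zero-field samples have undefined correlation; they are assigned class A
  (lowest index) with correlation 0, consistent with the global lowest-index
  tie-break.
* Empty clusters during k-means are refilled with the worst-fitted maps.
* A single-run epoch yields an all-zero transition vector with a
  `no_transition` flag, and the asymmetry test returns NA with a flag.
* Artifact rejection is a pure predicate (amplitude > 100 µV or per-channel
  variance > 500 µV², plus an optional manual-exclusion list standing in
  for visual inspection), so the kept set is reproducible.
* All stochastic steps take explicit integer seeds; derived sub-seeds stay
  below 2³¹.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use scaled synthetic designs
chosen as this package's own verification sizes: 8 subjects × 60 s for
topography/dwell recovery (19 channels, snr 5); 200–500 two-second epochs
per cell for feature identities and the planted +20% class-D dwell effect;
500 sequences × 1000 permutations (~400 runs per sequence, i.e. ~32 s of
80 ms states — long enough that the discrete permutation null is no longer
conservative under the add-one estimator) for calibration of the asymmetry
test; 250 epochs per group for the classification harness. The
empirical-convergence checks for the generator run at 10⁶ samples.

## Known limitations

* Epoch-level testing inflates effective sample size on real cohorts;
  subject-level aggregation is the defensible alternative and is one
  `aggregate()` away.
* Backfit dwell times are biased short at finite SNR (label noise fragments
  runs); at snr = 5 the bias is ~10–15% of an 80 ms dwell. Temporal
  smoothing would reduce it but changes the feature definitions, so it is
  deliberately opt-out by default (and not implemented here).
* The archetype matcher assumes the four canonical orientations are an
  adequate basis; pathological maps (e.g. all four nearly collinear) get a
  labeling, but the reported match scores should be inspected.
* EDF input is out of scope; recordings travel as a numeric matrix plus a
  JSON sidecar (`write_recording()` / `load_recording()`).

## A minimal end-to-end run

```{r example, eval = FALSE}
tp    <- generate_topographies(19, seed = 1)
truth <- microstate_truth(topographies = tp, snr = 5, seed = 1)
lab   <- generate_state_sequence(truth, 30000, 500, seed = 2)
rec   <- synthesize_eeg(truth, lab, seed = 3)
rec$subject_id <- "S01"; rec$condition <- "rest"; rec$group <- "good"

pp    <- preprocess_recording(rec)           # filter, re-ref, epoch, reject
model <- fit_microstates(pp$kept, seed = 4)  # pooled GFP-peak clustering
model$gev
ft    <- feature_table(pp$kept, model)       # 36 features per epoch
head(ft[, 1:8])
```
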