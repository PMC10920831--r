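---
title: "Population analysis of feeding-related neural activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analysis of feeding-related neural activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FeedScope)
```

# Scope

FeedScope analyses single-cell calcium-imaging trace matrices and fiber
photometry recorded while an animal approaches and consumes food. The
pipeline runs in five stages: behavioral epoch detection from pose,
trace preprocessing and event-locked quantification, population-geometry
statistics across co-registered sessions, matched-sample decoding and
bootstrap GLM cell classification, and an orchestrating report layer. A
synthetic-session generator with planted ground truth makes every stage
testable end to end without any recordings.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic data do and do not show about
real recordings.

# Behavioral epoch detection

Pose trackers deliver per-frame nose, ear and tailbase coordinates at
30 samples/s. *Head position* is defined as the midpoint of the two ear
coordinates (the nose is available as an alternative via
`headPosition(pose, "nose")`): trackers do not emit a "head" point, and
the ear midpoint is markedly more stable than the nose during feeding.

`detectApproach()` implements the approach definition: a maximal run of
samples with (1) continuous movement toward the food target, (2) a net
decrease in head-to-target distance of at least 10 cm, and (3) speed at
or above 2 cm/s at every sample. "Continuous movement toward" is not
defined at sample level by any standard; we operationalize it as a
non-increasing distance allowing a per-sample increase of up to 0.5 cm.
Without this tolerance, sub-millimetre tracking jitter fragments every
real approach into many short runs that individually fail the 10-cm
rule. Speed is a central difference over two frames; the first and last
samples copy their nearest neighbor.

Rearing (`detectRearing()`) is a threshold rule: in a circular arena,
head within 2 cm of the wall (the margin is exposed because only "a
minimum distance" is standard, not its value); in a rectangular arena, a
vertical coordinate above the wall-height threshold.

Eating cannot be derived from pose — in real experiments it is scored
manually — so eating epochs always enter through epoch tables; the
synthetic generator plants them.

All epochs are half-open `[start, end)` in seconds with 0-based
indexing. `rasterizeEpochs()` projects epochs onto any monotone time
grid with the fixed overlap priority eat > approach > rear, making ties
deterministic.

# Trace preprocessing and event-locked measures

Cell inclusion follows the variance rule: keep cells whose trace
variance is at least 10% of the maximum variance among non-outlier
cells. The outlier pass is unspecified in the underlying rule, so we
use a conventional two-pass Tukey fence: cells above Q3 + 1.5 IQR of
the per-cell variances are excluded from the reference maximum (they
remain candidates for inclusion themselves). This keeps one saturated
cell from silencing the population.

`alignToEvents()` builds events × offsets × cells tensors on the trace
grid; events whose window crosses a session edge are dropped and
counted. Pre/post eating modulation is the mean over events of
post-onset minus pre-onset mean df/F; windows default to 5 s per side,
a value consistent with the multi-second pre-eating activation the
analysis is designed to expose, and configurable because nothing pins
it more precisely.

`meanPeakAmplitude()` averages strict local maxima (both neighbors
smaller); a plateau contributes once, at its first sample. The series
is used as supplied — no denoising is applied first.

Isosbestic correction (`photometryCorrect()`) fits the 405-nm reference
to the 470-nm signal by ordinary least squares over the whole session
and returns `(sig - fit)/fit`. Any artifact that is an affine function
of the reference — motion, slow bleaching — is removed exactly (the
residual is at numerical zero in the noise-free case), while
calcium transients, which are absent from the reference, survive. A
rank-deweighted iterated fit is available behind `robust = TRUE` for
sessions where transients are so dense they tilt the OLS fit. A
constant reference falls back to baseline-percentile df/F with a
warning.

# Population geometry

`embedPCA()` fits a PCA over all session samples with cells as
variables and keeps the top three components for the approach/eat/rear
samples. Cells are z-scored first by default so high-amplitude cells do
not dominate the rotation; the raw option is retained. Component signs
are fixed by making each component's largest-magnitude loading
positive, which removes the sign ambiguity from tests and makes
repeated runs comparable.

`silhouetteScore()` is implemented in the package (vectorized over a
distance matrix for up to 3000 samples, and in row blocks directly from
coordinates above that, so no n × n matrix is ever held); both paths
agree to numerical precision and are checked against a brute-force
oracle in the tests. Samples in singleton clusters get a width of 0 by
convention. The chance level (`chanceSilhouette()`) permutes the label
vector; a circular-shift null was considered and rejected as the
default because epoch durations already enter through the label run
lengths, and plain permutation is the construction the score is
compared against. On strongly clustered clouds the permutation mean is
slightly below zero (order −0.01 at a few thousand samples) because the
silhouette's `b(i)` takes a minimum over competing cluster means; this
finite-sample effect shrinks with cluster size.

Cross-assay conservation uses the Mahalanobis distance of one assay's
behavior samples to the other assay's cluster, in the full neural space
(dimensions = co-registered cells) by default — a PC-space option
exists. Since no direction is canonical, both directions are computed
and pooled. A singular covariance is ridge-regularized with
`lambda = 1e-6 × mean(diag(Sigma))`. The eat-versus-approach contrast
is a two-tailed rank-sum comparison with a tie-corrected z
approximation (exact p below 25 samples per group).

# Decoding and cell classification

`buildDecodingDataset()` takes every trace sample in the 2 s after each
behavior onset as positives — the interval reading `(onset, onset + 2]`
was chosen over the single sample at onset + 2 s, which would discard
almost all the data — and samples an equal number of negatives
uniformly from outside all epochs of that behavior, so chance is 50%.
Sessions with fewer than five behavior epochs are excluded
(`sessionInclusion()`).

`crossvalDecode()` uses five contiguous-in-time folds; training rows
within 10 s of the validation block are dropped. Contiguous blocks were
chosen over random folds because they prevent temporal leakage by
construction; the 10-s gap then only needs to trim the block
boundaries. The classifier is a softmax (multinomial-logistic) fit with
a small ridge penalty (`decay = 1e-4`); features are z-scored with
training statistics by default, with a raw option. Chance-level inputs
decode at 50% within fractions of a percentage point when averaged over
seeds; single sessions scatter by 2–3 points, slightly below 50 on
average because contiguous folds anti-correlate training and
validation class imbalances.

Per-cell behavior coefficients come from a Gaussian identity-link GLM
of the trace on the 0/1 behavior indicator. With this family the
coefficient *equals* the in-behavior minus out-of-behavior mean df/F
(verified to machine precision in the tests), which makes the bootstrap
classification directly interpretable as a rate contrast; other links
can be hooked in where traces are transformed first.

The null (`bootstrapOnsetNull()`, `classifyCells()`) redraws epoch
start times uniformly, preserving durations, non-overlap and session
bounds — a circular-shift alternative sits behind a flag. One shuffled
schedule per iteration is shared by all cells of a session, so the 100
null coefficients of different cells are computed against the same
schedules, as a session-level analysis should. A cell is `+` (or `-`)
when its coefficient strictly exceeds (or is exceeded by) at least 95%
of the 100 null values; exact ties count against significance. With
100 shuffles this is a 6/101 ≈ 5.9% nominal rate per tail; on
unmodulated synthetic cells the empirical rates sit near that value,
fluctuating a couple of percentage points across seeds because the
shared schedules correlate cells' decisions.

Cross-assay consistency is quantified by Spearman correlation of
coefficients over co-registered cells and by Pearson correlation of
event-aligned mean activity profiles, with Fisher's r-to-z used to
compare two profile correlations.

# The synthetic generator

`generateSession()` plants everything the analyses are later asked to
recover. Cells are typed eat−, eat+, approach+ or unmodulated (default
mix 0.40/0.15/0.20/0.25, echoing the empirical preponderance of
negatively eating-modulated cells); each type multiplies a 0.5 events/s
baseline Poisson rate during its behavior (eat− ×0.2, eat+ ×3,
approach+ ×3). Events are drawn per trace bin and convolved with a
GCaMP6s-like double-exponential kernel (rise 0.2 s, decay 1.5 s, peak
normalized to 1), plus i.i.d. Gaussian noise (sd 0.05 df/F) — the
simplest noise model that supports every downstream test. Traces run at
7.5 samples/s (30 frames/s video downsampled by four), pose at
30 samples/s.

The epoch schedule alternates approach (6 s, from 22 cm to 1 cm from
the target, i.e. a 21-cm decrease at 3.5 cm/s), eating (8–12 s at the
target) and inter-trial intervals (14–24 s), with rearing bouts placed
in long intervals. The pose track physically realizes this schedule in
a circular 30-cm arena: radial approach paths, holds at the target
during eating, excursions to within 1 cm of the wall during rearing,
plus 0.02-cm tracking jitter. Geometry was chosen so that no
non-approach segment can satisfy the 10-cm/2-cm/s rule (returns to the
start ring decrease the target distance by at most ~8 cm), and the
approach detector recovers ≥ 90% of planted epochs at default
thresholds.

`generateAssayPair()` realizes the conservation structure: multipliers
of behaviors in the `overlap` set are copied between the two sessions,
others are redrawn independently; the co-registration map pairs each
cell with itself, thinned by a dropout fraction. With
`overlap = "eat"`, eat clusters coincide across assays up to noise
while approach clusters differ, reproducing the
eating-more-conserved-than-approach direction.

`generatePhotometry()` plants a shared low-frequency motion artifact
(Gaussian-smoothed noise, 2-s width) in both channels with equal gain,
behavior-locked transients in the signal channel only, and white noise;
the artifact, transients and event times are returned so tests can
verify removal and survival independently.

What the generator does **not** emulate: spatial footprints and
crosstalk between nearby cells, source-extraction artifacts, slow
drifts in event rate, non-Poisson burst statistics, behaviorally
graded (rather than switched) modulation, and realistic body
kinematics. Passing tests therefore demonstrate that the analysis code
recovers planted structure under the stated statistical model — not
that real recordings satisfy that model.

# Statistics and problem sizes

Comparisons use two-tailed Wilcoxon signed-rank/rank-sum tests (exact
for n ≤ 25 without ties, normal approximation with tie correction
otherwise) and one-sample t-tests against stated constants. Families of
p-values declared by the report are adjusted with the
Benjamini–Hochberg step-up, the standard choice when only "the false
discovery rate method" is named; the report records family membership
explicitly.

The shipped calibration suites use 30-minute, 50-cell sessions (the
default study conditions) for decoder chance (50 seeds), silhouette
chance (50 seeds), and conservation recovery (100 seed pairs at 10%
co-registration dropout); classifier calibration uses 500 unmodulated
cells and 200 planted eat− cells in single 30-minute sessions. The
permutation null inside `runPipeline()` caps the embedding at 1500
samples so that 200 shuffles stay tractable; observed-versus-chance
comparisons are unaffected beyond the small negative permutation bias
discussed above.

# Known limitations

* The approach detector's jitter tolerance (0.5 cm/sample) is tuned to
  pose noise at 30 samples/s; very different frame rates warrant
  rescaling it.
* The decoder's contiguous folds are conservative: with few epochs the
  10-s gap can strip most of a fold's training rows.
* `classifyCells()` with shared null schedules produces per-session
  classification rates whose seed-to-seed spread exceeds the binomial
  expectation; treat single-session +/− counts as descriptive.
* The Gaussian GLM treats df/F as homoscedastic; strongly skewed traces
  may prefer a transformed or alternative-link model.
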