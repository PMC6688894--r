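---
title: "Simulating and detecting motion artefacts in cine cardiac MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting motion artefacts in cine cardiac MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cine cardiac MR (CMR) acquires a 2D+time short-axis slice over one cardiac
cycle, filling Cartesian k-space line by line across several heartbeats
within a breath hold. Two failure modes corrupt this process: *mistriggering*
(ECG-trigger errors fill k-space lines with data from the wrong cardiac
phase) and *breathing* (respiratory translation of the heart between line
acquisitions). Both appear in image space as ghosting and temporal blurring
that degrade downstream measures such as ejection fraction. In
screening-scale cohorts the two classes are severely imbalanced: almost all
acquisitions are good, and the few artefact cases are what a quality-control
classifier must find.

`cineqc` implements the full synthetic pipeline for studying this problem
without access to restricted cohort data: a beating phantom with known
ground truth, physics-based k-space corruption at graded severity, an ROI
localizer, compact spatio-temporal classifiers, a severity-ordered
curriculum training scheme, and the evaluation stack.

## The phantom

`generate_phantom()` draws a bright myocardial ring (default intensity 0.9)
around a darker blood pool (0.5) on a dark background (0.1), mimicking bSSFP
contrast. The endocardial radius follows `r_mid - r_amp * cos(phase)` with
`phase` running through `beat_cycles` full periods from the first to the
last frame, so one noise-free cycle closes exactly (first frame equals last
frame). Edges use a 1-pixel linear ramp to limit aliasing. Noise is additive
Gaussian clipped at zero; Rician noise, realistic anatomy (papillary
muscles, multiple slices) and coil/phase effects are deliberately out of
scope. `generate_labelled_set()` jitters centre and radii uniformly within
the valid region so that localisation cannot memorise a fixed centre.

What passing tests on phantoms do *not* show: performance on real
acquisitions, whose texture, anatomy and artefact phenomenology are far
richer. The phantom establishes that the machinery is correct, not that the
classifier generalises to cohort data.

## K-space corruption

Both corruptions operate on the centred 2D DFT of each magnitude frame
(`to_kspace()`), with rows as the phase-encode axis, and reconstruct the
magnitude of the inverse transform (`from_kspace()`). True complex raw data
are unavailable for magnitude-only inputs; operating on the DFT of the
magnitude image is the standard surrogate and its identity limits are exact
(see the test suite): a temporally constant sequence is a fixed point of
mistriggering, zero amplitude is a fixed point of the breathing corruption,
and a constant integer displacement reproduces a circular translation.

**Mistriggering** (`corrupt_mistriggering()`): every z-th phase-encode line
of frame *i* is replaced by the same line of frame `(i + j) mod T`. The
frame offset `j` is drawn per frame (uniform on `1..T-1`) by default, or
fixed. The stride phase `r` is drawn per frame by default
(`phase_mode = "per_frame"`): each frame's k-space is filled during
different cardiac cycles, so trigger jitter plausibly corrupts different
line subsets per frame; a single per-sequence phase is available and is what
the line-replacement oracle tests pin down. A random-subset line selection
(`line_mode = "subset"`) is offered besides the deterministic 1-in-z stride.

**Breathing** (`corrupt_breathing()`): a sinusoidal displacement curve with
`cycles` periods (default 4) is sampled at `n_pe_samples` points (default
256) and resampled onto the frame's phase-encode lines; k-space row `l` is
taken from the frame translated by `d(l)` pixels along the phase-encode
axis via the Fourier shift theorem (sub-pixel, circular). By default every
frame sees the same within-frame sinusoid; a global acquisition clock
(`timing = "global"`) lets the sinusoid span frames. The sinusoid phase is
seeded uniform on `[0, 2*pi)` so samples do not share one breathing phase.

## Severity schedules

`severity_schedule()` grades corruption strength over `b` levels, level 1
most severe. Breathing amplitudes are log-spaced from 8 px down to 0.8 px.
Mistriggering strides default to the even ladder `z = 2, 4, ..., 2b`
(corrupted-line fraction 1/2 down to `1/(2b)`, the same factor-10 range).
The uniform parity is deliberate: k-space rows of a real image pair up by
conjugate symmetry, and the probability that a stride-z pattern replaces
both members of a pair is `2/z` for even z but `1/z` for odd z. Symmetric
replacements keep the corrupted inverse closer to real-valued and change the
magnitude image more, so a ladder mixing parities is *not* monotone in mean
image deviation even in expectation. With one parity, the mean absolute
deviation from the original decreases strictly across levels (asserted over
seeded phantom sets in the acceptance tests, with corruption seeds shared
across levels as a paired design).

## ROI localisation

Each slice sequence covers one heartbeat, so `temporal_activity()` takes the
magnitude of the first temporal Fourier harmonic per pixel (DC excluded;
the bin is configurable for multi-beat data). `hough_candidates()` builds an
edge map by thresholding the gradient magnitude at a percentile (default
0.9 — the edge operator is a free choice here), accumulates circular Hough
votes over a radius range (default 5–40 px at 1.8 mm spacing), normalises
scores by perimeter length so radii compete fairly, keeps the best circle
per radius and returns the top 10 overall. Ties break deterministically
(smaller radius, then first centre in column-major order).
`vote_centre()` sums score-scaled isotropic Gaussian kernels (default
`kernel_sigma` 5 px) over the candidates of one or several slices; the
argmax of that likelihood surface is the ROI centre, from which
`crop_roi()` cuts a `crop_size` (default 80 px) window clamped to the image.
`normalise_intensity()` standardises each cropped sequence to zero mean and
unit population standard deviation.

Coordinates are 1-based (row, col) with time as the last axis — the
idiomatic R convention, used consistently across the package.

## Classifiers

Two compact reference implementations of spatio-temporal video classifiers
are built in vectorised R (im2col gathers + BLAS products), with analytic
backpropagation verified against finite differences in the test suite:

* **3D-CNN**: six 3x3x3 convolutions (stride 1, same padding, ReLU) with
  four 2x max-pooling layers interleaved, then fully-connected layers of
  `fc_hidden` (default 1024) and `n_classes` units and a softmax.
* **LRCN**: a per-frame 2D feature extractor of six 3x3 convolutions and
  three pooling layers, vectorised into a fixed-length descriptor per frame,
  fed through an LSTM; the classification is read from the final LSTM step.

Dropout (default probability 0.5) follows every convolutional block and the
first dense layer / LSTM output. Filter counts default to
(16, 32, 32, 64, 64, 128) with LSTM width 128; the `"tiny"` preset
(2, 2, 4, 4, 8, 8; LSTM 16) is the desk-scale configuration used throughout
the tests. Pooling floors odd extents and passes size-1 axes through, so
short time axes remain valid.

Training (`train()`) is plain SGD with momentum 0.90, learning rate 1e-4
and batches of 50 sequences by default; the desk-scale tests use larger
learning rates (0.02–0.05) and smaller batches, as appropriate for
tiny networks on tiny inputs. Early stopping monitors validation balanced
accuracy: training stops once the count of consecutive epochs without a
relative improvement of at least 0.5% exceeds `patience` (default 100), and
the returned model carries the weights of the best validation epoch. With
`patience = 0` exactly one epoch runs. Undefined components of the
monitoring metric count as zero so the monitor is always comparable; the
reporting functions (below) are stricter.

Weight initialisation defaults to He-scaled Gaussians
(`sd = sqrt(2/fan_in)`); `init = "unit"` switches to unit-variance
Gaussians. We default to the scaled variant because unit-variance draws make
six-layer ReLU stacks saturate at any width — activations grow by roughly
`sqrt(fan_in/2)` per layer, which drives the softmax into its flat region
and stalls learning. The LSTM forget-gate bias starts at 1, the usual
recurrent-stability choice.

Class imbalance can be addressed by `inverse_class_weights()` (weighted
cross entropy) or by synthetic augmentation; `augment_translation()`
(random shifts up to a fifth of the image side, zero-filled) and
`augment_gaussian_blur()` (separable spatial Gaussian, kernel truncated at
4 sigma, zero padding) provide the two classical alternatives.

## Curriculum training

`build_curriculum()` creates `b` stages of freshly corrupted copies of
good-quality samples, one severity level per stage (most severe first).
`curriculum_train()` implements the baby-step scheme: the training pool
starts as the original data set — including every original artefact-labelled
sample, which therefore participates at every stage — and stage `i` adds its
synthetic samples before training for exactly `k = epochs_per_stage` epochs
(default 10; the bundled benchmark uses 2 to keep its 15 paired runs within
CPU minutes). After every epoch the best-validation weights seen so far are
retained and returned at the end; each stage resumes from the best weights
selected so far, with a fresh optimiser state. With `b = 1` the procedure
reduces exactly to one plain `train()` call, which the tests assert
weight-for-weight.

Two baselines complete the comparison: *anti* reverses the stage order
(least severe first) and *control* randomly permutes the pooled synthetic
samples into `b` equal stages. `compare_curricula()` runs all three on a
paired benchmark: an imbalanced original set (180 good : 20 artefact, both
artefact types, severities drawn uniformly over all levels — real artefact
severities are unknown, so a mild-only or severe-only test would bias the
comparison), a held-out test set from the same distribution, shared initial
weights and shared synthetic samples. The benchmark runs at 32x32 crops of
8-frame phantoms with the tiny LRCN; the acceptance checks assert the mean
hold-out AUC ordering (curriculum at least as good as anti and control)
over five seeds, mirroring the qualitative finding that easy-to-hard
ordering helps, not any particular AUC value.

Whether fresh corruptions should be generated per stage or one corrupted
pool split by severity is genuinely open; we generate per-stage fresh
corruptions, which also decorrelates stages.

## Evaluation

`confusion()` counts with artefact as the positive class. `metrics()`
reports accuracy, precision, standard recall `TP/(TP+FN)`, and balanced
accuracy; the default balanced accuracy is the `(precision + recall)/2`
variant used in this literature's quality-assessment tables, with the
textbook `(sensitivity + specificity)/2` behind `variant = "standard"`.
Metrics with empty denominators are `NA`, never silently zero. `roc_auc()`
sweeps thresholds over the unique scores and integrates the ROC curve by
trapezoids, which the tests verify equals the pairwise-comparison
probability (ties counted half) exhaustively at small sizes and against an
independent reference implementation. `stratified_kfold()` produces
(repeated) stratified partitions with per-fold class counts within one of
proportional. `variance_of_laplacian()` is the classical no-reference blur
score: the variance of the 4-neighbour Laplacian response over the frame
interior, averaged over frames. `evaluate_multiclass()` reports one-vs-rest
balanced accuracy per artefact class for the 3-class mode.

## Numerical and design notes

* All randomness flows through explicit seeds; `with_seed()` restores the
  caller's RNG state, so library calls never perturb user code. Bitwise
  reproducibility is promised per platform/BLAS, statistical
  reproducibility across them.
* FFTs use the unnormalised convention (`fft()`), so a constant frame of
  value c has DC energy `c * N^2`; `from_kspace()` divides by `N^2`.
* Pooling handles odd and degenerate extents by flooring and pass-through;
  gradient checks avoid points where a pre-activation sits exactly on the
  ReLU kink, where one-sided derivatives differ by construction.
* Problem sizes in the tests and the acceptance script (e.g. 96–128 px
  phantoms for localisation, 160-sequence classifier runs, the 15-run
  curriculum comparison) are the package's desk-scale verification sizes;
  the same code runs unchanged at native 80x80x50 crops.

## Limitations

The phantom is a geometric stand-in: no trabeculation, no through-plane
motion, no parallel-imaging ghosting, no arrhythmia simulation, no Rician
noise. Corruption acts on the DFT of magnitude images, not raw multi-coil
k-space. The classifiers are compact reference implementations intended for
method study and testing, not GPU-scale training; no pretrained weights are
shipped. Saliency/attention visualisation and significance testing between
ROC curves are out of scope.
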