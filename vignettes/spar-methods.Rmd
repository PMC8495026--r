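---
title: "Symmetric projection attractor reconstruction of the ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetric projection attractor reconstruction of the ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparecg)
```

## The method

An ECG is approximately periodic: each cardiac cycle repeats the
P-QRS-T morphology with beat-to-beat variation. Conventional automated
analysis reduces the waveform to fiducial points (R peaks, QT intervals,
...) and discards the samples in between. Symmetric projection attractor
reconstruction (SPAR) instead uses every sample. For a signal $x(t)$ and an
odd point count $N$, form the delay vector

$$\mathbf{x}(t) = \big(x(t),\, x(t-\tau),\, \dots,\, x(t-(N-1)\tau)\big),
\qquad \tau = T/N,$$

where $T$ is the average cardiac cycle length. As $t$ slides along the
recording, $\mathbf{x}(t)$ traces a bounded object in $N$-dimensional phase
space. Projecting onto the plane spanned by the orthonormal
discrete-Fourier pair at harmonic $k$,

$$c_j = \sqrt{2/N}\cos(2\pi jk/N), \qquad
  s_j = \sqrt{2/N}\sin(2\pi jk/N), \qquad j = 0,\dots,N-1,$$

gives a two-dimensional point cloud $(u, v) = (\mathbf{x}\cdot\mathbf{c},\,
\mathbf{x}\cdot\mathbf{s})$ — the *attractor*. Both basis vectors are
orthogonal to the all-ones direction, so adding a constant to the signal
leaves the attractor exactly unchanged: baseline wander is removed by
construction, not by filtering. For an exactly $T$-periodic signal the
attractor is invariant under rotation by $2\pi/N$, and an $N$-point
attractor of a pure sinusoid at the cycle frequency is a circle of radius
$A\sqrt{N/2}$ on the $k=1$ plane and collapses to the origin for
$k \ge 2$ — closed forms the test suite asserts.

### The admitted plane set

For each $N \in \{3, 5, \dots, 13\}$ the candidate harmonics are
$k = 1, \dots, (N-1)/2$. A plane with $\gcd(k, N) = g > 1$ is excluded:
algebraically its projection equals $1/\sqrt{g}$ times the $(N/g, k/g)$
projection of the period-averaged signal
$y(t) = \sum_{p=0}^{g-1} x(t - p\,(N/g)\,\tau)$, so it duplicates the
structure of a smaller point count. `verify_plane_reduction()` checks this
identity numerically (it holds at machine precision). In the range used
the only exclusion is $(N, k) = (9, 3)$, leaving exactly 20 planes — each
ECG lead therefore yields 20 attractors.

### Cycle length

$T$ is estimated per lead by a Pan-Tompkins style detector: zero-phase
Butterworth band-pass 5–15 Hz, derivative, squaring, 150 ms
moving-window integration, adaptive signal/noise thresholds with a 200 ms
refractory period and a 1.66·RR search-back, each detection refined to the
local maximum of the raw signal within ±80 ms. $T$ is the arithmetic mean
of the RR intervals. If detection fails on a lead (e.g. a flat or
disconnected channel) the record's lead II estimate is used instead; this
per-lead-with-fallback rule is our choice where the upstream procedure is
silent. The delay is realised as the integer shift $d =
\mathrm{round}(\tau f_s)$; at 500–1000 Hz the sub-sample error is far
below morphology scale, and fixing $d$ makes the exactness tests sharp.
The whole 10 s recording is one analysis window and no pre-filtering is
applied.

## Quantifying the attractor

Three polar profiles summarise each cloud:

* **r density** — unit-sum histogram of $r = \sqrt{u^2+v^2}$ over 100
  equal bins on $[0, r_{\mathrm{cap}}]$ (default $r_{\mathrm{cap}} = 3$
  mV; larger radii fall in the last bin);
* **θ density** — unit-sum histogram of $\theta = \mathrm{atan2}(v, u)$
  over 120 bins (3°) on $[0, 2\pi)$, counterclockwise from the positive
  $u$-axis, points at the exact origin assigned $\theta = 0$;
* **outline r** — the maximum $r$ per θ bin, in mV (0 for empty bins).

The densities are invariant to uniform scaling of the cloud (given a fixed
$r_{\mathrm{cap}}$ convention the r density shifts instead); the outline
scales linearly and so retains absolute attractor size, which differs
between the sexes. $r_{\mathrm{cap}}$ is shared across a cohort so that
k-NN feature vectors are comparable — per-record normalisation would
destroy the size signal. Bin counts and $r_{\mathrm{cap}}$ are
configurable; the defaults balance resolution against the ~5,000-point
clouds of a 10 s recording. The profile maxima give three "basic metrics"
per attractor; the full profiles feed the classifier.

## The synthetic generator

Real 12-lead recordings require accession downloads, so the package ships
a seeded generator that every downstream stage is tested on. A beat is a
sum of five Gaussian bumps (P, Q, R, S, T) with amplitudes in mV and
centers/widths as fractions of the cycle; beat onsets follow a renewal
process with RR ~ Normal($60/\mathrm{hr}$, `rr_sd`) truncated at 0.3 s;
one underlying waveform is scaled per lead (aVR negative, mid-precordial
leads largest); a shared baseline sinusoid and independent per-lead white
noise are added. Guard beats outside the window make the noise-free,
fixed-rate output exactly periodic — the symmetry and cycle-length oracles
rely on this.

Two presets emulate the reported sex differences: the F-like class has a
lower R amplitude (1.15 vs 1.60 mV) and a later, broader, lower T wave
(center 0.47 vs 0.42 of the cycle), i.e. a larger QT fraction. A
`separation` scalar interpolates both classes toward their midpoint, which
the monotone-recovery test uses. Defaults (70 bpm, `rr_sd` 0.03 s, 10 s at
500 Hz, 0.05 mV baseline at 0.3 Hz, 0.01 mV noise) are one fixed choice of
realistic resting-ECG conditions. The generator does **not** model a
cardiac dipole (lead morphologies are scaled copies), arrhythmia,
respiratory modulation, or electrode artifacts — so passing classification
tests demonstrate that the pipeline recovers a planted morphological
difference, not that real-cohort accuracies are reproduced.

## The stacked classifier

For each of the 720 feature blocks (12 leads × 20 planes × 3 measure
sets), a k-nearest-neighbour classifier (Euclidean distance, default
$k = 20$, posterior = unweighted neighbour fraction, distance ties broken
toward the lower training index) emits the posterior probability of
female. These posteriors, in a fixed canonical order (lead, then $N$, then
$k$, then measure kind), are the inputs of second-layer stackers: one
60-input network per lead and one 720-input network per subject. Each
stacker is a single-hidden-layer feed-forward network (25 logistic hidden
units, sigmoid output) trained on the cross-entropy loss with L2 weight
decay by full-batch Adam, with epoch-wise early stopping on a held-out
stratified validation portion (patience 50, cap 500 epochs). We train this
network in-package: a quasi-Newton fit with a full Hessian approximation
scales quadratically in the ~18,000 weights of the subject-level stacker,
whereas first-order training with early stopping is linear per epoch and
matches the intended procedure directly; an agreement test against an
independent single-hidden-layer implementation guards the architecture.
All fits are deterministic given their seed.

Heart rate is deliberately **not** a feature: the delay spacing already
normalises the attractor for rate, and appending rate has been observed to
slightly reduce accuracy.

### Cross-validation and leakage

Folds are stratified by sex × 10-year age band (missing age is its own
stratum): within each stratum records are shuffled (seeded) and dealt
round-robin, remainders going to the globally least-loaded folds, so fold
sizes differ by at most one overall *and* within every stratum — 8,903
records give folds of 890/891. Nested cross-validation holds out one test
fold and one inner validation fold per run: base k-NNs train on the
remaining folds, their out-of-fold posteriors on the validation fold train
the stackers, and scores are emitted only for the untouched test fold. A
provenance log records every record's role in every run;
`audit_leakage()` proves no test record entered any training step of its
run.

Scores in $[0,1]$ (female-positive, threshold 0.5) map to confidence
categories — strong male (< 0.1), mid male, indeterminate (0.35–0.65),
mid female, strong female (> 0.9) — with boundary values assigned to the
less extreme category, since the printed intervals overlap at their
endpoints. Evaluation reports accuracy, trapezoidal ROC AUC (via the rank
identity, cross-checked against an independent ROC implementation),
sensitivity/specificity with respect to female, by-age and by-category
breakdowns, and a per-lead accuracy table; degenerate single-class inputs
report `NA` rather than a number.

## Numerical choices and degenerate inputs

* Delay as integer sample shift; no interpolation.
* Orientation convention: $v$ is the +sine component, θ counterclockwise;
  published attractor images may be reflections of ours.
* θ of origin points is 0; radii ≥ $r_{\mathrm{cap}}$ count in the last
  bin; out-of-extent raster points clip to boundary bins.
* k-NN requires $k \le$ training-set size — at $k =$ train size the
  posterior degenerates to the prevalence, so desk-scale examples use a
  smaller $k$ than the study-scale default of 20.
* Constant signals: QRS detection raises an "insufficient beats" error;
  projections map to the origin; empty clouds are errors, not empty
  profiles.
* Deduplication keeps the earliest record per subject by
  (acquisition key, record id) — idempotent by construction.

## Problem sizes used in the shipped checks

Chosen as the smallest sizes at which each property is sharply testable:
the rotational-symmetry sweep uses one 30 s noise-free record per $N$ at
$f_s = 100N$ Hz (integer delay, boundary mismatch ~1–2% of mass against
the 5% band); the classifier recovery check uses a 200-record, 12-lead
cohort at full preset separation with 10-fold nested CV and $k = 20$,
plus a label-shuffled control; the oracle-equivalence check compares 100
random signals against a brute-force trigonometric projection at
$10^{-12}$ relative.

## Known limitations

* The generator's lead structure is a scaled single waveform; per-lead
  classifiers therefore differ mainly in signal-to-noise ratio, not in
  morphology, unlike real precordial gradients.
* Reported real-cohort figures (cross-validated and unseen-test
  accuracies, per-lead tables, median-profile distances) require accession
  ECG databases and are out of scope for the shipped tests.
* WFDB support covers the format-16 single-.dat layout used by the target
  databases, not the full format zoo.
* Only odd $N$; no sub-windowing of longer recordings in this version.
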