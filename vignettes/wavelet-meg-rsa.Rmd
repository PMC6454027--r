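---
title: "Linking Haar wavelet descriptors to MEG decoding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking Haar wavelet descriptors to MEG decoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavemeg)
```

## The question the pipeline answers

When a person views an image, the multichannel MEG signal carries a
time-resolved trace of how the visual system discriminates that image from
others. This package asks how much of that discriminability is explained by
a classical image representation — the multilevel 2D Haar wavelet transform
— and *when* each component of that representation is expressed in the
neural signal. Two empirical signatures are of particular interest:

* whether coarser (higher-level) approximation coefficients, which carry
  denser, more semantic content, peak **later** in the neural time-course
  than fine ones; and
* the **oblique effect**: cardinal (horizontal/vertical) edge structure
  being represented more strongly than diagonal structure, read out here as
  the number of statistically significant timepoints per orientation.

The pipeline is exercised end-to-end on synthetic stimuli and synthetic MEG
epochs with known injected ground truth, so every stage can be validated
against what was put in.

## Wavelet descriptors

Each grayscale stimulus (BT.601 luminance conversion for RGB inputs) is
decomposed with the separable 2D Haar filter bank: a low-pass pair
`(1, 1)/√2` and a high-pass pair `(1, −1)/√2` applied along rows and
columns, each followed by dyadic downsampling. One level yields four
sub-bands: the approximation **A** (low/low) and the oriented details
**H**, **V**, **D**. The *horizontal* detail is the band that responds
maximally to horizontal stripes (high-pass across rows); the alternative
gradient-direction labelling would swap H and V, and only relabels outputs.
Level *j + 1* re-decomposes the level-*j* approximation. Per level we keep
A, H, V, D and the concatenation `ALL = [H, V, D]`, so 5 levels give 25
descriptor vectors per stimulus (`W1`…`W25`, level-major, flattened
row-major).

Two numerical choices matter:

* **Normalization.** We use the orthonormal filter-bank scaling rather
  than an explicit `1/√(MN)` prefactor. All downstream dissimilarities are
  Pearson correlations, which are invariant to global rescaling (a property
  the test suite asserts), and orthonormality buys exact energy
  conservation and perfect reconstruction on even-sided inputs — both used
  as oracle checks.
* **Odd sides.** Odd-length axes are extended by repeating the boundary
  sample (symmetric half-sample padding), giving output side
  `floor((n + 1)/2)`. This reproduces the canonical
  175 → 88 → 44 → 22 → 11 → 6 size chain for 175-px stimuli, so level-5
  sub-images are 6 × 6.

## Synthetic data: what it emulates, and what it does not

`generate_stimuli()` composes three pure-orientation patterns — alternating
rows, alternating columns, and a checkerboard — whose contrasts are set by
per-condition orientation weights, plus a smooth low-amplitude random
texture that differentiates stimuli sharing a profile. Each pattern loads
on exactly one level-1 Haar detail band, so the band-energy ordering of a
generated image provably follows its weights. These are *not* photographs
of objects: they exercise the descriptor/decoding machinery with
controllable orientation content, but carry none of the categorical or
semantic structure of real object stimuli.

`generate_epochs()` builds condition-mean sensor patterns by classical MDS
of a target RDM (double-centering, eigen-decomposition, positive-eigenvalue
axes), embedded into channel space by a seeded random orthogonal rotation,
so the pairwise Euclidean distances of the noiseless patterns equal the
target dissimilarities. The pattern is modulated by a Gaussian temporal
envelope with a given peak latency and FWHM, **hard-zeroed before stimulus
onset** — a stimulus-evoked response cannot precede its stimulus, and this
keeps the pre-stimulus interval exactly signal-free rather than merely
small. Independent Gaussian noise is added per trial, channel and sample.
Several RDMs can be injected jointly (orthogonal channel subspaces with
per-geometry weights), which is how the oblique-effect suite makes cardinal
geometries stronger than the diagonal one.

What this generator does *not* model: realistic MEG forward fields and
channel covariance, inter-subject variability in pattern geometry, head
movement, or physiological artifacts beyond an optional rank-1 frontal
blink injector used to test the preprocessing stage. Passing tests on this
synthetic family therefore validate the *machinery* (descriptors, decoding,
RSA, statistics), not claims about real cortical dynamics.

A note on geometry recovery: the correlation-distance (1 − Pearson) RDM of
embedded patterns rank-matches the injected RDM exactly when the embedded
configuration has equal norms (a "spherical" geometry), because the cosine
distance is then a monotone function of Euclidean distance. For strongly
non-spherical geometries the two metrics genuinely diverge; the recovery
property is therefore asserted on spherical fixtures, while distance
recovery (which is exact for any embeddable RDM) is asserted separately.

## Preprocessing

The epoch-level cleaning chain mirrors standard MEG practice: per-trial
baseline-mean removal over the full pre-stimulus interval; peak-to-peak
trial rejection flagging trials whose worst channel range strictly exceeds
6,000 fT (flags only — data are never modified, and the flags are invariant
to baseline correction, which the suite checks); zero-phase low-pass
smoothing (4th-order Butterworth, default 30 Hz cutoff, applied
forward–backward so latencies — a headline quantity — are not biased); and
simplified eyeblink removal that detects excursions of the mean frontal
signal beyond a z-threshold (default 4) and projects the first principal
component of the pooled blink segments out of contaminated trials only.

## Decoding and RSA

At each timepoint, every unordered condition pair is decoded with a linear
soft-margin SVM (C = 1, no feature scaling) on pseudo-trials: raw trials
are randomly partitioned into K = 4 groups of 10 and averaged (groups
shrink to `floor(n/K)`, minimum 1, when fewer trials are available). The
classifier is trained on K − 1 pseudo-trials per condition and tested on
the held-out pair, across all K folds; the whole
permute–average–cross-validate cycle repeats 100 times (all defaults
config-exposed). One partition stream per repetition is shared by both
conditions of a pair: the trial-index permutation carries no condition
information, and identical inputs then yield identical pseudo-trials, so
indistinguishable conditions score exactly 0.5. Each (subject, pair) work
unit derives its own seed, making results independent of execution order.
Accuracies fill symmetric condition × condition RDMs with an undefined
diagonal, one per timepoint.

Descriptor RDMs are 1 − Pearson between descriptor vectors. RSA compares a
model RDM with each subject's neural RDM at each timepoint by Spearman
correlation over the vectorized strict upper triangle (the symmetric
matrices carry all information there), with average ranks for ties and
pairwise exclusion of missing cells; per-subject time-courses are averaged
on the correlation scale (Fisher-z averaging is deliberately not the
default, matching how such time-courses are conventionally reported).

## Statistics

Significance uses the two-sided sign-permutation test: under the null each
subject's time-course is symmetric around zero, so subject signs are
randomly flipped (1,000 draws by default); the two-sided p-value counts
draws (observed included, so p ≥ 1/(n_perm + 1)) whose absolute
subject-mean reaches the observed one. Cluster correction thresholds the
p-map at 0.05, forms maximal contiguous runs, and compares each run's
**size** (count of contiguous supra-threshold timepoints — the literal
reading of a cluster of connected timepoints; a mass statistic would also
be defensible) against the permutation null of the maximum cluster size at
corrected alpha 0.05.

Latencies are estimated by bootstrapping subjects (1,000 draws with
replacement): each draw's subject-average yields a peak (argmax within a
0–600 ms window, chosen to exclude baseline and late edge effects) or an
onset (start of the earliest significant post-stimulus cluster, recomputed
per draw; draws without one are reported as missing). SEM and the 95% CI
are the bootstrap distribution's standard deviation and 2.5/97.5
linear-interpolation percentiles. Peak-latency samples can be trimmed of
their top and bottom 5% and restricted to ≤ 150 ms (inclusive boundary),
the conventional upper bound for feedforward object recognition, before
histogramming. Orientation anisotropy is read out by counting significant
timepoints per descriptor and summing H, V and D counts across levels.

## Problem sizes and test design

The validation suite runs the full chain at reduced scale — typically 6–12
conditions, 3–8 subjects, 8–12 trials, 16–32 channels, 10–20 ms sampling
over a few hundred ms — which preserves the structure of the full design
(92 conditions, 16 subjects, 40 trials, 306 channels, 1 ms sampling over
−150…1,000 ms; all sizes remain configurable). Statistical calibration
checks (p-value uniformity, family-wise error of the cluster test,
agreement with the exhaustive 2^n sign-flip oracle) use a few hundred
simulated runs with 250–500 permutations. Headline-effect recovery injects
rank-stretched descriptor RDMs (a monotone transform that widens contrasts
without changing rank geometry — Spearman RSA is invariant to it) so that
peak latencies and significance counts are resolvable at these fixture
sizes.

## Known limitations

* The SVM repetition scheme re-randomizes the pseudo-trial partition and
  averages over all K held-out folds; reading "repeat" as a single
  held-out fold per repetition is available via the fold structure but not
  a separate mode.
* Eyeblink removal is a deliberate simplification (z-threshold detection +
  single-component projection), not a reimplementation of any particular
  vendor pipeline.
* Onset bootstrap draws re-run the permutation cluster test per draw; at
  the default 1,000 × 1,000 scale this is the most expensive statistic and
  is typically run with a reduced per-draw permutation count
  (`onset_n_perm`).
* The generator's condition patterns are identical across subjects; only
  noise differs. Between-subject geometry variability would lower RSA
  values on real data relative to these fixtures.
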