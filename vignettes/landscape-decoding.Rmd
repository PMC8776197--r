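---
title: "Decoding landscape perception from band-resolved EEG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding landscape perception from band-resolved EEG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Different visual environments — forest, wetland, grassland, desert, water,
farmland, city — evoke distinguishable patterns of cortical activity.
`eegscape` implements a complete within-subject decoding study of that
claim: multichannel scalp EEG is recorded while a subject watches seven
categories of landscape video (each ~40 s, repeated twice, in random order
with one-minute rests), the continuous signal is reduced to band-resolved
spectral features on 2-s epochs, and four standard classifiers try to
recover the landscape category from single epochs. Because the study's raw
recordings are not publicly deposited, the package also contains a
first-class synthetic-data generator that reproduces the study design, so
every stage of the pipeline is testable end to end without any download.

## The measurement model

A recording is a 32-channel 10–20 montage sampled at 500 Hz. Preprocessing
follows the standard sequence, fixed in this order:

1. re-reference to the average of the two mastoids (TP9/TP10), dropping the
   reference channels;
2. per-channel least-squares linear detrend;
3. anti-aliased polyphase decimation to 250 Hz (65-tap Hamming-windowed FIR,
   cutoff at 90% of the target Nyquist, group delay compensated);
4. zero-phase band-pass 0.5–70 Hz (4th-order Butterworth per pass,
   forward–backward);
5. ocular artifact removal (see below);
6. segmentation into contiguous, non-overlapping 2-s windows cut from each
   stimulus block onset forward, rejecting any window whose peak magnitude
   exceeds 100 µV on a feature channel.

A clean 40-s block yields 20 epochs; a full clean session yields
7 × 2 × 20 = 280 epochs per subject, hence 5600 for twenty subjects.

## Features

Five frequency bands are used: delta 1–4, theta 4–8, alpha 8–13, beta
13–30, gamma 30–70 Hz. Band bins are half-open (lo ≤ f < hi) so shared
edges are never double-counted; gamma's upper edge, the analysis band
limit, is inclusive. Per epoch and channel:

* **MAS** — natural log of the mean one-sided amplitude spectrum over the
  band's bins (single Hann-tapered periodogram on the 500-sample epoch,
  taper gain corrected so a unit sine reads 1.0);
* **PSD** — natural log of the mean periodogram density over the band;
* **DE** — differential entropy under the Gaussian closed form,
  ½ ln(2πeσ²), with σ² the variance of the band-pass-filtered epoch
  (4th-order zero-phase Butterworth, odd-reflection padding of 250 samples
  on each side — the epochs are short, so the padding choice matters and is
  recorded in the output metadata).

Spatial contrasts are derived from the 29-channel DE vector:
**DASM** (left − right) and **RASM** (left / right) over 13
mirror-symmetric electrode pairs, and **DCAU** (frontal − posterior) over
11 fronto-caudal pairs. The "total" band is the concatenation of the five
per-band vectors, giving 145 / 65 / 55 dimensions — this reproduces the
published dimensionality table exactly, which is why concatenation (rather
than a 1–70 Hz broadband computation) was adopted.

The 32-channel inventory and the exact 29/13/11 channel assignment are not
published; the packaged default (a standard actiCAP-style layout with
TP9/TP10 as references and Oz additionally excluded) satisfies every
printed count and is replaceable through the config. The left–right pairs
are the twelve natural mirror pairs plus (FT9, FT10); the fronto-caudal
pairs match each frontal line to its parietal/occipital counterpart plus
(Fz, Pz).

DE of a µV-scale signal can legitimately cross zero, so RASM ratios whose
denominator magnitude falls below 10⁻⁶ are flagged as `NA` sentinels;
design construction drops and counts sentinel rows.

## Classification protocol

Per subject and per (family, band) cell, four classifiers are compared:

* **BP** — single-hidden-layer back-propagation network (64 tanh units,
  softmax output, cross-entropy loss), trained by full-batch gradient
  descent with momentum 0.9, learning rate 0.1, at most 500 iterations,
  early-stopped on a 10% stratified inner validation split checked every
  10 iterations with patience 3. The architecture is not published; the
  layer size and iteration cap are package defaults. The trainer is
  implemented as compiled code because quasi-Newton fitters are
  quadratic in the weight count and do not scale to the 145-dimensional
  total-band designs.
* **KNN** — k = 5;
* **RF** — random forest with 500 trees (ranger backend, one thread);
* **SVM** — linear kernel, C = 1, one-vs-one multiclass (libsvm).

The source study states both an 80/20 split and 10-fold cross-validation
without relating them. The canonical protocol here is stratified 10-fold
cross-validation over all of a subject's epochs, reported as the mean over
folds; a stratified 80/20 holdout remains available as
`protocol = "holdout"`. Features are standardized per column with
statistics fitted on the training folds only — distance- and margin-based
classifiers need a common scale for a fair comparison. Fold assignment is
seeded per subject from the global seed, so subjects are independent but
every run is reproducible. Aggregates are mean ± SD of the per-subject
accuracies with the n−1 denominator; the SD axis (subjects, not folds) is
recorded in the grid metadata.

## The synthetic generator

Each channel is the sum of

* **1/f^α background** (α = 1, RMS 10 µV) synthesized by spectral shaping
  of white Gaussian noise; the spectrum is flattened below 0.5 Hz so that
  session-length drifts do not dominate the variance budget;
* **band-limited oscillations**: one white-noise process per channel is
  filtered into the five disjoint bands (4th-order Butterworth), giving
  mutually uncorrelated band components; baseline RMS per band is
  delta 4, theta 3, alpha 4, beta 2.5, gamma 3 µV — a plausible
  descending-spectrum profile;
* **artifacts**: 400-ms raised-cosine blink transients (80 µV at the
  frontopolar sites, frontally weighted loading, Poisson 12/min) and a
  50 Hz mains sinusoid (2 µV, ±20% per-channel coupling).

Class structure enters only through multiplicative band-power gains inside
stimulus blocks: within a class-k block the oscillation envelope is
baseline × √gain, so expected band power equals gain × baseline. By
default the seven classes are log-spaced in gamma (1× to 4×) and beta
(1× to 2.5×) with all other bands flat, plus a small left–right gamma
differential (±10% across classes). This mirrors the study's central
finding — high-frequency bands carry the discriminative signal — and is
deliberately strong: the source study reports ~98% gamma-band decoding,
so the emulated effect is sized for clean decodability rather than
subtlety. `effect_size = 0` collapses all classes to an exact null.
Inter-subject variability is modelled as ±10% multiplicative jitter on the
baseline amplitudes (per channel and band) and one per-subject scalar on
the log-gains; neither differs between classes, so the null stays null.

Mastoid channels carry background noise only, which keeps the class signal
out of the reference. Recordings are generated at 500 Hz so the 250 Hz
downsampling stage is exercised non-trivially, with 5 s of lead-in and
lead-out so filter edge effects land outside the blocks.

### What the generator does not emulate

Volume conduction and realistic inter-channel correlation, dipolar source
geometry, non-stationary rhythms (the per-block envelope is flat), subject
fatigue or habituation, and genuine perceptual variability. Passing tests
therefore demonstrate that the pipeline arithmetic, the feature
definitions and the protocol behave as specified — not that real EEG would
reach any particular accuracy.

### A caveat the synthetic data makes visible

With only two blocks per class, epoch-level cross-validation mixes epochs
from the same block across training and test folds. Any slowly varying
state shared within a block — blink density, drifting background — then
acts as a block fingerprint that classifiers can exploit: with artifacts
enabled, nominally uninformative bands decode a few points above chance.
This is a known hazard of block designs evaluated at the epoch level and
plausibly inflates accuracies in comparable real studies. The null
calibration is therefore run on artifact-free data, where all classifiers
sit inside the 99% binomial band of 1/7.

## Artifact removal

The ICA path whitens the re-referenced channels and runs a symmetric
FastICA (tanh contrast, at most 100 iterations, tolerance 10⁻⁴, seeded
initialisation). Components are flagged as ocular when at least 25% of
their absolute mixing weight concentrates on the frontopolar channels and
the kurtosis of their sub-4 Hz content exceeds 5 (blink trains are
sparse); flagged components are removed before reconstruction. These
thresholds are package defaults, not study values — the study does not
state its component-selection criteria. The contract is behavioural:
injected blinks lose at least 70% of their excess frontopolar delta power,
while blink-free recordings keep their band powers within 10%. A simpler
regression mode (low-passed frontopolar mean regressed out of every
channel) and a `none` mode are also provided.

## Numerical choices

* Zero-phase IIR filtering uses steady-state initial conditions; when the
  state system is near-singular (very narrow normalized bands) the state
  falls back to zero and the reflection padding absorbs the transient.
* The EDF writer scales each channel to its own ±ceiling(max |x|) µV range
  over a 16-bit grid; round-trip error is below half a quantization step.
* Degenerate inputs: zero-variance DE is −Inf (flagged), all-sentinel
  design slices raise errors naming the slice, a class with fewer examples
  than folds raises an error naming the class, and blocks shorter than the
  epoch window contribute zero epochs with a warning.
* Ties in per-subject maxima are all reported, ordered by (band, family,
  classifier).

## Problem sizes used by the tests

Unit tests run on compressed sessions (the same 14-block structure with
10-s blocks) and small epoch arrays. The acceptance suite runs the full
20-subject clean session for the epoch bookkeeping (5600 epochs), a
1000-epoch Gaussian conformance check for DE, and classifier grids at
5 subjects — frequency-domain families across the five bands for the band
trend, and all six families in the gamma band (with the asymmetry
component zeroed) for the frequency-vs-spatial comparison. These sizes
were chosen so the whole suite completes on a single CPU while the
quantities under test (counts, dimensionalities, chance levels, trend
directions) are already at their design values.

## Known limitations

* The 29-channel subset and the 13/11 pairings satisfy the published
  counts but are not verifiable against the source montage.
* Decoding accuracies on synthetic data are not comparable in magnitude to
  the published human-EEG accuracies; only their ordering across bands,
  families and classifiers is meaningful.
* The BP network's architecture, the ICA selection thresholds and the
  rejection threshold (100 µV) are declared defaults standing in for
  unpublished study parameters.
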