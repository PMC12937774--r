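---
title: "Screening GVS waveforms with resting-state EEG biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening GVS waveforms with resting-state EEG biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Galvanic vestibular stimulation (GVS) delivers weak currents over the mastoids.
In Parkinson's disease (PD), candidate therapeutic waveforms vastly outnumber
what patients can be asked to test behaviourally. `gvscreen` implements an
EEG-based screening pipeline built on one premise: *a good stimulus transiently
shifts a PD patient's resting-state EEG biomarkers toward the distribution seen
in healthy controls (HC)*. Each of 304 stimuli (one of which is a no-stimulation
sham) is presented once per subject inside a 9 s trial: 2 s pre-stimulation
baseline, 2 s stimulation, 5 s recovery. Every stage of the pipeline — feature
extraction, composite scoring, multi-criteria ranking, category inference — is
reusable on real recordings; a seeded synthetic cohort generator stands in for
human data so that the whole chain is testable at desk scale.

## Biomarkers

Sixteen biomarkers are computed per 2 s window, averaged over 13 central
electrodes (FC5, FC1, FCz, FC2, FC6, C3, Cz, C4, CP5, CP1, CPz, CP2, CP6), in a
fixed order: beta–gamma phase–amplitude coupling (Tort modulation index);
peak–trough asymmetry and rise–decay ratio of the beta waveform; aperiodic
exponent and offset; beta burst duration, amplitude and energy; beta and
relative beta power; Petrosian fractal dimension; Hjorth mobility and
complexity; spectral, approximate and sample entropy. The 5 s post-stimulation
interval is split into four overlapping 2 s windows (1 s overlap) whose
biomarkers are averaged, so every interval is estimated from windows of
identical length (no window-length bias).

Band edges and estimator parameters are nowhere pinned down by convention
alone, so they are explicit, documented defaults in `biomarker_options()`:

* **beta 13–30 Hz, gamma 50–100 Hz, broadband 1–45 Hz, aperiodic fit 2–40 Hz** —
  the most common choices in the PD EEG literature.
* **PAC**: Tort modulation index with 18 phase bins — bounded in [0, 1] with
  exact analytic anchors (uniform binned amplitude → 0; single-bin mass → 1),
  which makes it testable at its extremes.
* **Bursts**: Hilbert envelope of the beta-filtered signal; threshold = 75th
  percentile of the envelope pooled over that subject's pre-stimulation
  windows, per channel; minimum duration 100 ms (the Tinkhauser-style
  convention).
* **Aperiodic fit**: two iterations of peak-pruned least squares on the
  log–log Welch spectrum (points > 1 SD above the line are treated as
  oscillatory peaks and removed). This deterministic, dependency-light
  procedure recovers a noiseless power law exactly and is documented as an
  approximation to full spectral parameterization with Gaussian peak models.
* **Entropies**: ApEn/SampEn with m = 2, r = 0.2 · SD, Chebyshev distance,
  computed after anti-aliased 4× decimation (1000 → 250 Hz). At 1000 Hz,
  adjacent samples are nearly perfectly correlated, so m = 2 template matching
  mostly measures oversampling, and the O(N²) count at N = 2000 costs ~25 ms
  per window — unaffordable at ~10⁵ windows per cohort. All properties relied
  on downstream (noise > sinusoid ordering, scale invariance, defined
  degenerate values) hold at the decimated rate.
* **Filters**: linear-phase windowed-sinc FIRs applied zero-phase with
  reflection padding; length = 3 cycles of the band's low edge, capped at one
  third of the window (the uncapped rule would demand 3000 taps for the 1 Hz
  broadband edge — longer than the window). Zero-phase filtering commutes with
  time reversal, which is what makes "reversal negates the rise–decay ratio"
  an exact (1e-6) test rather than an approximate one.

Degenerate inputs never produce NaN: constant windows, burst-free envelopes and
windows with fewer than three beta cycles map to documented constants, because
the downstream model requires complete feature vectors.

## Composite score and distances

An L1-regularized logistic model (HC vs PD) is trained on pre-stimulation
feature vectors with leave-one-subject-out outer folds. Within each fold,
features are z-scored on the 9 training subjects and λ is chosen by the 1SE
rule from an inner 5-fold cross-validation on binomial deviance whose folds
are whole subjects, class-balanced round-robin (deterministic — no RNG).
Balanced class weights keep the intercept-only null model at the decision
boundary; without them the 5/4 training splits make a null model
systematically misclassify the held-out subject. Per-fold coefficients are
mapped back to a common (pooled) standardization and averaged; the composite
score is the averaged linear predictor, interpretable as log-odds of PD.

The healthy reference is the mean score over all 5 × 304 HC pre-stimulation
trials. The per-trial distance is |score − reference|: the printed distance
definition carries no absolute-value bars, but the quantity is then inverted
(1/Dist) to build the decision matrix, so a signed version would be
meaningless — the absolute value is the only reading under which the
construction goes through.

## SES ranking and group inference

Distances for the 5 PD subjects form a 304 × 5 matrix, inverted entry-wise
(ε = 1e-9 guards exact zeros) and normalized per subject column. The
normalization method is not specified by the source analysis; the canonical
TOPSIS vector normalization (unit Euclidean column norm) is the default, with
min–max and sum-to-one exposed as alternatives. Each stimulus row is scored by
relative closeness SES = d⁻/(d⁺ + d⁻) to the ideal (column-max) and anti-ideal
(column-min) points, with equal subject weights; rank 1 = highest SES, ties
averaged.

Category-level inference groups the 304 stimuli into 37 morphology categories,
drops the two singletons (DC and sham), and computes: per-subject median ranks
per category; tie-corrected Kendall's W with the χ²(k−1) approximation
(m = 5 raters is small, but the approximation is verified null-uniform at
k = 35 by simulation); and a one-tailed ("less": lower rank is better)
Wilcoxon rank-sum test of each category's global SES-derived ranks against the
pooled complement, BH-corrected across the 35 categories at q ≤ 0.1. Testing
SES values or SES-derived ranks is equivalent here because the rank-sum test
only sees the ordering of the pooled sample. BH rejection uses the closed
boundary (q ≤ threshold), which reproduces the classic step-up set exactly.
Per-channel paired-t maps (relative beta power and peak–trough asymmetry on
the trials of selected categories, 36 channels) are BH-corrected within each
map; the correction scope is configurable because pooling across maps is an
equally defensible reading.

## The synthetic cohort: what it emulates and what it does not

`simulate_segment()` builds each channel as 1/f^χ background (exact
frequency-domain amplitude shaping of seeded white noise, so
exponent-recovery tests have an analytic target) + a burst-gated 20 Hz beta
source with a nonsinusoidal shape (a phase-locked second harmonic sharpens
peaks; a phase skew makes rises faster than decays) + a 65 Hz gamma source
whose envelope is modulated by beta phase + white sensor noise. Oscillatory
sources are shared across channels with distance-decayed gains (central strip
strongest); background and sensor noise are independent per channel. Gamma
amplitude is fixed (not proportional to beta) so that the planted beta-power
contrast does not leak into the entropy contrast. Per-channel noise streams
are seeded by montage position, so generating a channel subset reproduces
exactly the samples of a full-montage run — this is what lets the pipeline
stream features channel-by-channel within memory limits.

PD differs from HC in `group_parameter_table()`: higher beta amplitude, longer
bursts, deeper PAC, stronger waveform asymmetry, lower sensor noise (hence
lower entropy). No quantitative HC-vs-PD effect sizes are available for any
biomarker, so the between-group separation was calibrated once against a
single published operating point — leave-one-subject-out pre-stimulation
classification accuracy in the 80–90% band on the default 5+5 cohort — and
then frozen. "Effective" stimulus categories (11, 20, 33, 36 by default) pull
PD generator parameters linearly toward the HC group mean by δ = 0.6 during
the stimulation interval only; sham and HC trials always use δ = 0. Effects
are strictly transient by construction (pre and post segments are generated
from baseline parameters with interval-specific seeds).

The generator does **not** emulate: volume conduction or realistic topography,
eye/heart/muscle artifacts, the GVS stimulation artifact (the pipeline
consumes cleaned EEG; artifact removal is a separate preprocessing concern),
electrode impedances, non-stationarity across the session, or between-trial
parameter drift. A green end-to-end test therefore establishes that the
analysis chain recovers effects of the planted kind at the planted size — not
that it would detect effects in any particular real cohort.

## Numerical and design choices worth knowing

* All randomness derives from one master seed through a deterministic
  splitter; segment seeds are per (subject, trial, interval), so restricting
  generation to some intervals or channels never changes the others. The
  global RNG state is saved and restored around every generator call.
* EDF export quantizes to 16-bit integers over a per-channel physical range
  written into the 8-character header fields; round-trips are exact to one
  quantization step of that range.
* Segments of a trial are generated independently (no phase continuity at
  interval boundaries). The segmentation never places an analysis window
  across a boundary, so no biomarker sees the seam.
* The sham trial is exchangeable with every δ = 0 stimulus by construction,
  so its SES rank is approximately uniform over the non-effective stimuli; a
  single-seed "sham ranks mid-scale" check would be a coin flip, and the
  acceptance suite instead requires the mean sham rank across replicate
  seeds to sit in the middle half of the scale.
* Kendall's W p-values use the χ²(k−1) approximation, which reproduces
  published W/p pairs exactly but has a mildly conservative null at m = 5;
  null calibration is therefore asserted as a small KS distance and valid
  test size, not as strict uniformity.
* Scaled-down acceptance replicates (2 HC + 2 PD, 3 central channels through
  the public `central_channels` argument) keep the suite inside its compute
  budget; the 13-electrode contract and the full 5+5 cohort are exercised
  once, in the structural and accuracy-band criteria.

## Known limitations

The stimulus table of the original 303-waveform library is not public; the
default library reconstructs the printed structural constraints (304 stimuli,
one sham, families, 0.5–200 Hz, 37 categories with exactly two singletons and
the four named effective categories) but not the exact parameter grids. The
aperiodic fit is a robust-line approximation, adequate for exponents but not a
peak model. Kendall's W p-values rely on the χ² approximation; an exact
permutation path is straightforward but slow and was not needed at k = 35.
Real-data behavior of the MCDA step may depend on the (unstated) column
normalization; this is exposed as configuration rather than decided silently.
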