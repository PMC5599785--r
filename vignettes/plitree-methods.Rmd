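---
title: "plitree: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plitree: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were made, and what a passing test
suite does and does not establish.

## The analysis model

The pipeline treats each subject's resting-state EEG as a sample of an
underlying functional network, estimated per frequency band:

1. **Preprocessing.** Optional re-referencing to the mean of named
   channels, optional broadband (0.5–70 Hz) filtering, band-pass filtering
   into delta (0.5–4 Hz), theta (4–8 Hz), alpha (8–13 Hz) and beta
   (13–25 Hz), segmentation into non-overlapping 8-s epochs, and retention
   of the first 10 epochs whose per-channel peak-to-peak amplitude stays
   below 100 µV.
2. **Connectivity.** Per epoch, instantaneous phases from the analytic
   signal; per channel pair, the phase lag index
   `PLI = |mean(sign(sin(Δφ)))|`.
3. **Topology.** Per PLI matrix, the maximum-weight spanning tree and seven
   global tree metrics; per subject, metrics averaged over epochs.
4. **Inference.** Pooled two-sample t-tests per (band, metric) and Pearson
   correlations between alpha-band metrics and smoking covariates.

Assumptions worth stating explicitly: the signal of interest is oscillatory
and band-limited; a *consistent nonzero* phase lag indicates interaction
while zero-lag covariation is treated as reference/volume-conduction
artefact and deliberately discounted (`sign(0) = 0` contributes nothing);
and the strongest N−1 connections form a meaningful backbone, so that tree
topology can be compared across subjects without any connectivity
threshold.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `fs` | 512 | Hz | the acquisition rate the defaults are derived for |
| `epoch_seconds` | 8 | s | 4096 samples/epoch at 512 Hz; long enough for stable PLI at band frequencies |
| `n_epochs_keep` | 10 | epochs | standard artifact-free budget from a 2-min recording |
| `ptp_threshold_uv` | 100 | µV | surrogate for visual artifact screening (see below) |
| bands | δ, θ, α, β | Hz | the four classical bands; edges are −3 dB corners |
| `filter_order` | 4 | — | Butterworth prototype order: ~24 dB/octave per pass |
| `reference_labels` | `NULL` | — | see "Re-referencing" below |
| `aggregation_mode` | `per_epoch_trees` | — | see "Aggregation" below |
| coupling `strength` | 0.9 (presets) | [0,1] | phase jitter sd is (1−strength)·π/4 rad |
| `amplitude` / `noise_sd` | 40 / 5 | µV | ~80 µV peak-to-peak oscillation, realistic sensor noise, below the artifact threshold |

## Numerical choices

**Filter realisation.** Band-pass Butterworth of prototype order 4,
designed via the analog prototype → lowpass-to-bandpass transform →
bilinear transform, and kept as second-order sections: a single polynomial
transfer function of order 8 is numerically fragile for the delta band at
512 Hz (poles clustered near z = 1), sections are not. The design matches
scipy.signal reference magnitudes to 1e-7 (frozen in the test suite).
Filtering is forward-backward (zero phase) because any residual filter
phase would bias the instantaneous-phase estimates that PLI consumes; edges
are handled by odd-symmetric extension whose length scales with the slowest
passband period (3 periods of the low edge). Band edges are interpreted as
half-power corners.

**Processing order.** Re-reference → (optional broadband) → band filter →
epoch → artifact screen. Band filtering precedes epoching so filter
transients do not sit inside epochs; no per-epoch settling trim is needed.
Whether a broadband pre-filter preceded the band filters in the original
processing chain is not determinable; both orders are supported
(`broadband = c(0.5, 70)` or `NULL`), default off for synthetic data, and
for band-limited analysis the band filter dominates either way.

**Artifact surrogate.** Visual inspection cannot be reproduced in code. An
epoch is "clean" iff every channel's peak-to-peak amplitude is ≤ 100 µV;
the first 10 clean epochs in temporal order are kept. If fewer exist, all
clean epochs are used and a warning is logged — silently proceeding would
hide data loss, aborting would discard a usable subject.

**Hilbert phases.** Analytic signal via the FFT one-sided-spectrum method;
phases wrapped to (−π, π]. The phase difference enters `sin()` unwrapped
(sine is 2π-periodic). On 4096-sample epochs the finite-length end effects
are negligible at band frequencies, so no samples are trimmed by default; a
`trim` argument exists because on *continuous* (non-epoched) data the first
and last few dozen samples of the analytic signal are unreliable and can
flip a handful of signs.

**Tree construction and ties.** "Minimum spanning tree" on similarity
weights means the maximum-weight tree (identical to the minimum tree of
distance 1 − PLI, which the tests verify against igraph). Kruskal's
algorithm runs on edges sorted by descending weight with ties broken by
ascending (i, j) index pair, so the tree is unique and deterministic even
when weights repeat — which happens systematically when coupling saturates
PLI at 1.0.

**Degenerate statistics.** Strongly coupled small networks can give a
metric the identical value in every subject (every star subject has leaf
fraction exactly 1). The comparison and correlation tables then emit the
row with NA statistics instead of aborting, preserving partial output; the
scalar `two_sample_t` keeps the strict contract (error on zero pooled
variance with equal means, ±Inf with distinct means).

## Open design decisions and how they were settled

**Metric normalisations.** The tree literature is not uniform here. Max
degree, leaf count, diameter and mean eccentricity are divided by
M = N − 1; betweenness is normalised by (n−1)(n−2) over ordered pairs.
These conventions reproduce the magnitude ranges reported for 64-channel
resting-state MSTs (leaf fraction ≈ 0.7, diameter ≈ 0.17, T_H ≈ 0.46–0.49)
and give clean closed forms (star-64: leaf 1, T_H 0.5, κ 32; path-64:
diameter 1, κ 250/126) that the acceptance tests pin down exactly.

**Tree hierarchy.** T_H is computed as N_leaf/(2·M·BC_max). BC_max is also
the aggregate reported as the "BC" metric (any other aggregate would be
inconsistent with T_H's own denominator).

**Eccentricity aggregate.** Eccentricity is per-node; one number per
subject is reported. The mean over nodes is used (max and min are attached
as attributes).

**Mean PLI.** Reported as the mean over all unordered channel pairs, not
only over tree edges.

**Aggregation.** Per-epoch trees with metric averaging is the default
(matching per-epoch processing upstream); building a single tree from the
epoch-averaged PLI matrix is available as `aggregation_mode =
"averaged_matrix_tree"`. The two differ in general — averaging matrices
smooths weight ties before tree construction — and the package makes the
choice explicit rather than silent.

**Re-referencing default.** The classical montage re-references to the
bilateral mastoids (TP9/TP10) and the pipeline supports exactly that via
`reference_labels = c("TP9", "TP10")`. The *default* is `NULL` (skip):
referencing to absent labels is a hard error by contract, and synthetic
recordings carry no mastoid channels, so a TP9/TP10 default would make the
pipeline fail on the package's own simulations.

**Statistics.** Pooled-variance t (the SPSS equal-variance row, df 38 for
20 + 20) rather than Welch, two-sided, no multiple-comparison correction —
matching standard practice in this literature; Welch and Holm-corrected
values are emitted in clearly separate columns as extensions, never
silently substituted.

**EDF input.** Out of scope in this build: no EDF reader is available in
the supported dependency set, and a binary-format parser is not something
to hand-roll. Plain-text matrices plus a TSV manifest are the input
contract.

## The synthetic generator: what it emulates and what it does not

Each channel is `A·sin(θᵢ(t))`. Free channels integrate an instantaneous
frequency drawn inside the carrier band (uniform base frequency in the
central 70 % of the band plus slight white frequency jitter, sd 2 % of the
bandwidth), with a random initial phase. A coupled follower copies its
driver's phase plus a constant lag plus white Gaussian phase jitter of sd
(1 − strength)·π/4. An optional square mixing matrix superimposes channels
with zero lag (volume conduction / common reference); independent Gaussian
sensor noise is added last. Presets: `star` (hub drives all, common lag
π/4) and `chain` (sequential, lag π/4 per hop).

This stated world gives analytically known phase-lag structure — which is
the point — but it is *not* realistic EEG: no 1/f background, no blinks or
EMG, no biophysical head model, sinusoidal rather than broadband
oscillators. Two consequences of the model worth knowing:

* With per-hop lag π/4, chain pairs at hop distance ≡ 0 (mod 4) have
  accumulated lags near 0 or π, exactly the lags PLI is blind to; other
  distant pairs remain strongly coupled. At strength 0.9 the jitter is too
  small to decorrelate them, so many chain PLI values saturate at ~1 and
  the recovered chain trees are *partially* star-like under deterministic
  tie-breaking (leaf fraction ≈ 0.9 at 20 channels, not the path floor
  2/19). The star ground truth is recovered exactly. The recovery test
  therefore establishes a robust *ordering* (star leaf fraction > chain
  leaf fraction in ≥95 % of paired runs), not exact chain reconstruction —
  an estimator property, not a claim about real EEG.
* Smoking covariates for synthetic smokers are drawn from the reported
  cohort distributions (FTND 4.6 ± 1.5, cigarettes/day 14.05 ± 3.9,
  pack-years 3.0 ± 1.8, onset age 15.3 ± 1.8) but are *independent* of the
  simulated brain signal: the null preset's correlation table should show
  no systematic effects, and the tests expect none.

Hence a green suite establishes: the estimator honours the PLI boundary
identities exactly; the tree builder is provably optimal (enumeration
oracle at n ≤ 7, igraph cross-check beyond); the metrics obey their bounds
and closed forms; the t/correlation layer is calibrated (type-I error
0.05 ± 0.02 under the null); and ground-truth topology ordering is
recovered through the full pipeline. It does not establish anything about
recordings the generator cannot imitate.

## Known limitations

* PLI is blind to true zero-lag and π-lag interactions by construction;
  discounting volume conduction costs sensitivity to genuinely
  instantaneous coupling.
* The artifact surrogate (peak-to-peak threshold) is cruder than visual
  inspection or ICA-based correction, both out of scope.
* Group inference assumes one value per subject per metric; nested
  epoch-level variance is averaged away rather than modelled.
* Disconnected graphs are not handled by the tree builder — irrelevant for
  PLI matrices on complete graphs, which are always connected.
* No notch filtering, resampling, or bad-channel interpolation; the
  sampling rate in the manifest is taken as ground truth.
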