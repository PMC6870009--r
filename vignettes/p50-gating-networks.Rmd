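---
title: "Methods: source-space functional networks from P50 sensory gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-space functional networks from P50 sensory gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatenet)
```

## Overview

`gatenet` implements the full analysis chain of a paired-click P50
sensory-gating study comparing three clinical stages — first-episode
schizophrenia (FESZ), ultra-high-risk individuals (UHR) and healthy
controls (HC):

1. **ERP stage** — preprocessing of epoched EEG, trial averaging, P50
   scoring and gating measures;
2. **Inverse stage** — an eLORETA-style weighted minimum-norm projection
   of the 30–90 ms condition segments onto 80 cortical regions;
3. **Connectivity stage** — normalized mutual information (NMI) between
   all C(80,2) = 3160 region pairs, per subject and condition;
4. **Graph stage** — characteristic path length, clustering coefficient
   and global efficiency of each network;
5. **Group statistics** — edge-wise permutation tests between group
   pairs, node-degree summaries, Kruskal–Wallis and Bonferroni post hoc
   tests of the scalar measures;
6. **Staging classifier** — a post-pruned decision tree over 24 features
   (4 ERP, 9 network, 3 demographic, 8 cognitive), evaluated by 101
   random 20 %-per-group splits and stratified fivefold cross-validation.

Because no public dataset exists for this paradigm, the package ships a
first-class synthetic cohort generator with a known forward model and a
planted connectivity ground truth, so that every downstream stage is
testable end to end.

## The synthetic cohort generator

### Paradigm and cohort constants

The generator reproduces the paradigm of the emulated study: paired
clicks with S1 at 0 ms and S2 at +500 ms, 80 click-pair trials, epochs
from −200 to +1000 ms at 1000 Hz, and group sizes 25 FESZ / 23 UHR / 19
HC (67 subjects, the cognition subsample used for classification).
Per-group P50 source amplitudes (S1: 1.24 ± 0.58, 1.13 ± 0.73,
1.30 ± 0.90 µV; S2: 0.99 ± 0.61, 0.67 ± 0.43, 0.74 ± 0.56 µV) and all
covariate distributions (age, education, gender rates, eight MCCB
scores) follow the published group means and SDs. Covariates are drawn
from group-specific normals truncated at zero; gender is Bernoulli with
the subsample female rates.

### Forward model

The default head model is a quasi-spherical single-shell analytic model:
sensors form a Fibonacci lattice on the upper cap of a unit sphere, one
dipole source sits at each of 80 quasi-uniform shell positions (40 per
hemisphere, AAL-style labels), and the gain is the homogeneous-conductor
dipole potential with random fixed orientations. Multi-layer skull
modelling is deliberately omitted: extra shells mainly rescale gain
columns with depth and nothing downstream depends on that. A pure
Gaussian random gain (`lead_field_type = "gaussian"`) is available for
unit tests. The lead field is *calibrated* so that 1 µV of source
amplitude in the bilateral auditory (superior temporal) regions produces
1 µV on the average-referenced mean of the three vertex-nearest
channels; this ties the amplitude parameters above to the sensor-level
P50 measures, so the ERP stage can recover Table-level group means.

### Signal model

Each trial contains, per source, 1/f background noise (spectral exponent
1, SD `noise_sd` = 1 µV) — chosen over white noise because the analysis
is broadband 1–40 Hz and autocorrelated noise is the harder case for a
histogram MI estimator — plus spatially white sensor noise
(`sensor_noise_sd` = 0.5 µV). P50 components are Gaussian-windowed
bursts (SD 12 ms) peaking 50 ms after each click, injected into the two
auditory regions with the subject's S1/S2 amplitudes.

**Planted connectivity** is trial-locked by design. A planted edge draws,
once per subject and click window, a smooth random latent waveform,
tapers it to the 30–90 ms post-click window, and injects it into *both*
regions on every trial with amplitude `coupling × planted_amp_uv`
(default 0.5 µV RMS, the scale of the published gating-difference
amplitudes). Trial-locked injection is the only mechanism that can
produce connectivity in this pipeline at all: the networks are built
from *trial-averaged* segments, and averaging 80 trials annihilates any
non-phase-locked activity (a first implementation with per-trial latent
mixing produced a provably vanishing group effect for exactly this
reason). The default planted truth follows the published top-24
gating-stage connection pairs, which also reproduces the published hub
structure (paracentral lobule and middle temporal gyrus as high-degree
nodes); couplings are 0.9 in both patient groups and 0 in controls, so
patient-vs-control comparisons carry signal while FESZ-vs-UHR carries
none.

One side effect of this design is physiologically sensible and worth
knowing: the planted evoked activity leaks through the forward model
into the vertex measurement channels, so patient-group P50 amplitudes
measure somewhat above their configured means (≈0.1–0.5 µV, depending
on the cohort's random dipole geometry) while control amplitudes do
not. Group means remain within two empirical standard errors of the
configured values, which is how the recovery tests bound it.

What the generator does *not* emulate: ocular/muscle artifacts with
realistic topographies (artifact rejection is exercised with amplitude
outliers only), volume-conduction asymmetries of a layered skull,
between-subject head-geometry variability, and any coupling between
covariates and electrophysiology beyond shared group membership. Passing
tests therefore demonstrate correctness of the analysis chain under a
known truth, not clinical validity on real recordings.

## ERP stage

Preprocessing per trial: offset removal, artifact rejection at a
configurable absolute-amplitude threshold (default 100 µV) on the raw
trace, average re-referencing, zero-phase band-pass filtering (1–40 Hz),
and baseline correction over −200–0 ms. Independent-component EOG
removal is out of scope for synthetic data without modelled ocular
sources; the rejection threshold is the pluggable artifact hook.

The band-pass is the two-pass magnitude response of an order-4
Butterworth design, applied with exactly zero phase in the frequency
domain on reflection-padded signals. This matches
`signal::filtfilt(signal::butter(4, band))` in magnitude (verified in
the test suite) while vectorizing over all trials and channels; an
order-4 design is used so that mains-frequency interference is
attenuated by at least 20 dB (an order-2 design reaches only ~16 dB).

The P50 is the maximum positive sample of the channel-subset mean
(default: the three vertex-nearest channels, standing in for the
vertex-adjacent sites of the emulated montage) within 30–90 ms after the
click, endpoints inclusive, ties to the earliest latency. Amplitude is
the baseline-corrected peak value. Gating measures are the difference
S1−S2 and ratio S2/S1; subjects with S1 amplitude below 0.5 µV are
flagged invalid and skipped by group statistics (the published exclusion
rule prints "0.5 mV", which would exclude nobody at ~1 µV amplitudes and
is read as 0.5 µV; the threshold is configurable). The exclusion is
applied to the reported S1 amplitude, i.e. after channel averaging.
Condition segments are the 30–90 ms windows after each click (61 samples
at 1000 Hz) and the pointwise gating segment S1−S2.

## Inverse stage

The inverse operator is the eLORETA-style weighted minimum norm: with
average-reference-centered gain `K`, diagonal weights `W` and centering
operator `H`, iterate `w_i ← sqrt(k_i' (K W⁻¹ K' + αH)⁺ k_i)` to
convergence (tolerance 1e-6 on the relative weight change, at most 100
iterations) and form the kernel `W⁻¹ K' (K W⁻¹ K' + αH)⁺`. The
pseudoinverse truncates eigenvalues below 1e-10 of the largest. `α` is
specified as a fraction (default 0.05) of the mean eigenvalue of the
centered sensor Gram matrix. This construction has zero localization
error for noiseless point sources as α → 0 — the property the test suite
asserts for all 80 sources. Dipoles are fixed-orientation (one time
course per region, as the network pipeline requires); the 6329-voxel
grid of the original desktop software is not reproduced — the source
space is the ROI-resolution grid of the generator or any user-supplied
lead field. Each region is represented by its centroid source ("central
voxel" rule); with one source per region this is the identity.

With 32 sensors and 80 sources the inverse is strongly underdetermined:
the resolution matrix carries only ~16 % self-weight per region, so
reconstructed series share substantial leakage and the NMI floor between
reconstructed regions sits near 0.45 rather than the source-level
estimator floor of ~0.2. Group comparisons are differences at fixed
leakage, so this raises baselines without invalidating contrasts; users
wanting higher spatial fidelity can raise `n_sensors` (up to 128).

## Connectivity stage

NMI uses equal-width histogram plug-in entropies over each signal's own
observed range: `MI = H(S) + H(Q) − H(S,Q)`, normalized by the geometric
mean `sqrt(H(S)H(Q))` — the reading under which identical signals score
exactly 1 (an arithmetic-mean denominator is selectable). Bin count
defaults to the square-root rule capped at 32 bins: `ceiling(sqrt(n))`
for short segments (8 bins for the 61-sample windows) while keeping the
plug-in bias `(B−1)²/2N` small for long signals. At n = 61 the
independent-pair NMI floor is ≈ 0.2 (quantified against a long-sample
oracle in the tests); all group comparisons are therefore relative, never
absolute. Entropies are computed in bits; NMI itself is base-invariant.
Constant signals have zero marginal entropy and NMI defined as 0 with a
warning. Matrices are built per subject and condition (80 × 80,
symmetric, zero diagonal, entries in [0,1]) because the permutation test
shuffles subjects.

## Graph stage

Characteristic path length and global efficiency are computed on the
full weighted graph with edge length 1/weight (inverse-weight mapping,
the convention for similarity-weighted brain graphs; −log(w) is not
offered). L is the mean shortest-path length over ordered pairs with
disconnected pairs excluded under a warning; efficiency is the mean
reciprocal shortest-path length with disconnected pairs contributing 0
(the printed formula that averages the lengths themselves is treated as
a typo for the standard reciprocal-distance efficiency). The clustering
coefficient requires a binary adjacency, so the network is binarized by
proportional threshold (top `density·C(n,2)` edges, default density 0.2,
ties by stable edge order) before computing
`C_i = E_i / (k_i (k_i − 1))` with triangle counts over ordered neighbor
pairs and `C_i = 0` for degree < 2. Whether the emulated study also
binarized before L and E is unreported; computing them fully weighted is
recorded as a possible divergence. The nine features per subject are the
three metrics for the S1, S2 and S1−S2 networks.

## Group statistics

The edge-wise statistic is the difference of group means of each edge
weight — chosen over a t statistic because the permutation null makes no
variance assumption and the mean difference is exchangeable-valid. The
null shuffles group labels over pooled subjects (default 5000 shuffles
in standalone use; 2000 in the packaged pipeline; exact enumeration when
at most 20000 assignments exist) and two-sided p-values use the add-one
rule, so p ∈ (0,1] and the test is valid by construction. Edges with
p < 0.05 are reported per group pair with their sign; no cross-edge
correction is applied, matching the per-edge reporting convention of the
emulated study (a correction flag exists but is off by default). Degree
tables count incident significant edges per node, sorted by degree with
ties in atlas order. Scalar measures use `stats::kruskal.test`
(tie-corrected H, chi-squared reference, df = k−1; fully tied input is
reported as H = 0, p = 1) with Wilcoxon rank-sum post hocs multiplied by
the number of pairs and capped at 1.

## Staging classifier

The 24 features (canonical order and class partition 4 ERP / 9 NET /
3 DEM / 8 MCCB) feed an `rpart` classification tree grown with cp = 0,
`minsplit` = 8 and `minbucket` = 3 (the defaults of 20/7 are too coarse
for 53 training samples), then post-pruned by cost-complexity with the
penalty chosen at the minimum internal fivefold cross-validation error
(ties resolved toward the larger penalty, i.e. the smaller tree). Each
of the 101 repetitions draws a fresh 20 %-per-group split (5/5/4 test
subjects; 14 test, 53 train) and re-runs the pruning CV independently.
The headline accuracy is the median (51st order statistic); the
confusion matrix of the first repetition attaining it is kept, along
with per-class correct/total counts. Stratified fivefold CV partitions
67 subjects into folds of 13/13/13/14/14 with per-group counts balanced
within one subject, remainders assigned to the currently smallest folds.
Feature-class importance sums rpart's impurity-decrease importance
within each class across repetitions and normalizes to 100 %. Gender is
a binary indicator; no feature scaling is applied (trees are
scale-invariant).

## Numerical choices and degenerate inputs

* Window endpoints are inclusive; the sample at exactly 30 ms belongs to
  the segment; latencies are reported relative to their own click.
* Peak ties resolve to the earliest latency; proportional-threshold ties
  resolve by stable edge index; accuracy-median ties take the first
  repetition attaining the median.
* An S1 amplitude of zero leaves the gating ratio undefined (`NA`).
* All-rejected trial sets, single-class training sets, fully
  disconnected graphs and rank-deficient lead fields raise errors naming
  the offending subject/region where applicable.
* Determinism: cohorts are bit-identical given the configuration seed
  (each subject owns a derived RNG stream, so subjects can be generated
  independently or streamed); permutation tests and classifiers are
  deterministic given their seeds.

## Problem sizes used in the packaged checks

The test suite and the acceptance script exercise the full default
cohort (67 subjects, 80 trials, 32 sensors, 80 regions) once end to end
with 2000 permutations per edge test and 101 split repetitions; unit and
property tests use reduced cohorts (3–12 subjects, 6–24 trials, 10–16
sensors), 200–500 permutations, and 15–50 seed replicates per
Monte-Carlo property. These sizes were chosen so the whole suite runs on
one CPU in well under half an hour while keeping every Monte-Carlo
margin several standard errors wide.

## Known limitations

* The NMI floor of ~0.45 between reconstructed regions (leakage) and
  ~0.2 between raw 61-sample segments (estimator bias) means absolute
  NMI values are not interpretable; only contrasts are.
* The forward model is single-shell and spherical; gains are not meant
  to be anatomically faithful, only well-conditioned and calibrated.
* Published headline statistics (group test statistics, classification
  accuracies) derive from an unavailable clinical dataset; the package
  reproduces the *design-level* counts exactly and validates each stage
  against planted synthetic truth instead.
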