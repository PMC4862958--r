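---
title: "Multi-layer amplitude-envelope connectivity: models and methods"
author: "meglayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer amplitude-envelope connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meglayer)
```

## The problem

MEG records neural oscillations over a wide frequency range, and
inter-regional communication is carried both *within* frequency bands
(e.g. correlated beta-band amplitude envelopes across the motor network)
and *between* bands (e.g. the alpha envelope of one region co-varying
with the gamma envelope of another). Treating each band in isolation
discards the between-band structure. `meglayer` implements a
multi-layer network analysis in which each band is one layer: envelope
correlation is estimated for every region pair within each band and for
every ordered band pair, and the results are assembled into a single
block matrix, the super-adjacency matrix (SM).

The pipeline, end to end:

1. **Source reconstruction** (optional; users may enter at the regional
   level). A scalar LCMV beamformer with broadband (1–150 Hz)
   covariance, 5% Tikhonov regularization, closed-form orientation
   optimization, unit-gain spatial filters, Gaussian distance-weighted
   regional aggregation and sign alignment.
2. **Band-limited envelopes.** Zero-phase FIR band-pass filtering into
   alpha (8–13 Hz), beta (13–30 Hz), low gamma (30–50 Hz) and high
   gamma (50–100 Hz), followed by the magnitude of the analytic signal
   (the Hilbert envelope).
3. **Connectivity.** Per analysis window and per trial: pairwise
   leakage orthogonalization, optional magnetomyogram (120–150 Hz
   envelope) regression, Pearson correlation of the windowed envelopes,
   and the arithmetic mean of the per-trial correlations.
4. **Statistics.** Sign-flip permutation tests with BH-FDR for
   task-induced change; effect-of-diagnosis and effect-of-severity
   matrices with a dual-permutation tile-correlation test and
   conjunction edge selection for case–control studies.
5. **Synthetic data.** A generator with planted envelope couplings,
   task modulation, leakage mixing and muscle artifact, used by every
   recovery and calibration test in the package.

## Beamforming

The data covariance is computed on band-passed (1–150 Hz by default),
window-concatenated, demeaned sensor data — using as much data as
possible minimizes covariance estimation error. Regularization is
`C + 0.05 * lambda_max(C) * I` (`tikhonovRegularize()`).

For each source, the free-orientation gains `L` (sensors × 3) are
collapsed to a fixed orientation `eta` maximizing the output SNR ratio

    (eta' L' Cinv   L eta)
    ----------------------  ,
    (eta' L' Cinv^2 L eta)

solved as a generalized symmetric eigenproblem. This is the closed form
of the usual "non-linear search" over orientations: `scalarOrientationGrid()`
retains the brute-force search as an oracle, and the two agree to within
an SNR ratio of 1e-6 on random instances (tested). Two degenerate cases
are handled explicitly: a magnetically silent direction (the radial
orientation in a spherical conductor) makes the denominator matrix
singular, so the pencil is solved on its non-null subspace; and when the
covariance is proportional to the identity every orientation ties, in
which case the dominant right singular vector of `L` is returned and
flagged.

The LCMV weights are `w = Cinv l / (l' Cinv l)`, satisfying the
unit-gain property `w'l = 1` exactly; this is asserted in tests at
1e-10. Voxel timecourses are aggregated into a regional timecourse with
Gaussian weights `exp(-r^2/400)` (distance `r` in mm from the regional
centre of mass), implemented in `regionWeight()`. The half-maximum
*radius* of this kernel is `sqrt(400 log 2) ≈ 16.65 mm` (the
half-maximum diameter is twice that); weights are not renormalized,
since downstream Pearson correlation is scale invariant, and a
`normalize` flag exists for users who want sum-to-one weights. Region
membership of voxels is left to the caller (atlas geometry is an input,
not a concern of this package).

Beamformer outputs have arbitrary polarity. `signAlign()` flips each
region so its correlation with the first principal component of the
regional set is non-negative. The reference sign itself is fixed by a
majority vote across regions (ties broken by the strongest correlate),
so the output is deterministic and invariant to single-region input
polarity.

## Filtering and envelopes

Band-pass filters are windowed-sinc FIRs applied forward and backward
(zero phase), protecting envelope timing. The filter length is
`2.5 * fs / delta` taps with transition width
`delta = max(0.25 * f_lo, 0.05 * bandwidth)`; for the narrowband
analysis bands this meets > 40 dB attenuation at 25% beyond either band
edge with < 1 dB passband ripple (verified numerically in the tests),
while the bandwidth term keeps the broadband covariance filter short
relative to a trial. The filter length is recorded in the container
metadata; the first and last filter-length samples are flagged as edge
transients and excluded from window statistics by default.

The time–frequency spectrogram (`tfs()`) uses 33 overlapping bands with
log-spaced edges spanning 1–150 Hz: with 35 log-spaced edge points `e`,
band `k` spans `(e[k], e[k+2])`, giving 50% overlap between
neighbours. The exact band layout is a package choice (only the count,
range and overlap are fixed by convention) and is configurable.

Task-induced amplitude change is quantified as the fractional change of
the trial-averaged envelope between a stimulus (0–2 s) and a rebound
(2–4 s) window, tested per region with a two-sided Wilcoxon signed-rank
test across subjects and Bonferroni correction over the number of
regions actually analysed (not a hard-coded 78). Zero differences are
dropped (the zero-exclusion convention) and counted in the output.

## Connectivity estimation

Signal leakage between reconstructed sources appears as zero-lag linear
correlation. `pairwiseOrthogonalize()` removes it by regressing the
seed out of the test signal *per window and per trial* — windowed
orthogonalization matters because task-induced variance changes
modulate leakage magnitude. Within-band tiles are computed in both
directions and averaged, making the stated tile symmetry exact by
construction despite the regression being directional. Cross-band
orthogonalization (seed band regressed from test band at the
band-limited signal level) is on by default but configurable off; with
near-disjoint bands it mainly guards overlapping transition bands.

A known limitation, demonstrated in the tests: pairwise regression
removes zero-lag correlation *exactly*, but when mixing is strong or
involves third parties, some envelope-level co-modulation survives
(the residual still contains other regions' envelope fluctuations,
and magnitudes are insensitive to the regression's sign bookkeeping).
The method is accurate in the small-leakage regime it was designed
for.

Muscle (magnetomyogram) artifact is broadband at high frequencies and
typically bilateral, inflating high-gamma envelope correlation. The
120–150 Hz band — above neural frequencies of interest — is used as a
reference: its Hilbert envelope is regressed out of both the seed and
test envelopes, independently per trial (`mmgRegress()`). Whether the
reference should be regressed from envelopes or from band-limited
signals is ambiguous in common practice; this package regresses from
envelopes (computed immediately after enveloping), which is also the
pathway the regression can actually correct. Envelope regression
cannot remove contamination carried by cross-spectral carrier
coherence; the artifact end-to-end test isolates the envelope pathway
accordingly.

Connectivity per region pair is the Pearson correlation of windowed
envelopes computed within each trial and averaged raw over trials (no
Fisher transform, matching the mean-correlation convention). Envelopes
are not downsampled by default. `trialAveragedCorrelation()` implements
the contrasting estimator — average envelopes over trials first, then
correlate — which retains only task-locked structure; the difference
between the two estimators is itself informative and is exercised in
the tests.

Tiles are assembled into the SM with within-band tiles on the block
diagonal (symmetric, diagonal set to 0 as self-connectivity is not
interpreted) and directed between-band tiles off the diagonal; block
`(b, a)` stores the transpose of block `(a, b)`. Four bands give
exactly 10 distinct tiles (`B + B(B-1)/2`). Cross-band tile diagonals
(same region, two bands) are retained as valid measurements.

## Statistics

**Task contrast.** Each subject's active-window SM minus control-window
SM is a dSM. Under the null, window labels are exchangeable, which for
a paired difference is a per-subject sign flip; 20,000 sham averages
build an element-wise null, two-tailed p-values use the exact-test
convention `(1 + #exceedances)/(nPerm + 1)` (floor `1/(nPerm+1)`), and
BH-FDR controls the discovery rate across elements. The null is built
per element (an option pools it); the Monte-Carlo test agrees with
exhaustive sign-flip enumeration at 12 subjects to within ±0.01.

**Case–control.** The effect of diagnosis is the control-minus-patient
mean SM; the effect of severity is the element-wise Pearson correlation
between patient connectivity and a severity score (the first principal
component of three z-scored clinical measures, sign-anchored to the
first measure). Tile correlation relates the two matrices within each
tile, over each tile's unique elements: the strict upper triangle for
symmetric tiles, all non-same-region elements for directed tiles. The
dual permutation null independently exchanges group labels (preserving
group sizes) and shuffles severity scores in each of 10,000 iterations;
two-tailed significance is Bonferroni corrected to
`0.05/(2 * nTiles)` — 0.0025 for 10 tiles — with `p < 0.025` flagged as
a trend. `nTiles` is computed from the band list. Within a flagged
tile, `edgeSelection()` tests each element independently for diagnosis
and severity effects and returns elements with both permutation
p-values below 0.01.

## The synthetic-data generator

The generator emulates the study conditions: 78 regions, 45 trials of
9 s at 600 Hz (2 s stimulus + 7 s baseline; the analysis windows are
active 0–4 s, control 4.5–8.5 s, whole-trial 0–8.5 s, all half-open so
abutting windows are disjoint), the four canonical bands, and
task-locked modulation (beta gain 0.6 during the stimulus with a 1.4
rebound, alpha 0.6, low gamma 1.2, high gamma 1.5 during the
stimulus). These defaults *are* the reference conditions; tests and the
acceptance script pass smaller region counts, trial counts and
durations explicitly to keep runtimes reasonable, and those reduced
sizes are stated where used.

Per band and region, the signal is an independent band-pass-filtered
Gaussian noise carrier (synthesized in the Fourier domain)
amplitude-modulated by a log-normal envelope `exp(sigma * z)`, with
`sigma = 1` and `z` a unit-variance Gaussian process band-limited to
1 Hz. The `z` processes of all (band, region) nodes share a Gaussian
copula whose correlation matrix implements the requested within- and
cross-band couplings; a non-positive-semi-definite request fails with
advice to enable nearest-correlation projection. Regional signals are
the sum over bands plus white noise (sd 0.05), optionally mixed by an
instantaneous leakage matrix.

Because the measured Hilbert envelope is the product of the planted
log-normal envelope and the carrier's own (Rayleigh-distributed)
envelope, the measured envelope correlation is an attenuated, monotone
function of the copula correlation, with a ceiling (≈ 0.75 at
`sigma = 1`). `calibrateCoupling()` maps between the two scales by
Monte-Carlo simulation of the full estimator at the caller's geometry;
with `couplingSpace = "envelope"` the generator applies the inverse map
so targets are interpretable on the measured scale (cross-band targets
use the mean of the two per-band maps). The calibration uses a private
RNG stream so it does not perturb seeded simulations, and is cached per
parameter set. Statistical tests that only need ordered coupling
strengths use `couplingSpace = "latent"` to skip calibration.

The muscle artifact is a shared Hann-windowed burst train (rate 0.5/s,
0.4 s bursts) with broadband 60–150 Hz carriers: broadband because
myogenic activity contaminates the high-gamma range while its
120–150 Hz portion is what the reference regression sees. Carriers
share 90% of their variance across regions by default (bilateral bursts
share common drive); fully independent carriers cap the raw cross-region
envelope correlation near 0.78, which is why the default is shared.

The cohort generator plants a connectivity deficit: patients' coupling
on selected edges of one tile is reduced by
`deficitSize + severitySlope * severity`, with standardized severity
scores, against a common base coupling; controls are unaltered.

**What the generator does not emulate**: 1/f sensor noise spectra,
biophysically realistic neural dynamics, non-stationary coupling
epochs, head movement, or realistic artifact topographies. Passing
recovery tests therefore demonstrates correctness of the estimators
under the stated generative model, not performance on real recordings.

## Numerical choices and degenerate inputs

- Sample `k` (0-based) lies at `t0 + k/fs`; windows are half-open
  `[tStart, tEnd)`.
- Zero-variance seeds leave the test series unmodified (flagged); a
  constant magnetomyogram reference demeans only (flagged);
  zero-variance trials are dropped from the trial average with a
  reported count; zero-variance regions are left unflipped by sign
  alignment with a warning.
- Permutation p-values can never be 0 (`+1` in numerator and
  denominator); masks never select non-finite statistics.
- The container stores raw little-endian float64, so write/read round
  trips are bit-identical; non-finite payloads and missing required
  attributes are rejected on load with the offending field named.
- All randomized operations take explicit seeds and record them in
  their results; fixing the seed fixes every output bit for bit.

## Problem sizes used in the tests

Unit and property tests run at 2–6 regions, 8–45 trials, 2–8.5 s
trials, 250–600 Hz, chosen as the smallest sizes at which each
statistical property is decisively testable. The calibration suites
use 20 seeds × 23 subjects (window-test uniformity, 2,000
permutations), 1,000 replicates of m = 6,000 (FDR control), and 200
null cohorts (tile-test type-I error). The recovery suites use the
study's 45 trials × 8.5 s at 600 Hz for coupling recovery, and
23 + 23 subjects at 6 regions × 2 bands for deficit localization.
`scripts/acceptance.R` recomputes the same quantities from scratch in
about a minute.
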