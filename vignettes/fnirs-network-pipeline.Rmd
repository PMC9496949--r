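---
title: "Resting-state fNIRS networks and complexity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state fNIRS networks and complexity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsnet)
```

## What the package computes

`fnirsnet` implements a complete resting-state functional near-infrared
spectroscopy (fNIRS) analysis for a 27-channel prefrontal probe sampled at
25 Hz with two wavelengths (690/830 nm):

1. **Preprocessing** — edge trimming, optical-density (OD) conversion,
   discrete-wavelet motion-artifact correction, PCA removal of global
   physiological noise, zero-phase 0.01–0.08 Hz band-pass, and the modified
   Beer–Lambert law (MBLL) giving HbO/HbR concentration changes in µM.
2. **Connectivity** — Pearson correlations between all channel pairs of the
   HbO series, Fisher r-to-z transformed, then binarized over a sparsity
   grid (0.13–0.40, step 0.01) at exactly matched edge counts.
3. **Graph metrics** — clustering coefficient Cp, characteristic path
   length Lp, global/local efficiency, nodal efficiency, and
   small-worldness σ against degree-preserving random networks; every curve
   is collapsed to its integral over the sparsity grid (AUC).
4. **Complexity** — multiscale sample entropy (coarse-graining scales 1–25,
   pattern length m = 2, tolerance r = 0.2 SD) with AUC over scales.
5. **Behavior** — spatial N-back scoring: RT cleaning, hit/false-alarm
   tabulation, and the non-parametric sensitivity index A′.
6. **Group statistics** — the network-based statistic (NBS) permutation
   test on edges, covariate-adjusted two-sample t-tests with
   Benjamini–Hochberg FDR across metrics, partial correlations, and an
   exact noncentral-t sample-size calculation.

Because no recordings ship with the package, a synthetic two-group
generator (`simulate_cohort()`) produces raw two-wavelength intensities,
N-back trial tables and covariates with *known* ground truth, so every
stage has a parameter-recovery test surface.

## The synthetic generator

### Signal model

Each subject's clean HbO signal is band-limited Gaussian noise
(0.01–0.08 Hz) mixed across channels through the Cholesky factor of a
target correlation matrix. The target is a two-block structure over the
probe — a rostral (frontopolar, Brodmann area 10) and a caudal (dorsal
prefrontal, areas 8/9/46) compartment, derived from the packaged probe
table — plus symmetric per-subject edgewise heterogeneity
(`corr_heterogeneity_sd = 0.10`, eigenvalue-clipped back to a valid
correlation matrix). Heterogeneity matters: with perfectly uniform block
correlations, sparsity thresholding sees only the within/between ranking
and both groups would produce structurally identical binary networks;
individual variation in edge strength is also the realistic regime.

Group defaults encode an "exposed" group with *higher between-block and
lower within-block* coupling (control: within 0.60 / between 0.15;
exposed: within 0.45 / between 0.30) — a shift from segregated toward
integrated organization, the qualitative pattern the group-statistics
recovery tests check (higher global-efficiency AUC, lower local-efficiency
AUC in the exposed group).

**Exactness contract.** The mixing noise is *empirically whitened* against
the band-passed central analysis window (the recording minus the
conventional 15 s edge trim, filtered the same way the preprocessing
filter works), so the realized correlation of the clean signal on that
window equals the attached ground truth to machine precision. This is what
makes `<0.05` end-to-end recovery tolerances meaningful rather than
sampling-noise lotteries. A band of width B over a window of length T
carries about 2BT independent spectral coordinates; with B = 0.07 Hz the
window covariance has full rank for 27 channels only when the post-trim
duration exceeds roughly 200 s. For shorter recordings the generator falls
back to plain standardized mixing and flags `target_exact = FALSE`; the
default 480 s duration (450 s post-trim, 11,250 samples) is comfortably in
the exact regime and also supports scale-25 coarse-graining.

### Noise model

Out-of-band contaminants are added in µM units on top of a unit-SD signal:

* **drift** — two slow sinusoids per channel (0.001–0.006 Hz, independent
  across channels; instrumental), peak amplitude 1;
* **Mayer waves** (~0.1 Hz, amplitude 2.5), **respiration** (~0.3 Hz,
  amplitude 2), **cardiac** (~1 Hz, amplitude 5) — *spatially global*
  oscillations: one subject-level frequency (±10%) and phase, channel
  gains jittered ×U(0.5, 1.5) and channel phase lags N(0, 0.3 rad).
  Systemic oscillations cross a small cortical patch near-coherently, which
  makes them low-rank spatial components — precisely the structure the PCA
  stage exists to remove. Raw-signal cardiac amplitude dominating the
  hemodynamics by several-fold matches real recordings;
* **motion spikes** — Poisson events (2/min per channel), amplitudes
  N(0, 10 µM), exponential decay with a 0.3 s time constant: the sharp
  sub-second transient profile wavelet filtering targets. A slower decay
  would place a large share of spike energy *inside* the hemodynamic band,
  where no filter could separate it from signal.

HbR is generated as −HbO/3; the generator targets HbO covariance (all
downstream analysis uses HbO), not chromophore biophysics, and makes no
attempt at scalp optics or hemodynamic response shapes.

### Behavior

Trials follow the blocked spatial N-back design (3 conditions × 5 blocks ×
15 trials, one-third targets). Responses come from an equal-variance
Gaussian signal-detection model — P(yes | target) = Φ(d′/2 − c),
P(yes | non-target) = Φ(−d′/2 − c) — with defaults d′ = (3.2, 2.9, 2.4)
across 0/1/2-back and criterion 0.25, chosen to land A′ near the
0.92–0.95 range typical of healthy young adults on this task. RTs are
lognormal per condition (medians ≈ 450/530/700 ms, σ = 0.25 log-units);
an RT beyond the 1500 ms response window becomes a non-response.

## Preprocessing: numerical choices

* **Order is fixed and logged**: trim → OD → wavelet → PCA → band-pass →
  MBLL. The `processing_log` on every `hemo_series` records each stage
  with its parameters; tests assert the order.
* **Wavelet correction** uses a periodic Daubechies-2 transform (depth
  `floor(log2(T)) − 4`, capped at 8) with reflection padding. Detail
  coefficients outside the boxplot fences — quartiles ± 1.5 × IQR of their
  own level and channel — are zeroed. Two deliberate deviations from the
  naive rule "zero |d| > 1.5 IQR": (i) fences are anchored at the
  quartiles (the convention of the standard fNIRS implementation); a
  threshold of 1.5 × IQR from zero sits at ≈2σ for Gaussian detail
  coefficients and would clip ≈25% of the *signal's* energy at the levels
  carrying the hemodynamic band. (ii) levels with fewer than 32
  coefficients are never thresholded — quartile fences cannot be estimated
  from a handful of values, and those deep levels carry slow hemodynamics,
  not motion transients. The hot loop is compiled; an R reference
  implementation of the same transform is kept in the package and the test
  suite asserts bit-level agreement.
* **PCA global-noise removal** (threshold 0.8) removes the leading
  principal components whose cumulative explained variance stays at or
  under the threshold, at least one ("under" rule; the "reach" reading is
  a switch). Both wavelength planes share one decomposition — the global
  component is one physiological process seen at both wavelengths. Setting
  the threshold to `NULL`/0 disables the stage. On data *without* a
  dominant global component the stage necessarily removes signal — the
  leading PC of an all-positive connectivity structure is close to the
  global mean direction, so removing it acts like global-signal
  regression. For that reason the noiseless recovery tests run with PCA
  disabled, and the noise-robustness comparison uses the same
  configuration in both arms; PCA's own contract is tested directly
  (rank-1 removal, cumulative-variance bookkeeping).
* **Band-pass** is a zero-phase frequency-domain filter with the magnitude
  response of a forward-backward 3rd-order Butterworth
  (gain = 1/(1 + Ω^6), Ω = (f² − f₁f₂)/(f(f₂ − f₁))); numerically
  identical in response to `filtfilt` but with no marginally stable IIR
  state at the extreme normalized cutoffs this band implies at 25 Hz
  (8 × 10⁻⁴). Measured: 0.04 Hz passes at gain 0.999, 0.005 Hz at −41 dB,
  1 Hz at < −130 dB. The series is mirror-extended before the FFT so large
  slow components cannot leak broadband energy through the circular wrap.
* **MBLL** ships extinction coefficients from the standard literature
  compilation (per mM per cm — 690 nm: HbO 0.276, HbR 2.052; 830 nm:
  HbO 0.974, HbR 0.693), DPF 6.0 at both wavelengths, 3 cm
  source–detector separation; all configurable and logged. Because OD is
  referenced to mean intensity, concentrations are recovered relative to
  their own mean — round-trip tests compare demeaned series.

## Connectivity and graph metrics

Binarization keeps the `round(s·N(N−1)/2)` strongest edges at each
sparsity s, ranking by *signed* z (most positive first; resting HbO
correlations within one cortical patch are predominantly positive, and
positive thresholding is the common toolbox default — `rank_by = "abs"` is
the switch). Rounding is half-up; ties break by lexicographic channel
order, so the construction is deterministic and the ensemble nested.

Metric definitions: Lp averages shortest paths over *connected* pairs only
(the sparsity floor of 0.13 was chosen in the source design to avoid
isolated nodes, so disconnection is an edge case, but the convention must
be fixed); efficiencies use 1/∞ = 0; local efficiency is the global
efficiency of each neighbor-induced subgraph; nodes with degree < 2
contribute zero to Cp and Eloc. σ normalizes Cp and Lp by their means over
100 degree-preserving (double-edge-swap) randomizations with 10 attempted
swaps per edge — counts the source design leaves unstated, so common
toolbox defaults are used, seeded and configurable. Null-model rewiring
and null-network metrics go through igraph; the test suite proves the
package's own metric definitions coincide with the igraph conventions and
with independent brute-force enumeration (explicit BFS and triangle
counting) on hundreds of random graphs. AUC is trapezoidal
(rectangle-sum is a switch, recorded in output metadata).

One inference the package flags as its own reconstruction: the claim
"σ exceeds 1" is assessed by comparing each group's mean σ-AUC per unit
sparsity against 1 (a one-sample view across subjects); the original
analysis did not describe its test.

## Multiscale entropy

Sample entropy is −ln(A/B) with Chebyshev template matching, self-matches
excluded, and both template lengths counted over the same N − m start
points. The tolerance is fixed at r = 0.2 × SD of the *original* series
for all scales — the canonical multiscale-entropy convention
(`per_scale_r = TRUE` renormalizes per scale, since the source analysis
does not say which it used). Undefined entropies (no template matches, or
coarse series shorter than m + 2) are recorded as missing; the AUC covers
the longest defined prefix of the curve and never fabricates values. A
constant series is assigned entropy 0 (every template matches). The
template counter is compiled; tests require identical (A, B) counts to a
literal O(N²) counter.

## Behavior scoring

The RT outlier rule reads "shorter than 150 ms or longer than mean +
2.5 SD" as a floor plus an *upper* cut (a symmetric band is a switch): the
lower tail is already handled by the floor, which is standard RT-cleaning
practice. The mean and SD are computed per subject × condition on the
post-floor set and frozen, making the filter idempotent. Non-response
trials count as misses (targets) or correct rejections (non-targets). A′
uses the two-branch formula with H = FA (including the degenerate 0/0)
mapped to 0.5, and satisfies A′(H,FA) + A′(FA,H) = 1 identically.

## Group statistics

NBS: edge-wise pooled-variance t-tests; one-tailed suprathreshold
selection at p < 0.001 per direction (matching separately reported
"increased" and "decreased" components; two-tailed pooling is a switch);
component size = edge count; family-wise control via the permutation null
of the *maximum* component size over group-label shuffles;
p = (1 + #{null ≥ observed})/(1 + n_perm), which is unbiased and never
zero. Edge tests are not covariate-adjusted by default. Metric/entropy AUC
comparisons residualize on age (pooled least squares) before a classical
two-sample t, with Benjamini–Hochberg FDR across metrics; with no
covariates this is exactly the textbook t-test. The sample-size operation
searches the smallest equal-allocation N whose two-sided noncentral-t
power reaches the target; at d = 0.5, α = 0.05, power 0.8 it returns 128,
and 192 at α = 0.01.

The behavioral mixed-model ANCOVA of the original design is deliberately
not reproduced; the covariate-adjusted two-sample comparison on A′ and RT
summaries targets the same question with the same covariates (age, Raven's
score), and the original behavioral result is a null.

## What the tests do and do not show

The generator emulates block-structured covariance, global physiological
oscillations, drift and sharp motion transients. It does **not** emulate
scalp/skull optics, hemodynamic response functions, spatially smooth
channel correlations beyond the two-block structure, heteroscedastic
channel noise, or non-stationarity. Passing recovery tests therefore
demonstrates that the pipeline's *computations* are correct and that its
stages remove what they claim to remove under the declared noise model —
not that any scientific conclusion transfers to real recordings.

Problem sizes in the default test run are chosen to keep the suite fast
while preserving the study conditions that matter: the group-contrast
recovery test uses 50 replicates of 30 subjects per group at 240 s
recordings (the contrast encoding, channel count and group sizes are the
study's); NBS calibration uses 200 null replicates at 15 subjects per
group with 200 permutations; the small-world bound runs the full pipeline
on 2 × 15 subjects at full 480 s duration with 100 nulls per network, the
same computation the acceptance script performs.

A note on NBS calibration: with the default cluster-forming threshold
(p < 0.001) on a 27-node graph, the expected number of suprathreshold
edges under the null is 351 × 0.001 ≈ 0.35, so most null datasets produce
no component at all and the maximum-component-size null distribution is
concentrated on {0, 1}. The permutation test then controls the
family-wise error rate as designed, but conservatively — its empirical
size in simulation is near 0.01 rather than the nominal 0.05. Near-exact
behavior requires a denser suprathreshold graph (a larger cluster p or
many more edges); this is a property of extent-based cluster inference at
strict thresholds, not of the implementation.

## Known limitations

* SNIRF (HDF5) input/output is not provided; the plain CSV dialect plus a
  JSON metadata sidecar is the interchange format.
* The exact-correlation contract of the generator holds on the central
  analysis window under the default trim/band conventions; custom
  preprocessing parameters see it only approximately.
* σ is undefined (NA, with a warning) when the null networks degenerate
  (e.g. vanishing null clustering); extremely sparse graphs below the
  0.13 sparsity floor are not a supported regime.
* The pipeline analyzes HbO only, as the source design does; HbR is
  carried through preprocessing but not analyzed further.
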