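# fnirsnet

Resting-state functional near-infrared spectroscopy (fNIRS) analysis for a
27-channel prefrontal probe: preprocessing of raw two-wavelength light
intensities into hemoglobin concentration changes, sparsity-thresholded
functional-network construction, graph-theoretic network metrics,
multiscale-entropy complexity, spatial N-back behavioral scoring, and
between-group inference — plus a synthetic two-group generator with known
ground truth so the whole pipeline is testable without human recordings.

It is aimed at researchers who analyze resting-state optical neuroimaging
of the prefrontal cortex and want a scripted, auditable, reproducible
version of the standard toolbox workflow (Homer-style preprocessing,
GRETNA-style network analysis).

## The analysis in brief

Raw intensities `I(t)` at 690/830 nm become optical-density changes
`ΔOD = −log(I/mean I)`, are motion-corrected by zeroing outlying discrete
db2-wavelet detail coefficients (quartiles ± 1.5 IQR per level), cleaned of
global physiological noise by projecting out leading principal components
(cumulative variance ≤ 80%), band-passed to 0.01–0.08 Hz with a zero-phase
Butterworth-magnitude filter, and converted by the modified Beer–Lambert
law, `ΔOD(λ) = d·DPF(λ)·[ε_HbO(λ)ΔHbO + ε_HbR(λ)ΔHbR]`, into µM
concentration changes.

Connectivity is Pearson correlation between all HbO channel pairs, Fisher
z = atanh(r), binarized at each sparsity s ∈ {0.13, 0.14, …, 0.40} by
keeping the round(s·351) strongest edges. On each binary network the
package computes the clustering coefficient Cp, characteristic path length
Lp, global/local efficiency E_glob/E_loc, nodal efficiency E_nod, and
small-worldness σ = (Cp/⟨Cp_rand⟩)/(Lp/⟨Lp_rand⟩) against 100
degree-preserving rewirings; each curve is summarized by its integral over
the sparsity range (AUC). Channel complexity is multiscale sample entropy
(scales 1–25, m = 2, r = 0.2 SD; SampEn = −ln(A/B) with Chebyshev
matching). Behavior is scored by RT cleaning (150 ms floor, mean + 2.5 SD
cut) and the sensitivity index

    A' = 0.5 + (H − FA)(1 + H − FA) / (4H(1 − FA))    for H ≥ FA

(mirrored for FA > H). Group inference: the network-based statistic
(edge-wise t at p < 0.001, component extent vs the permutation null of the
maximum component, 1000 label shuffles), covariate-adjusted two-sample
t-tests with Benjamini–Hochberg FDR on metric AUCs (age regressed out),
partial correlations with behavior, and an exact noncentral-t sample-size
search.

See `vignettes/fnirs-network-pipeline.Rmd` for the full model description,
parameter defaults and design rationale.

## Worked example

```r
library(fnirsnet)

cfg <- pipeline_config(
  simulation = simulation_config(n_subjects_per_group = 5),
  seed = 7, include_sigma = FALSE, run_mse = FALSE, n_perm = 200)
res <- run_pipeline(cfg)
res$group_tests
#>      metric mean_group1 mean_group2      t df        p        q
#> 1    cp_auc       0.157       0.107   6.79  8 1.40e-04 1.40e-04
#> 2    lp_auc       0.411       0.559 -10.16  8 7.56e-06 1.51e-05
#> 3 eglob_auc       0.100       0.155 -11.29  8 3.40e-06 1.36e-05
#> 4  eloc_auc       0.195       0.147   7.26  8 8.75e-05 1.17e-04
```

Group 1 is the control group, group 2 the "exposed" group whose generator
target has weaker within-block and stronger between-block coupling. The
t-tests (age-adjusted, FDR-corrected q) recover exactly the injected
reorganization: higher global-efficiency AUC (0.155 vs 0.100) and lower
local-efficiency and clustering AUCs in the exposed group — a shift from
segregated toward integrated network organization. (Lp here averages over
connected pairs only, so the densely clustered control networks, whose
cross-cluster pairs are disconnected at low sparsity, score the *shorter*
path length.) The NBS in the exposed-greater direction finds the injected
between-block component (largest component 13 edges, p_perm ≈ 0.01), and
the behavioral A′ means sit in the 0.93–0.97 range typical for this task,
with no group difference by design:

```r
#>        control exposed
#> 0-back   0.970   0.968
#> 1-back   0.961   0.951
#> 2-back   0.938   0.929

sample_size_two_groups(0.5, alpha = 0.05, power = 0.8)   # 128
sample_size_two_groups(0.5, alpha = 0.01, power = 0.8)   # 192
```

A command-line front-end ships in `inst/cli/fnirs-netpipe.R`
(`simulate` and `run` subcommands over the same functions).

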