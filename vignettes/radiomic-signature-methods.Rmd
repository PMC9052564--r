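---
title: "Methods: a planning-CT radiomic signature for pathologic response in rectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a planning-CT radiomic signature for pathologic response in rectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Neoadjuvant chemoradiation for locally advanced rectal cancer produces
pathologic good response (GR) — Dworak tumor regression grade (TRG) 3 or 4 —
in roughly half of patients. Predicting GR before treatment from the
radiotherapy planning CT would cost nothing extra: the scan is acquired
anyway, in treatment position, with calibrated Hounsfield units. This package
implements the full analysis pipeline for building and externally validating
such a radiomic signature, and — because no patient imaging is distributed —
a synthetic phantom-cohort generator with *known* class structure, so every
stage can be exercised and the pipeline's ability to recover an injected
effect can be measured.

The binary endpoint is `GR = 1` iff TRG is 3 or 4 (`derive_gr_labels()`);
pathologic complete response (TRG 4 alone) is exposed as a secondary label
for reporting only.

## Feature extraction

Each case is a 3-D CT volume plus a binary gross-tumor-volume (GTV) mask on
the same anisotropic grid (default 1 x 1 x 3 mm; features are computed on
the native grid without resampling). The catalogue (`feature_catalogue()`)
holds 1150 features:

* **16 shape features**, from the mask only: voxel-count volume, face-count
  surface area, sphericity-family descriptors, maximum 3-D diameter, and the
  principal-axis lengths from the spacing-aware covariance of voxel centres,
  with elongation = sqrt(lambda2/lambda1) and flatness = sqrt(lambda3/lambda1).
* **9 image channels**: the original CT plus the 8 channels of a one-level
  undecimated separable coiflet-1 decomposition (`wavelet_decompose()`), each
  carrying
* **48 intensity features** (18 moment/robust statistics, 23
  intensity-histogram features on the discretised levels, 7
  intensity-volume-histogram features) and **78 texture features** from the
  five grey-level matrix families: GLCM (25), GLRLM (16), GLSZM (16),
  GLDZM (16) and NGTDM (5).

16 + 9 x (48 + 78) = 1150. The published per-feature list is not available;
this enumeration is a consistent IBSI-style reconstruction constrained by the
published total and by the five published signature components
(`LHL_glszm_large_zone_emphasis`, `original_shape_elongation`, `HHH_ih_mean`,
`HLL_glrlm_grey_level_variance`, `HHH_glcm_cluster_tendency`), all of which
the catalogue contains. "Run Level Variance" is implemented as GLRLM
grey-level variance, the closest standard feature to that printed name (the
run-length variance also exists in the catalogue under its own name).

Texture matrices are computed in 3-D: co-occurrences at Chebyshev distance 1
over the 13 unique directions, runs along the same 13 directions, zones as
26-connected components, zone distances as the minimum Chebyshev distance to
outside the ROI with border voxels at distance 1, and NGTDM differences
against the valid 26-neighbourhood mean. Directional counts are *merged*
into a single matrix per family by default; per-direction feature averaging
is available (`aggregation = "averaged"`). These kernels are written in C++
and are verified in the test suite against naive nested-loop reference
implementations on hundreds of random arrays — that oracle equivalence, not
any reference dataset, is the correctness anchor.

### Wavelet conventions

The published analysis states only "coiflet-1, one level, undecimated, 8
filter combinations". Everything else is a convention that must be fixed for
channel names like `HLL` to be reproducible, and is therefore fixed here
once:

* channel letter order is (x, y, z): `HLL` is high-pass along x;
* boundary handling is half-sample symmetric (mirror) padding, avoiding the
  wrap-around artefacts periodic padding would create on anatomy;
* filtering is applied to the **full volume before masking**, then features
  are computed within the ROI of each filtered channel — filtering a
  masked-out volume would let the mask boundary dominate the response;
* the low-pass filter is normalised to unit DC gain (taps sum to 1), so the
  LLL channel preserves mean HU and wavelet intensity features stay on an
  interpretable scale; the orthonormal sqrt(2) convention is available
  (`coif1_bank("orthonormal")`).

### Discretisation

No discretisation scheme is published. The defaults follow standard practice
for calibrated CT: fixed bin width of 25 HU anchored at -1000 HU on the
original channel, and a fixed bin count of 64 on wavelet channels, whose
intensities carry no absolute scale. Both are configurable per channel, and
an optional HU re-segmentation window exists but is off by default. Fixed
conventions keep degenerate inputs finite: a constant ROI yields a
single-level discretisation, `0 log 0 = 0`, correlation-type features are 0
when a variance term vanishes, and NGTDM coarseness is capped at 1e6.

## Feature reduction (fitted on training data only)

1. **Robust scaling**: per feature, `(x - median) / IQR`, with median and
   IQR learned from training rows. Zero-IQR features pass through flagged
   (divisor 1) and die at the variance filter.
2. **Correlation clustering**: agglomerative clustering with distance
   `1 - |r|` (Pearson) and complete linkage, cut at `|r| > 0.95`. Complete
   linkage makes the cut semantics exact — every pair inside a cluster
   correlates above the threshold; `|r|` treats anti-correlated features as
   redundant. Linkage and sign handling are configurable because neither is
   published.
3. **PCA meta-features**: each cluster collapses to the first
   principal-component score of its train-centred members — the single
   direction conserving the maximum variance inside the cluster. Loadings
   are unit-norm with the largest-magnitude loading forced positive;
   singletons pass through unchanged. Meta-features are named after their
   dominant member.
4. **Variance filter**: meta-features with training variance strictly below
   0.3 are dropped. The filter sits after scaling and after the PCA step,
   matching the published order (clustering, then PCA, then the exclusion on
   the final feature set).

The whole reduction is frozen after fitting: applying it to validation rows
changes nothing (`write_reducer()` serialises medians, IQRs, clusters and
loadings to JSON, and the test suite checks the no-leakage contract by
hashing the fit before and after validation use). Whether the original
analysis fitted these statistics on the training cohort only is not
published; fitting on training only is this package's contract, since the
alternative leaks validation information.

## Signature selection and validation

Model search uses sequential forward selection to a fixed signature size
(default 5 meta-features), scoring every candidate set by mean stratified
fivefold cross-validated ROC-AUC, *jointly* over the candidate model grid:
k-NN with k in {3, 5, 7, 9}, Gaussian naive Bayes, an RBF SVM, and a random
forest. The (feature set, model) pair with the best mean CV AUC wins; ties
break to the less complex model, then the lexicographically smaller feature
name. Forward selection is fixed as the one reproducible default because the
original report names only "several feature selection algorithms" (its
machine-learning stack's flagship selector is sequential); a univariate
AUC ranking can be emulated by setting `signature_size = 1` repeatedly, but
is not a separate code path.

The k-NN scorer is deterministic by construction: Euclidean distance in
meta-feature space, score = positive fraction among the k nearest, distance
ties broken by training-row order. With k = 5 scores take only six values;
ROC curves are swept over the observed scores, tied scores move diagonally,
and the trapezoid area is cross-checked against the normalised Mann-Whitney
U statistic on every validation report (they must agree to 1e-10).

External validation applies the frozen reducer and frozen classifier to
cohort B and reports the ROC and AUC. Nothing refits; a missing signature
column is an error, not an imputation.

## The phantom generator

`generate_cohort()` emulates the statistical skeleton of the dual-cohort
design, not CT realism:

* two cohorts (training A, external validation B) with a mild additive
  inter-site intensity shift (default +10 HU on B);
* GR prevalence 0.49 (the observed 99/201), exact by stratified rounding,
  with TRG drawn conditionally on the label (3:4 as 74:25 among responders,
  0:1:2 as 2:31:69 otherwise) so the endpoint derives from TRG exactly as in
  the clinical definition;
* roughly ellipsoidal GTVs with configurable in-plane elongation
  (default 0.55-0.95) and principal semi-axes of 9-14 mm on a
  40 x 40 x 16 voxel grid at 1 x 1 x 3 mm — phantom tumours of a few cm^3,
  kept modest so a full dual-cohort study stays desk-scale;
* soft-tissue-like background (about 40 +/- 15 HU) so masked extraction is
  really exercised;
* interior texture as a Gaussian random field whose smoothing length and
  amplitude depend on the class: good responders get a longer correlation
  length and lower amplitude (lower heterogeneity, consistent with the
  direction of the published signature), scaled by `texture_effect`. At
  `texture_effect = 0` (and zero site shift) the classes are exchangeable by
  construction.

What passing tests on phantoms do **not** show: that the pipeline reaches
any particular AUC on real rectal-cancer CTs. The published cohorts are not
deposited, so the published AUCs (0.65 +/- 0.02 training, 0.63 validation)
cannot be recomputed; they are treated as qualitative context only. What the
phantom studies do show is that the pipeline (i) recovers a strong injected
texture effect through the whole stack — synthetic cohorts of 120 training /
75 validation cases (mirroring the 126/75 split) give validation AUC > 0.8 —
and (ii) does not hallucinate signal: with no injected effect the mean
validation AUC over 20 seeds stays in [0.38, 0.62].

## Problem sizes and numerical choices

The recovery and null studies run at 195 cases (120/75) on the default
40 x 40 x 16 grid; the parameter-recovery and null studies use the k-NN
branch of the model grid (the confirmatory model class of the published
signature), while single end-to-end runs and the analysis scripts search the
full grid. Random-forest candidates use 128 trees with a fixed seed;
the SVM uses cost 1 on already-scaled inputs. All stochastic steps (cohort
generation, fold assignment, forest growth) derive from the single pipeline
seed, and two runs of `run_end_to_end()` with the same config are identical
apart from timings.

Known limitations: no isotropic resampling or scanner harmonisation (the
analysis relies on HU calibration); no 2-D feature variants; no multi-level
or non-coiflet wavelets; the "volume-averaged and voxelized" dual extraction
mentioned in the source report is undefined there and not implemented; and
the exact 1150-feature enumeration is a reconstruction, so feature *names*
are reproducible only under this package's conventions.

## Running the analysis

```{r}
library(larcradiomics)
cfg <- pipeline_config(seed = 11)
manifest <- run_end_to_end(cfg)
manifest$signature$features
manifest$validation$auc
```

The numbered scripts under `analysis/` run the same stages as separate,
inspectable steps (simulate, extract, reduce, train, validate), writing
their tables under `results/`.
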