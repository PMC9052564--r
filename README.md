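# larcradiomics

Radiomics pipeline for predicting pathologic response to neoadjuvant
chemoradiation in locally advanced rectal cancer (LARC) from radiotherapy
**planning CT** scans — feature extraction, feature reduction, signature
selection with cross-validation, and frozen external-cohort validation —
plus a synthetic phantom-cohort generator so the whole pipeline is testable
and its parameter-recovery behaviour measurable without patient data.

## The science in one paragraph

The endpoint is pathologic **good response** (GR): Dworak tumor regression
grade (TRG) 3 or 4 on the surgical specimen, observed in roughly half of
patients. From each patient's planning CT and manually contoured gross tumor
volume (GTV), the pipeline extracts **1150 features**: 16 shape descriptors
(including elongation from the spacing-aware covariance eigenvalues,
`sqrt(lambda2/lambda1)`), and on each of 9 image channels — the original CT
plus the 8 channels of a one-level **undecimated coiflet-1 wavelet**
decomposition (`{L,H}^3` along x, y, z) — 48 intensity features and 78
texture features from the five 3-D grey-level matrix families
(GLCM / GLRLM / GLSZM / GLDZM / NGTDM, IBSI-style definitions, 13 merged
directions, 26-connectivity). Features are scaled by the training-cohort
median/IQR, clustered hierarchically at Pearson `|r| > 0.95` (complete
linkage), each cluster is collapsed to its first principal-component
**meta-feature**, and meta-features with training variance `< 0.3` are
dropped. A signature of 5 meta-features is selected by sequential forward
selection scored with mean stratified **fivefold cross-validated ROC-AUC**,
jointly over a candidate model grid (k-NN with k in {3,5,7,9}, Gaussian
naive Bayes, RBF SVM, random forest), and the frozen model (scaler,
clusters, loadings, classifier) is applied once to the external cohort. AUC
is computed as the normalised Mann–Whitney U statistic and cross-checked
against the trapezoid ROC area on every report.

## Worked example

A complete study on a synthetic dual-cohort phantom set (cohort A trains,
cohort B is the frozen external validation):

```r
library(larcradiomics)

cfg <- pipeline_config(
  cohort = synthetic_cohort_config(n_cases = 195, texture_effect = 3,
                                   validation_fraction = 75 / 195, seed = 11),
  grid = default_model_grid("knn"), seed = 11)
manifest <- run_end_to_end(cfg)

manifest$signature$features
manifest$signature$mean_cv_auc
manifest$validation$auc
```

which prints (run as shown):

```
> manifest$signature$features
[1] "HLH_stat_maximum"                "HHH_glcm_cluster_prominence"
[3] "HHH_glcm_inv_var"                "HHH_glcm_cluster_shade"
[5] "HHH_gldzm_zone_distance_entropy"
> manifest$signature$mean_cv_auc
[1] 1
> manifest$validation$auc
[1] 0.9964438
```

The selected meta-features are wavelet-channel intensity and texture
descriptors — exactly the families the injected class difference (interior
heterogeneity) lives in. The training cross-validated AUC is 1.0 and the
frozen model transfers to the untouched external cohort at AUC 0.996.

`texture_effect = 3` injects a class difference in interior heterogeneity
(good responders smoother and flatter); the signature picks texture
meta-features and the validation AUC shows the effect survives the frozen
external application. With `texture_effect = 0` the classes are exchangeable
by construction and the validation AUC hovers around 0.5.

The same study, step by step with inspectable intermediate tables under
`results/`, is in the numbered scripts:

```sh
Rscript analysis/01_simulate_cohorts.R   # phantom cohorts -> NIfTI + clinical.csv
Rscript analysis/02_extract_features.R   # 1150-feature table
Rscript analysis/03_reduce_features.R    # scaler + clusters + PCA meta-features
Rscript analysis/04_train_signature.R    # forward selection over the model grid
Rscript analysis/05_validate_external.R  # frozen validation, ROC + AUC
```

## Layout

```
R/                  pipeline implementation (cohort generator, NIfTI I/O,
                    discretisation, wavelet bank, feature families,
                    reduction, modelling, orchestration)
src/                C++ texture-matrix kernels (Rcpp)
analysis/           numbered step-by-step study drivers
scripts/            acceptance script
tests/testthat/     unit, property and acceptance tests (incl. brute-force
                    oracles for every texture family and the wavelet bank)
vignettes/          methods vignette: model, conventions, design choices
```
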