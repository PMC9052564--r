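Package: larcradiomics
Title: Planning-CT Radiomics Signatures for Pathologic Response in Rectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible radiomics pipeline for predicting
    pathologic good response (Dworak tumor regression grade 3-4) to neoadjuvant
    chemoradiation in locally advanced rectal cancer from radiotherapy planning
    CT scans. Implements 3-D IBSI-style feature extraction (intensity, shape,
    and GLCM/GLRLM/GLSZM/GLDZM/NGTDM texture families) on the original image
    and on eight one-level undecimated coiflet-1 wavelet channels,
    interquartile-range feature scaling, correlation-based hierarchical feature
    clustering collapsed to per-cluster principal-component meta-features with
    a variance filter, and sequential forward signature selection over a
    candidate model grid (k-nearest neighbours, Gaussian naive Bayes, SVM,
    random forest) scored by stratified fivefold cross-validated ROC-AUC, with
    frozen external-cohort validation. A synthetic phantom-cohort generator
    with known class structure makes every stage testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    e1071,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
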