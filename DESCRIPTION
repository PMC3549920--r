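Package: netfmri
Title: Voxel-Level Functional Network Features and Classification for Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds voxel-level functional connectivity networks from task fMRI
    runs and compares their topological features with conventional GLM
    activation maps. Provides a latent-factor synthetic cohort generator in
    which two groups share identical task-activation statistics but differ in
    long-range, inter-hemispheric inter-voxel coupling; GLM fitting with
    canonical double-gamma HRF regressors, drift and motion nuisance terms, and
    contrast t-maps; thresholded correlation graphs with degree, strength,
    clustering, local-efficiency, global and distance-resolved features;
    mass-univariate group statistics with Benjamini-Hochberg and Bonferroni
    correction, selection stability, and motion-confound checks; Gaussian naive
    Bayes, linear support-vector, and sparse Gaussian Markov random field
    classifiers (the latter via l1-penalised inverse-covariance estimation with
    a duality-gap certificate); and a leave-one-subject-out cross-validation
    pipeline with in-fold feature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
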