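Package: tdcsfc
Title: Predicting tDCS Treatment Response from Seed-Based Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting clinical response to transcranial direct
    current stimulation (tDCS) in schizophrenia patients with persistent
    auditory verbal hallucinations from baseline resting-state fMRI.
    Implements subject-level quality control (outlier-volume scrubbing,
    censored-fraction exclusion), aCompCor nuisance regression, band-pass
    filtering, despiking and Gaussian smoothing of 4D BOLD series;
    left superior temporal gyrus seed-based connectivity mapping with
    Fisher Z transformation and atlas-masked feature extraction;
    L1-regularized logistic classification under repeated stratified
    cross-validation with a paired model comparison and a clinical-covariate
    baseline; a desk-scale 3D convolutional classifier with a
    transfer-learning protocol (CGI-rule labelling, stratified minority
    oversampling, layer freezing, revert-style early stopping); and exact
    Shapley attribution for linear models with regional aggregation.
    Because the source cohort is not public, a synthetic-cohort generator
    with planted seed-to-region coupling provides statistically matched
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
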