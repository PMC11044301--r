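Package: adcr
Title: Quantitative ADC Voxel Analysis for Neuroprognostication After Cardiac Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of apparent diffusion coefficient (ADC) maps
    for predicting neurological outcome in comatose cardiac-arrest survivors.
    Computes the ADC-R(x) statistic (the percentage of analysable brain voxels
    with ADC between 200 and x, in units of 1e-6 mm^2/s), derives
    zero-false-positive-rate cutoffs on a derivation cohort and validates them
    in internal and external cohorts, with empirical ROC curves, DeLong
    variance estimates and tests, exact Clopper-Pearson confidence intervals,
    and nonparametric group comparisons. Includes a synthetic three-tissue ADC
    phantom generator (parenchyma, CSF, hypoxic-ischaemic lesions) so the full
    derivation/validation pipeline can be exercised end-to-end without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    stats,
    utils,
    graphics,
    parallel
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
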