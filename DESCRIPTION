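Package: dceradiomics
Title: Pharmacokinetic DCE-MRI Radiomics Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for pharmacokinetic radiomics of
    dynamic contrast-enhanced MRI. Generates digital phantoms and labeled
    cohorts from forward Tofts and spoiled gradient-echo physics, estimates
    R1/M0 from variable-flip-angle volumes and voxelwise Tofts parameters
    (ktrans, kep, ve) plus initial area under the enhancement curve, segments
    lesions by a relative-enhancement threshold, extracts 163 shape,
    first-order and 3D co-occurrence texture features per lesion, and builds
    multivariable logistic models of binary histological outcomes through
    gain-equation feature reduction, imbalance-adjusted bootstrap resampling
    and 0.632+ bootstrap AUC stepwise selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
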