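Package: TumorHabitats
Title: Multiparametric PET/MRI Tumor Habitat Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise quantitative imaging pipeline for discovering and
    tracking physiological tumor subregions ("habitats") from combined
    PET and MRI acquisitions. Provides forward simulation of a digital
    tumor phantom (diffusion-weighted MRI, variable-TR T1 mapping,
    dynamic contrast-enhanced MRI, FDG/FLT PET activity and matched
    histology stain-density sections), voxel-wise parametric mapping
    (apparent diffusion coefficient, saturation-recovery T1, Extended
    Tofts pharmacokinetics, standardized uptake values) with
    physiological filtering, mutual-information affine coregistration,
    pooled hierarchical habitat clustering with silhouette model
    selection, multiregional spatial-interaction statistics against a
    size-preserving randomized null, histology habitat mapping, and
    permutation-based imaging-histology validation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    minpack.lm,
    pracma,
    cluster,
    mclust,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
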