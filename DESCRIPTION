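Package: strokeflow
Title: Longitudinal SPECT/MRI Quantification of Stroke Recovery in the Rodent Brain
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for longitudinal SPECT/MRI follow-up of
    experimental stroke (rodent middle cerebral artery occlusion). Builds
    Lassen-corrected relative cerebral blood flow (rCBF) parametric maps from
    HMPAO SPECT volumes, classifies hypo- and hyperperfused tissue against a
    healthy reference cohort with per-region 2-SD bands over a brain atlas,
    tracks perfusion inside the day-0 hypoperfused mask across timepoints,
    profiles recovery as a function of distance from the injection site,
    quantifies cerebral edema on T2 MRI by contralesional Gaussian histogram
    thresholding with ventricle and space-occupying corrections, and aggregates
    neurological deficit and cylinder-test scores. A seeded phantom generator
    emulates the statistical structure of such studies with full ground truth,
    so every stage of the analysis is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, RNifti, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'volumegrid.R'
    'volio.R'
    'lassen.R'
    'perfusion.R'
    'edema.R'
    'regions.R'
    'behavior.R'
    'phantom-geometry.R'
    'phantom.R'
    'pipeline.R'
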