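Package: TNMseg
Title: Task-Aware Evaluation of Lesion Segmentations for TNM Staging in
    Whole-Body PET/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates automated lesion segmentations of whole-body
    oncologic FDG PET/CT against expert reference masks at the level that
    matters clinically: voxel overlap (Dice, false negative/positive
    volume, total metabolic tumour volume, Bland-Altman agreement),
    lesion-level detection with an aetiology-based error taxonomy,
    rule-based TNM category derivation and UICC (9th edition) stage
    grouping from lesion sets, and patient-level stage migration with
    treatment decision-boundary impact levels. Ships a synthetic phantom
    generator that emulates the characteristic failure modes of
    segmentation models (missed lesions, taxonomy-tagged false positives,
    boundary perturbation, hilar lesion merging) so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'io.R'
    'lesions.R'
    'metrics.R'
    'staging.R'
    'migration.R'
    'phantom.R'
    'evaluate.R'
    'cli.R'
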