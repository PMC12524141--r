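Package: cimqc
Title: Multi-Dimensional Quality Control for Multicenter Cancer-Imaging Repositories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-validation toolkit for multicenter cancer-imaging repositories
    holding DICOM series, NIfTI annotation masks and tabular clinical metadata.
    Scans a provider/patient/timepoint/modality tree, evaluates rule-based
    quality dimensions (completeness, validity, consistency, integrity,
    anonymization), profiles subgroup fairness, detects duplicate images by
    UID screening and pixel mean-squared-error similarity, checks annotation
    masks against their imaging series, summarizes acquisition-relevant DICOM
    attributes, audits de-identification compliance including burnt-in report
    detection, and emits a machine-readable quality report. Ships a synthetic
    repository generator with controlled defect injection that serves as the
    ground-truth oracle for every metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
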