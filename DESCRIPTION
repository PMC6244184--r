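Package: lipidflow
Title: Targeted Lipidomics Signal Extraction with QC-Anchored Drift
    Correction and Technical Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-acquisition processing for targeted-extraction untargeted
    lipidomics assays run on LC-MS instruments with pooled-plasma quality
    control (QC) injections. Provides a lipid target-ion database model with
    monoisotopic adduct m/z arithmetic, a synthetic multi-batch LC-MS run
    generator with known ground truth, extracted-ion-chromatogram peak-height
    extraction with internal-standard quadratic retention-time recalibration,
    QC-anchored LOESS drift correction with leave-one-out cross-validated
    span selection and cross-batch median normalization, adduct and
    dual-polarity deduplication by lowest QC relative standard deviation,
    RSD-based feature filtering, and a technical-validation suite (duplicate
    paired t-tests, PCA overview, blank carryover checks, RSD histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
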