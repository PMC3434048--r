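Package: tumourvol
Title: MRI-Based Tumour Volumetry with Partial-Volume Error Bounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic volumetry of small subcutaneous tumours in
    T2-weighted small-animal MR images. Implements ROI-derived threshold
    segmentation with per-slice threshold adjustment, manual polygon
    exclusion, and growing-seed conversion of enclosed low-signal regions,
    followed by voxel-count to mass conversion under an assumed tissue
    density. A deterministic sphere-on-grid simulator quantifies the
    maximum possible partial-volume-effect error as a function of the
    voxels-per-tumour-diameter ratio, a synthetic phantom generator
    provides MR-like test images with analytic ground-truth volumes, and
    agreement statistics (coefficient of variation, signed interobserver
    deviation, least-squares regression with Pearson r squared) support
    repeatability studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
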