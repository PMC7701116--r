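Package: voxpipe
Title: Cohort-Scale Medical Image Project Store and Pipeline Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, scriptable system for managing cohorts of medical
    images as NIfTI+JSON pairs inside an on-disk project with a tag-driven
    database, and for designing and executing dependency-aware processing
    pipelines over them. Includes a converter for single-frame DICOM series
    and NIfTI files with YAML-customizable metadata extraction, BIDS import,
    a library of processing modules (Gaussian smoothing, thresholding, ROI
    masking, affine reslicing, brain extraction, CT preprocessing, local
    entropy texture maps, seeded region growth, first-order ROI statistics
    export), full per-file provenance recorded in JSON sidecars, a parallel
    job executor with crash-safe staging, and deterministic synthetic-cohort
    generators for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    png,
    yaml,
    igraph,
    parallel,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
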