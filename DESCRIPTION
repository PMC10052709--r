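Package: hepavol
Title: Computed Tomographic Hepatic Volumetry with Slice Decimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for slice-summation (Cavalieri) organ volumetry from CT
    segmentation masks or per-slice area series, with a focus on canine
    hepatic volumetry. Computes full liver volumes, re-estimates them from
    decimated slice subsets via an extrapolation formula with exhaustive
    phase-offset enumeration, quantifies interobserver variability
    (coefficient of variation, greatest and pairwise percent differences),
    and summarises decimation error by slice-interval group and by
    slice-count bin. Includes a synthetic canine-liver phantom generator
    with a calibrated multiplicative observer-noise model so the entire
    pipeline is testable without clinical CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
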