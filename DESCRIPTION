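Package: hrdot
Title: Characterization of Hyperreflective Dots in Structural and
    Angiographic OCT B-Scan Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, three-dimensional tracing, shape and location
    classification, and perfusion-status assignment of hyperreflective dots
    in stacks of structural and angiographic optical coherence tomography
    (OCT) B-scans of the macula. Includes a synthetic OCT phantom generator
    producing paired structural/angiographic volumes with layered retinal
    reflectivity, multiplicative speckle, planted granules and capillary
    segments with ground truth, and a statistics stage with per-subject
    grading summaries, exact rank-sum testing and a packaged per-subject
    grading table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tiff,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
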