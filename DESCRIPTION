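Package: spheromorph
Title: Brightfield Spheroid Morphometry and Mesenchymal Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated morphometry of bioprinted tumor spheroids imaged by
    brightfield microscopy. Segments spheroids in single-plane TIFF images
    through a fixed preprocessing chain (grayscale conversion, unsharp-mask
    sharpening, Gaussian smoothing, Sobel edge enhancement) followed by
    minimum cross-entropy thresholding with correction factor and bounds,
    edge-ring solidification, intensity-seeded declumping and diameter/border
    filtering. Computes per-object shape descriptors (area, perimeter, convex
    hull area, solidity, form factor, major axis length) and a mesenchymal
    morphology score 1/(form factor x solidity) used as a shape proxy for
    epithelial-mesenchymal transition, and aggregates longitudinal
    per-condition summaries with normalization to a control baseline and
    Student's t-tests. Includes a seeded synthetic brightfield image
    generator with exact geometric ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
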