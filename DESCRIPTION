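Package: beadmap
Title: Marker-Bead Sequence Alignment for Mapping Flow-Cytometry Images
    to Plate Positions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for relating single-cell images acquired in flow to the
    physical positions of the same cells after robotic first-in-first-out
    dispensing onto a porous membrane. Marker beads of three sizes are
    interleaved with the cells and read on both instruments as a sequence
    over a three-letter alphabet; global alignment of the two readouts
    detects and localizes deletion and misplacement errors, per-gap
    cell-count verification isolates erroneous regions, and the surviving
    regions yield an unambiguous image-to-position mapping. Includes
    simulators for event streams, dispensing-error processes and
    low-resolution plate images, Monte Carlo error-detection experiments,
    size-based object detection and micron-accurate registration on plate
    images, 2D/3D morphological feature extraction, and k-means clustering
    with a fit/predict workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
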