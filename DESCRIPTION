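Package: hemocount
Title: Automated Hemocytometer Cell Counting from Phone Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated counting of cultured cells (e.g. the prostate cancer
    lines PC3, LN-CaP and DU-145) in hemocytometer chamber photographs taken
    with ordinary phone cameras. A hierarchical region-proposal stage combined
    with a small convolutional network locates the counting-grid region of
    interest inside cluttered scenes; the cropped chamber is then processed by
    grayscale conversion, morphological opening, Canny edge detection and a
    gradient-voting Hough circle transform with perimeter verification to
    detect and count cells. Per-chamber counts are aggregated into a cell
    concentration using the standard 0.1 cubic-millimetre chamber volume.
    Includes a seeded synthetic-scene generator with exact ground truth,
    classification and counting evaluation metrics, and command-line entry
    points for simulation, training, counting and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    png,
    jpeg,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
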