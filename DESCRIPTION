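Package: chiralcell
Title: Cell Chirality from Micropattern Dominant-Orientation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies population-level cell chirality from stitched
    fluorescence images of cells confined on rectangular micropatterns.
    Implements the full semi-automated workflow: fiducial-referenced grid
    cropping with rotation normalisation, cell-coverage filtering,
    structure-tensor dominant-orientation estimation, and axial circular
    statistics (angle doubling, circular mean/SD, large-sample confidence
    intervals for the mean direction, Watson's two-sample U-squared test)
    leading to clockwise/counterclockwise chirality calls. Includes a
    synthetic micropattern scene generator with known ground truth so every
    stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    readxl,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
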