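Package: tearllt
Title: Tear-Film Lipid Layer Thickness from Placido-Disk Interference Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized quantification of tear-film lipid layer thickness
    (LLT) from placido-disk tear film analyzer imagery. Decomposes blink-cycle
    recordings into timestamped frames, constructs the inferior-half annular
    region of interest, removes the dark placido-ring background by
    maximum-entropy (Kapur) thresholding, converts each pixel's interference
    color to a thickness via nearest-Euclidean-distance look-up against a
    thin-film optics reference table, and summarizes per-frame mean LLT.
    Includes the per-timepoint linear transform mapping pre-segmentation to
    post-segmentation LLT, reliability statistics (ICC(2,1), Pearson
    correlation, paired t-tests), a physics-based generator for the
    thickness-to-RGB look-up table, and a synthetic phantom module that
    renders placido-ring interference images with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
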