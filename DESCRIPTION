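Package: markalign
Title: Fiducial-Mark Detection and Automated Stage Realignment for
    Multi-Chamber Microscopy
Version: 0.1.0
Authors@R:
    person("Markalign", "Developers", email = "markalign@example.org",
           role = c("aut", "cre"))
Description: Detects three-circle fiducial alignment marks in bright-field
    micrographs of microfluidic culture chambers and drives closed-loop
    realignment of a motorized xy stage.  The detection pipeline combines
    Gaussian lowpass filtering, Sobel gradient extraction with non-maximum
    suppression and morphological thinning, and tri-valued circle-template
    matching on the edge image.  A virtual stage simulator and a synthetic
    image renderer with known ground-truth pose allow the alignment-error
    experiments (drift accumulation over serpentine scans, pre/post
    alignment error distributions, chamber-distance updating) to be
    reproduced entirely in silico.  Also includes normalized chamber
    intensity tracing for liquid-replacement characterization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
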