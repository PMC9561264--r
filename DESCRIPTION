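Package: afmdna
Title: Single-Molecule Atomic Force Microscopy Analysis of Protein-DNA Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies protein-DNA interactions from atomic force microscopy
    (AFM) topography images: worm-like chain simulation of surface-deposited
    DNA with bound protein complexes (a testable stand-in for raw AFM scans),
    DNA contour tracing with quality control, per-complex measurement of
    fractional binding position, DNA bend angle, complex volume and quantum-dot
    labelling status, position-histogram Gaussian fits yielding binding
    specificities and site occupancies per DNA, bend-angle state decomposition,
    replicate significance testing, and Hill-equation fits of fluorescence
    polarisation titrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stringr,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
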