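Package: beadsort
Title: Simulated Fluorescence Screening and Sorting of Porous Library Beads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-silico re-creation of an automated microfluidic screen for
    one-bead one-compound (OBOC) peptide libraries. Synthesizes two-channel
    (red/green) 12-bit fluorescence images of porous beads with homogeneous or
    halo-like label distributions, detects and segments beads by local-mean
    thresholding and morphological cleanup, extracts percentile-based intensity
    and alpha homogeneity metrics, classifies beads against operator-defined
    decision hyperplanes, discriminates ambiguous halo classes by K-means, and
    simulates the valve-driven sorting loop to report yield and accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
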