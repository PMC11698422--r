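Package: clonotangle
Title: Concordance of Transcript-Derived and DNA-Derived Clonal Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds tumour clonal phylogenies from four data channels --
    genomic SNV genotypes (identity-by-state), genomic copy-number segments
    (fixed-width binning with thresholded calls and bootstrap-supported
    clustering), expression-inferred copy number (a moving-average
    inferCNV-style profile), and trinary-discretized transcript counts --
    and quantifies their concordance with a tanglegram entanglement
    statistic together with exact one- and two-sided untangling.  A
    clone-tree simulator generates paired DNA+RNA observations (single
    cells, multi-region bulk, pseudo-bulked spatial sections) so every
    stage of the comparison is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    yaml,
    optparse
Config/testthat/edition: 3
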