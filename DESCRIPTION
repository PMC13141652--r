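Package: nanochimera
Title: Detection and Signal-Based Filtering of False-Positive Chimeric
    Reads in Nanopore Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies artifact (false-positive) chimeric reads in nanopore
    long-read sequencing data and filters them using their raw current
    signals. Split-read alignments are typed into inverted-repeat, cross and
    gapped chimera geometries with an overlap-ratio and homology screen; a
    low-amplitude low-variance "smoothed segment" feature is detected in the
    current trace near chimeric junctions; a one-dimensional residual
    convolutional network (with MLP and deep-CNN baselines) classifies
    breakpoint-centered signal windows; and the effect of filtering on
    structural-variant calling is quantified by clean-versus-raw VCF
    comparison. A built-in squiggle and read simulator generates references,
    chimeric reads with ground truth, and pore-like current traces so the
    whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    Rsamtools,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
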