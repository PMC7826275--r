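Package: tandemscope
Title: Tandem Repeat Copy Number Estimation from Long Sequencing Reads
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the copy number of tandemly repeated DNA units
    (macrosatellite arrays such as the budding yeast CUP1 locus) directly
    from individual long sequencing reads. Implements a match-run profile
    between a read and a repeat-unit reference, dense-region detection and
    a discrete Fourier transform repeat counter; a k-mer dot-plot diagonal
    counter used as an orthogonal estimate and to locate cassette
    insertions; spanning-read selection from flanking sequences; a
    nanopore-like read simulator with per-molecule ground truth; and
    population-level copy-number and instability statistics (variation
    index, qPCR calibration, marker-loss frequency).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, LongRead, CopyNumberVariation, Alignment, Software
RoxygenNote: 7.3.3
Collate: 
    'tandemscope-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'profile.R'
    'detector.R'
    'dotplot.R'
    'popstats.R'
    'sequence-io.R'
    'simulate.R'
    'span.R'
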