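Package: stressmark
Title: Island Calling and Time-Course Classification of Stress-Responsive
    Histone Marks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide analysis of H3K4me3 ChIP-seq in factorial
    stress time-course designs. Implements Poisson island-based enrichment
    calling against input controls, sliding-window exact-binomial
    differential detection between treatment groups, factorial time-course
    rules that classify regions as drought-, combined drought-and-heat-, or
    heat-responsive, genomic-feature annotation with TSS metaprofiling,
    peak-to-gene overlap with hypergeometric enrichment statistics, MapMan
    export, relative-expression computation for qPCR validation by the
    2^-ddCT method, and a synthetic-data generator that emulates the
    3-condition x 6-time-point x 3-replicate study design with implanted
    ground-truth islands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
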