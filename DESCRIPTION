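Package: splicearray
Title: Design and Analysis of Exon-Junction Splice Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for two-color alternative-splicing microarrays:
    a probe designer that emits thermodynamically balanced exon, junction and
    control oligonucleotides from transcript models using nearest-neighbor
    melting temperatures with secondary-structure and cross-hybridization
    screens; a hybridization simulator that generates realistic two-channel
    intensities from known isoform mixtures, including partial-match residual
    binding, spike-in controls and multiplicative lognormal noise; and an
    analysis engine that separates whole-gene expression change from
    splice-form change using self-to-self-calibrated variance thresholds and
    a form-change ranking of candidate genes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    methods,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
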