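Package: refpick
Title: Data-Driven Selection and Evaluation of RNA-Seq Reference Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects custom reference (housekeeping) genes directly from an
    RNA-seq count matrix: counts are converted to transcripts per million
    (TPM), a data-adaptive per-sample expression cutoff separates weakly
    expressed from expressed genes, and the lowest-coefficient-of-variation
    fraction of the expressed genes is returned as the reference set.
    Includes a stability-evaluation suite (geNorm M-value ranking, a
    NormFinder-style model-based stability index, coefficient-of-variation
    comparison across gene sets), median-of-ratios size factors restricted
    to a control-gene set, and a negative-binomial simulator with planted
    stable, noise and differentially expressed genes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    DESeq2,
    rtracklayer,
    GenomicRanges,
    IRanges
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
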