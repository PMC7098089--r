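Package: insuloop
Title: Sequence Models of CTCF/Cohesin Insulator Loops and Variant Impact
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models CTCF/cohesin-mediated insulator loops directly from DNA
    sequence and predicts the impact of non-coding variants (SNVs and indels)
    on loop probability. Provides readers for the standard interval and
    variant formats (FASTA, BEDPE, BED/narrowPeak, FIMO TSV, VCF), a dataset
    builder that standardizes loop anchors to fixed-length windows and
    constructs the three non-anchor and five non-loop negative classes, a
    five-model stack (dilated convolutional and bidirectional-LSTM anchor
    models, a combined anchor model, an anchor orientation model, and a loop
    model over anchor pairs) trained by backpropagation in compiled code,
    class-activation-map interpretation with LOESS smoothing and peak
    calling, a variant engine for reference/alternate loop scoring and
    single-base saturation deletion scans, and a synthetic-grammar genome
    simulator that makes the whole pipeline trainable and testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    data.table,
    vcfR,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
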