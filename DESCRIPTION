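Package: ampliconBE
Title: Quantification of Base-Editing Outcomes from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cytidine base-editor experiments assayed by
    targeted amplicon deep sequencing. Reads are quality-masked at a Phred
    threshold, locally aligned to the amplicon reference with an affine-gap
    Smith-Waterman aligner, and tallied per reference position to obtain
    per-cytosine C-to-T conversion frequencies across the protospacer,
    windowed indel frequencies around the nickase cleavage site,
    Phred-derived detection limits, treated-versus-control significance
    tests, on/off-target specificity ratios with detection-limit imputation,
    and dose-response regression. A synthetic FASTQ generator with known
    per-position editing rates, indels, sequencing error and quality models
    makes every stage testable without external sequencing data, including
    an in-vitro substrate mode with flank-anchored protospacer extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
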