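Package: codonbias
Title: Codon Usage Bias, Positional Composition and Skew Analysis of
    Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage in collections of
    protein-coding sequences: CDS validation and filtering, per-gene
    composition and usage indices (base frequencies at synonymous third
    positions, GC content, effective number of codons, relative synonymous
    codon usage, GRAVY, aromaticity), ENC-GC3 and parity-rule-2
    diagnostics of mutation versus selection pressure, correspondence
    analysis of RSCU matrices, optimal-codon identification from axis
    extremes, positional hydrogen-bond profiles with bootstrap confidence
    bands, sliding-window CG- and AT-skew trends, and a synthetic CDS
    generator with closed-form expectations for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
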