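Package: repeatquant
Title: Repeatome RNA-seq Quantification and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies transcription of repetitive elements (pericentromeric
    and centromeric satellites, LINEs, SINEs, endogenous retroviruses) from
    short-read RNA-seq. Builds a combined repeat reference holding one
    canonical entry per repeat type plus flank-extended genomic instances,
    assigns reads to repeat types under uniqueness criteria with an optional
    genome-masking filter, estimates type-level abundance with k-mer
    equivalence classes and a variational Bayes EM (TPM output), and tests
    two-condition differential repeat expression with Kal's Z-test or the
    Baggerly weighted proportion test under Benjamini-Hochberg FDR control.
    Ships a synthetic genome and read simulator that emulates drug-induced
    derepression of silenced repeats and records ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
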