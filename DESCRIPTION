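Package: cellscreen
Title: Genomic Integrity Screening of Cultured Cell Lines from SNP Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens SNP genotyping array data for genomic abnormalities in
    cultured cell lines. Detects whole-chromosome aneuploidy and sample
    contamination by constrained Gaussian peak fitting of B-allele-frequency
    (BAF) distributions, and sub-chromosomal copy-number variants with a
    four-state hidden Markov model over BAF and Log R Ratio (LRR), including
    a 16-state paired mode that calls differences between a cell line and
    the material it was derived from while ignoring copy-number variation
    shared by both. Ships a simulation benchmark emulating a genotyping
    array and overlap-based evaluation of calls against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    vcfR,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
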