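Package: editscan
Title: Whole-Genome Detection and Quantification of CRISPR/Cas9 Editing
    Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and quantifies CRISPR/Cas9 editing sites in plant
    genomes from whole-genome and targeted sequencing. Provides a
    mismatch- and bulge-tolerant guide-RNA site scanner, multi-caller
    variant-call consensus with wild-type and different-target control
    subtraction, candidate-window extraction around surviving variants
    with on-/off-target labelling, Digenome-style in vitro cleavage-site
    calling from read-start pileups, and amplicon deep-sequencing editing
    efficiency and mutation-spectrum quantification. A deterministic
    synthetic-data generator makes every stage runnable end-to-end
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
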